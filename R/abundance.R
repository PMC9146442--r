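#' Construct a sample-by-taxa abundance table
#'
#' The central container of the pipeline: a numeric samples x taxa matrix in
#' either `counts` mode (non-negative integers) or `relative` mode (each row
#' sums to one), together with a taxonomy table holding the parsed lineage of
#' every column.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   taxa in columns (colnames = taxon ids).
#' @param taxonomy data.frame with a `taxon_id` column matching
#'   `colnames(values)` plus one column per rank (`kingdom` ... `species`);
#'   `NA` marks an unassigned rank. Missing rank columns are filled with `NA`.
#' @param mode `"counts"` or `"relative"`.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, taxonomy, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundance values must be finite and non-negative")
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(taxonomy)) stop("taxonomy needs a 'taxon_id' column")
  if (!setequal(taxonomy$taxon_id, colnames(values)) ||
      nrow(taxonomy) != ncol(values))
    stop("taxonomy taxon_id set must match the table's columns")
  taxonomy <- taxonomy[match(colnames(values), taxonomy$taxon_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  for (r in TAXONOMY_RANKS)
    if (!r %in% names(taxonomy)) taxonomy[[r]] <- NA_character_
  taxonomy <- taxonomy[, c("taxon_id", TAXONOMY_RANKS)]
  # unassigned ranks must propagate downwards
  for (i in seq_along(TAXONOMY_RANKS)[-1]) {
    hi <- taxonomy[[TAXONOMY_RANKS[i - 1]]]
    taxonomy[[TAXONOMY_RANKS[i]]][is.na(hi)] <- NA_character_
  }
  if (mode == "counts") {
    if (any(abs(values - round(values)) > 1e-8))
      stop("counts mode requires integer values")
    values <- round(values)
  } else {
    rs <- rowSums(values)
    if (any(rs == 0)) stop("relative mode disallows all-zero samples: ",
                           paste(rownames(values)[rs == 0], collapse = ", "))
    if (any(abs(rs - 1) > 1e-9))
      stop("relative mode requires rows summing to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
  }
  structure(list(values = values, taxonomy = taxonomy, mode = mode),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  assigned <- colSums(!is.na(t(x$taxonomy[TAXONOMY_RANKS])))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Sample identifiers of an abundance table
#' @param table an `abundance_table`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(table) rownames(table$values)

#' Taxon identifiers of an abundance table
#' @param table an `abundance_table`.
#' @return character vector of taxon ids.
#' @export
taxon_ids <- function(table) colnames(table$values)

# tokens treated as "no assignment" at a rank
UNASSIGNED_TOKENS <- c("", "__", "uncultured", "unclassified", "unassigned",
                       "ambiguous_taxa", "na", "none", "unknown")

#' Parse taxonomy lineage strings
#'
#' Accepts Greengenes-style prefixed lineages (`k__Bacteria; p__Firmicutes;
#' ...`) and plain semicolon-delimited strings (SILVA exports). Empty,
#' prefix-only or "uncultured"-type tokens are marked unassigned, and an
#' unassigned rank forces all lower ranks to unassigned.
#'
#' @param lineages character vector of lineage strings.
#' @return data.frame with columns `kingdom` ... `species` (`NA` =
#'   unassigned), one row per input string.
#' @export
parse_lineage <- function(lineages) {
  prefix_map <- c(k = "kingdom", d = "kingdom", p = "phylum", c = "class",
                  o = "order", f = "family", g = "genus", s = "species")
  out <- matrix(NA_character_, length(lineages), length(TAXONOMY_RANKS),
                dimnames = list(NULL, TAXONOMY_RANKS))
  for (i in seq_along(lineages)) {
    toks <- trimws(strsplit(lineages[i], ";", fixed = TRUE)[[1]])
    if (length(toks) == 0) next
    has_prefix <- grepl("^[a-zA-Z]__", toks)
    for (j in seq_along(toks)) {
      tok <- toks[j]
      if (has_prefix[j]) {
        rank <- prefix_map[tolower(substr(tok, 1, 1))]
        tok <- sub("^[a-zA-Z]__", "", tok)
      } else {
        if (j > length(TAXONOMY_RANKS)) next
        rank <- TAXONOMY_RANKS[j]
      }
      if (is.na(rank)) next
      if (tolower(tok) %in% UNASSIGNED_TOKENS) next
      out[i, rank] <- tok
    }
    # enforce downward propagation of unassignment
    for (j in seq_along(TAXONOMY_RANKS)[-1])
      if (is.na(out[i, j - 1])) out[i, j] <- NA_character_
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

format_lineage <- function(taxonomy) {
  pre <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  apply(taxonomy[TAXONOMY_RANKS], 1L, function(row) {
    row[is.na(row)] <- ""
    paste0(pre, row, collapse = "; ")
  })
}

#' Read a feature table from TSV
#'
#' Reads QIIME2-style TSV exports. Leading comment lines (`#Constructed from
#' biom file`) are tolerated; a header line starting with `#OTU ID` is used
#' as the header. Orientation is auto-detected by which axis carries lineage
#' strings (semicolons); ambiguous files are read as taxa-in-rows.
#'
#' @param path path to a TSV file. Taxa-in-rows files need a first column of
#'   taxon ids and a lineage column (named `taxonomy`/`lineage`/`Taxon`, or
#'   detected by content); remaining columns are samples. Taxa-in-columns
#'   files carry lineage strings as column names and sample ids in the first
#'   column.
#' @return an `abundance_table` in counts mode.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # skip leading comment lines ("#Constructed from biom file"); a "#OTU ID"
  # style line (tab-delimited) is the header, with its leading "#" stripped
  first <- 1L
  while (first <= length(lines) && startsWith(lines[first], "#") &&
         !grepl("\t", lines[first], fixed = TRUE))
    first <- first + 1L
  if (first > length(lines)) stop("no tabular content in ", path)
  keep <- lines[first:length(lines)]
  keep[1] <- sub("^#", "", keep[1])
  df <- utils::read.delim(text = paste(keep, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs at least two columns")
  char_cols <- which(vapply(df, is.character, logical(1)))[-1]
  lineage_col <- NULL
  named <- which(tolower(names(df)) %in% c("taxonomy", "lineage", "taxon"))
  if (length(named)) lineage_col <- named[1]
  else if (length(char_cols)) {
    semi <- vapply(char_cols, function(j) mean(grepl(";", df[[j]])), numeric(1))
    if (any(semi > 0.5)) lineage_col <- char_cols[which.max(semi)]
  }
  if (!is.null(lineage_col)) {            # taxa in rows
    ids <- as.character(df[[1]])
    lineage <- df[[lineage_col]]
    mat <- as.matrix(df[, -c(1, lineage_col), drop = FALSE])
  } else if (any(grepl(";", names(df)[-1]))) {  # taxa in columns
    ids <- names(df)[-1]
    lineage <- ids
    mat <- as.matrix(df[, -1, drop = FALSE])
    colnames(mat) <- ids
    rownames(mat) <- as.character(df[[1]])
    tax <- cbind(taxon_id = ids, parse_lineage(lineage))
    return(build_read_table(mat, tax, path))
  } else stop("could not locate lineage strings in ", path)
  storage.mode(mat) <- "double"
  mat <- t(mat)
  colnames(mat) <- ids
  tax <- cbind(taxon_id = ids, parse_lineage(lineage))
  build_read_table(mat, tax, path)
}

# integer values are read as counts; fractional values with unit row sums
# as relative abundances
build_read_table <- function(mat, tax, path) {
  if (any(is.na(mat))) stop("non-numeric values in ", path)
  if (any(mat < 0)) stop("negative values in ", path)
  if (all(abs(mat - round(mat)) < 1e-8))
    return(abundance_table(mat, tax, mode = "counts"))
  if (all(abs(rowSums(mat) - 1) <= 1e-6)) {
    mat <- mat / rowSums(mat)
    return(abundance_table(mat, tax, mode = "relative"))
  }
  stop("values in ", path, " are neither integer counts nor row-normalized ",
       "relative abundances")
}

#' Write an abundance table to TSV
#'
#' Taxa-in-rows layout with a trailing `taxonomy` column holding the
#' prefixed lineage string, re-readable by [read_feature_table()].
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(`taxon_id` = taxon_ids(table),
                   t(table$values), check.names = FALSE)
  df$taxonomy <- format_lineage(table$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse taxa to a taxonomic rank
#'
#' Sums counts of all taxa sharing a name at `rank`. Taxa unassigned at
#' `rank` are discarded from the collapsed table (they remain available for
#' analyses at higher ranks, where their assigned names keep them).
#'
#' @param table an `abundance_table` in counts mode.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return a collapsed `abundance_table` in counts mode; taxon ids are the
#'   names at `rank`, ranks above `rank` are retained where unambiguous.
#' @export
collapse_taxa <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "counts") stop("collapse_taxa requires counts mode")
  if (!rank %in% TAXONOMY_RANKS[-1])
    stop("'rank' must be one of: ", paste(TAXONOMY_RANKS[-1], collapse = ", "))
  names_at <- table$taxonomy[[rank]]
  keep <- !is.na(names_at)
  if (!any(keep)) stop("no taxa assigned at rank '", rank, "'")
  vals <- table$values[, keep, drop = FALSE]
  grp <- factor(names_at[keep], levels = unique(names_at[keep]))
  agg <- vals %*% outer(grp, levels(grp), `==`)
  colnames(agg) <- levels(grp)
  higher <- TAXONOMY_RANKS[seq_len(match(rank, TAXONOMY_RANKS))]
  tax <- data.frame(taxon_id = levels(grp), stringsAsFactors = FALSE)
  for (r in higher) {
    vals_r <- tapply(table$taxonomy[[r]][keep], grp, function(v) {
      u <- unique(v[!is.na(v)])
      if (length(u) == 1) u else NA_character_
    })
    tax[[r]] <- as.character(vals_r[levels(grp)])
  }
  tax[[rank]] <- levels(grp)
  abundance_table(agg, tax, mode = "counts")
}

#' Convert counts to relative abundances
#'
#' @param table an `abundance_table` in counts mode with positive sample
#'   totals.
#' @return the table with each row divided by its total, in relative mode.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "relative") return(table)
  tot <- rowSums(table$values)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(rownames(table$values)[tot == 0], collapse = ", "))
  abundance_table(table$values / tot, table$taxonomy, mode = "relative")
}

#' Drop rare taxa by mean relative abundance
#'
#' Keeps taxa whose mean relative abundance across samples is at least
#' `min_mean_relative`; taxa strictly below the threshold are excluded
#' (the boundary is kept). Column order is preserved. Applied to a counts
#' table, the counts are retained for the surviving taxa.
#'
#' @param table an `abundance_table` (counts or relative).
#' @param min_mean_relative threshold in `[0, 1)`; default 0.001 (0.1%).
#' @return the filtered table, same mode as the input.
#' @export
filter_rare <- function(table, min_mean_relative = 0.001) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(min_mean_relative) || length(min_mean_relative) != 1L ||
      min_mean_relative < 0 || min_mean_relative >= 1)
    stop("'min_mean_relative' must lie in [0, 1)")
  rel <- to_relative(table)
  keep <- colMeans(rel$values) >= min_mean_relative
  vals <- table$values[, keep, drop = FALSE]
  if (table$mode == "relative") {
    tot <- rowSums(vals)
    if (any(tot == 0))
      stop("sample(s) left empty by the rare filter: ",
           paste(rownames(vals)[tot == 0], collapse = ", "))
    vals <- vals / tot   # renormalize so rows still sum to one
  }
  abundance_table(vals, table$taxonomy[keep, , drop = FALSE],
                  mode = table$mode)
}
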