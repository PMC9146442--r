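#' Two-group Wilcoxon rank-sum test
#'
#' Mann-Whitney U with average ranks on ties. The p-value is exact (full
#' arrangement enumeration) when both groups have at most 10 observations
#' and there are no ties; otherwise the normal approximation with tie
#' correction and 0.5 continuity correction is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list: `statistic` (U for `x`), `p_value` (two-sided), `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Per-taxon two-group abundance screen
#'
#' Runs [wilcoxon_rank_sum()] on the relative abundance of every shared
#' taxon between two cohorts, with optional Benjamini-Hochberg adjustment
#' across taxa.
#'
#' @param table_a,table_b `abundance_table`s in relative mode sharing the
#'   same taxon set (order may differ).
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame: `taxon`, `statistic`, `p_value`, `direction` (which
#'   cohort has the higher median: `"a"`, `"b"` or `"none"`), and `q_value`
#'   when BH-adjusted.
#' @export
per_taxon_group_test <- function(table_a, table_b, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(table_a, "abundance_table"),
            inherits(table_b, "abundance_table"))
  if (table_a$mode != "relative" || table_b$mode != "relative")
    stop("per_taxon_group_test requires relative mode")
  if (!setequal(taxon_ids(table_a), taxon_ids(table_b))) {
    diff <- c(setdiff(taxon_ids(table_a), taxon_ids(table_b)),
              setdiff(taxon_ids(table_b), taxon_ids(table_a)))
    stop("taxon sets differ: ", paste(diff, collapse = ", "))
  }
  taxa <- taxon_ids(table_a)
  res <- lapply(taxa, function(tx) {
    xa <- table_a$values[, tx]
    xb <- table_b$values[, tx]
    wt <- wilcoxon_rank_sum(xa, xb)
    dm <- stats::median(xa) - stats::median(xb)
    data.frame(taxon = tx, statistic = wt$statistic, p_value = wt$p_value,
               direction = if (dm > 0) "a" else if (dm < 0) "b" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") out$q_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' ANCOM compositional differential abundance
#'
#' Analysis of composition of microbiomes: because relative abundances sum
#' to one, a shift in one taxon perturbs all others, so per-taxon tests on
#' proportions are confounded. ANCOM instead tests every pairwise additive
#' log-ratio `log((c_i + pc) / (c_j + pc))` between groups with the Wilcoxon
#' rank-sum test. For each taxon its `m - 1` pair p-values are BH-adjusted
#' at `alpha`; the taxon's `W` is the number rejected, and it is flagged
#' differentially abundant when `W >= ceiling(w_frac * (m - 1))`.
#'
#' @param table `abundance_table` in counts mode with at least 2 taxa.
#' @param grouping two-level label per sample, each group of size >= 2.
#' @param pseudocount added to counts before taking logs (default 1).
#' @param alpha per-taxon BH level for the pairwise tests.
#' @param w_frac fraction of the `m - 1` tests that must reject.
#' @return data.frame `taxon`, `W`, `reject`; settings kept as attributes
#'   (`pseudocount`, `alpha`, `w_frac`, `w_threshold`).
#' @export
ancom <- function(table, grouping, pseudocount = 1, alpha = 0.05,
                  w_frac = 0.7) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "counts") stop("ancom requires counts mode")
  m <- ncol(table$values)
  if (m < 2) stop("ancom needs at least 2 taxa")
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(table$values))
    stop("grouping length must match the samples")
  sizes <- table(grouping)
  if (length(sizes) != 2) stop("ancom compares exactly 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  ga <- grouping == names(sizes)[1]
  logc <- log(table$values + pseudocount)
  pmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    lr <- logc[, i] - logc[, j]
    pmat[i, j] <- pmat[j, i] <- wilcoxon_rank_sum(lr[ga], lr[!ga])$p_value
  }
  W <- vapply(seq_len(m), function(i) {
    sum(stats::p.adjust(pmat[i, -i], "BH") <= alpha)
  }, numeric(1))
  w_threshold <- ceiling(w_frac * (m - 1))
  out <- data.frame(taxon = taxon_ids(table), W = as.integer(W),
                    reject = W >= w_threshold, stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "alpha") <- alpha
  attr(out, "w_frac") <- w_frac
  attr(out, "w_threshold") <- w_threshold
  out
}

#' Firmicutes / Bacteroidetes ratio per sample
#'
#' @param table_phylum phylum-level `abundance_table` containing both
#'   `Firmicutes` and `Bacteroidetes`.
#' @return data.frame `sample_id`, `fb_ratio`, `defined`; the ratio is `NA`
#'   (flagged undefined) where Bacteroidetes is absent.
#' @export
fb_ratio <- function(table_phylum) {
  stopifnot(inherits(table_phylum, "abundance_table"))
  ids <- taxon_ids(table_phylum)
  missing <- setdiff(c("Firmicutes", "Bacteroidetes"), ids)
  if (length(missing)) stop("phylum table lacks: ", paste(missing, collapse = ", "))
  rel <- to_relative(table_phylum)
  f <- rel$values[, "Firmicutes"]
  b <- rel$values[, "Bacteroidetes"]
  ratio <- ifelse(b > 0, f / b, NA_real_)
  data.frame(sample_id = sample_ids(table_phylum), fb_ratio = ratio,
             defined = b > 0, stringsAsFactors = FALSE)
}
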