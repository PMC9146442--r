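# Programmatic fixtures used across test files.

toy_table <- function(values = rbind(s1 = c(3, 4, 5), s2 = c(1, 0, 2)),
                      phyla = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
                      genera = c("Blautia", "Lactobacillus", "Bacteroides")) {
  colnames(values) <- genera
  tax <- data.frame(taxon_id = genera, kingdom = "Bacteria", phylum = phyla,
                    class = paste0(phyla, "_c"), order = paste0(phyla, "_o"),
                    family = paste0(genera, "_f"), genus = genera,
                    stringsAsFactors = FALSE)
  abundance_table(values, tax, mode = "counts")
}

random_counts_table <- function(n = 8, m = 20, seed = 1) {
  set.seed(seed)
  vals <- matrix(rpois(n * m, lambda = rexp(m, 1 / 50)[col(matrix(0, n, m))]),
                 n, m)
  vals[1, ] <- vals[1, ] + 1   # no all-zero sample
  rownames(vals) <- sprintf("s%02d", seq_len(n))
  colnames(vals) <- sprintf("t%02d", seq_len(m))
  tax <- data.frame(taxon_id = colnames(vals), kingdom = "Bacteria",
                    phylum = rep(c("Firmicutes", "Bacteroidetes"),
                                 length.out = m),
                    genus = colnames(vals), stringsAsFactors = FALSE)
  tax$class <- paste0(tax$phylum, "_c")
  tax$order <- paste0(tax$phylum, "_o")
  tax$family <- paste0(tax$genus, "_f")
  abundance_table(vals, tax, mode = "counts")
}

# presence-pattern table: binary matrix -> counts table (presence = 1 read)
presence_table <- function(P, phyla = NULL) {
  m <- ncol(P)
  if (is.null(colnames(P))) colnames(P) <- sprintf("g%02d", seq_len(m))
  if (is.null(rownames(P))) rownames(P) <- sprintf("s%03d", seq_len(nrow(P)))
  if (is.null(phyla)) phyla <- rep("Firmicutes", m)
  tax <- data.frame(taxon_id = colnames(P), kingdom = "Bacteria",
                    phylum = phyla, class = paste0(phyla, "_c"),
                    order = paste0(phyla, "_o"),
                    family = paste0(colnames(P), "_f"), genus = colnames(P),
                    stringsAsFactors = FALSE)
  abundance_table(P * 1, tax, mode = "counts")
}

# a tiny null two-cohort spec (identical templates, nothing planted)
null_study_spec <- function() {
  spec <- default_spec(n_pairs = 0, assoc_rho = 0)
  spec$cohorts$nonobese$phylum_means <- spec$cohorts$obese$phylum_means
  spec
}
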