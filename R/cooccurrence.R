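#' Presence/absence matrix
#'
#' @param table an `abundance_table` (counts or relative).
#' @param detection_threshold a taxon is present in a sample when its value
#'   is strictly greater than this (default 0).
#' @return integer samples x taxa matrix of 0/1.
#' @export
presence_matrix <- function(table, detection_threshold = 0) {
  stopifnot(inherits(table, "abundance_table"))
  if (detection_threshold < 0) stop("detection threshold must be >= 0")
  m <- (table$values > detection_threshold) * 1L
  dimnames(m) <- dimnames(table$values)
  m
}

#' Presence summary of a taxon pair
#'
#' @param N total samples; `a`, `b` presence counts of the two taxa; `k`
#'   copresence count. Must satisfy `max(0, a + b - N) <= k <= min(a, b)`.
#' @return validated list of class `presence_pair`.
#' @export
presence_pair <- function(N, a, b, k) {
  stopifnot(length(N) == 1, length(a) == 1, length(b) == 1, length(k) == 1)
  if (a > N || b > N || a < 0 || b < 0)
    stop("presence counts must lie in [0, N]")
  if (k > min(a, b) || k < max(0, a + b - N))
    stop("copresence count k violates its support bounds")
  structure(list(N = N, a = a, b = b, k = k), class = "presence_pair")
}

#' Jaccard index of a presence pair
#'
#' Ratio of the number of samples containing both taxa to the number
#' containing at least one: `J = k / (a + b - k)`.
#'
#' @param pair a [presence_pair()].
#' @return J in `[0, 1]`.
#' @export
jaccard <- function(pair) {
  stopifnot(inherits(pair, "presence_pair"))
  if (pair$a + pair$b - pair$k <= 0)
    stop("Jaccard undefined: neither taxon occurs")
  pair$k / (pair$a + pair$b - pair$k)
}

#' Hypergeometric copresence / exclusion test
#'
#' Under random placement of the two presence sets (sizes `a` and `b` among
#' `N` samples), the copresence count follows Hypergeometric(N, a, b).
#' Both tails are inclusive: `p_copresence = P(X >= k)` and
#' `p_exclusion = P(X <= k)`.
#'
#' @param pair a [presence_pair()].
#' @return list `p_copresence`, `p_exclusion`.
#' @export
hypergeom_test <- function(pair) {
  stopifnot(inherits(pair, "presence_pair"))
  with(pair, list(
    p_copresence = stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE),
    p_exclusion  = stats::phyper(k, a, N - a, b)))
}

#' Build a genus cooccurrence network
#'
#' Applies the rare-genus filter, binarizes to presence/absence, and tests
#' every unordered genus pair for copresence (upper hypergeometric tail) and
#' mutual exclusion (lower tail). Raw p-values are Bonferroni-corrected over
#' the whole family (pairs x 2 tails by default; per-tail families behind
#' `tail_family`), and edges with adjusted p <= `alpha` are retained with
#' the sign of the winning tail. Nodes are the genera incident to at least
#' one retained edge.
#'
#' @param table genus-level `abundance_table` in counts or relative mode.
#' @param min_mean_rel rare filter threshold (default 0.001).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param correction `"bonferroni"` (the only supported correction).
#' @param detection_threshold passed to [presence_matrix()].
#' @param tail_family `"both"` (family = pairs x 2) or `"per_tail"`
#'   (family = pairs, each tail corrected separately).
#' @return list of class `cooccurrence_network`: `nodes` (data.frame
#'   `genus`, `phylum`, `degree`), `edges` (data.frame `genus_a`, `genus_b`,
#'   `phylum_a`, `phylum_b`, `jaccard`, `sign`, `strength`, `p_raw`,
#'   `p_adj`), `clustering`, `n_genera_tested`, `n_tests`, `graph`
#'   (an igraph object).
#' @export
build_network <- function(table, min_mean_rel = 0.001, alpha = 0.05,
                          correction = "bonferroni", detection_threshold = 0,
                          tail_family = c("both", "per_tail")) {
  stopifnot(inherits(table, "abundance_table"))
  tail_family <- match.arg(tail_family)
  correction <- match.arg(correction, "bonferroni")
  # at threshold 0 the filter is the identity; skipping it lets presence/
  # absence tables with empty samples through (they carry no information
  # loss for the margin counts)
  filt <- if (min_mean_rel > 0) filter_rare(table, min_mean_rel) else table
  g <- ncol(filt$values)
  if (g < 2) stop("fewer than 2 genera survive the rare filter")
  P <- presence_matrix(filt, detection_threshold)
  N <- nrow(P)
  a <- colSums(P)
  K <- crossprod(P)                         # copresence counts
  ij <- which(upper.tri(K), arr.ind = TRUE)
  k <- K[ij]
  ai <- a[ij[, 1]]; bj <- a[ij[, 2]]
  p_co <- stats::phyper(k - 1, ai, N - ai, bj, lower.tail = FALSE)
  p_ex <- stats::phyper(k, ai, N - ai, bj)
  n_pairs <- nrow(ij)
  n_tests <- if (tail_family == "both") 2 * n_pairs else n_pairs
  adj_co <- pmin(1, p_co * n_tests)
  adj_ex <- pmin(1, p_ex * n_tests)
  is_co <- adj_co <= alpha
  is_ex <- adj_ex <= alpha & !is_co
  keep <- is_co | is_ex
  J <- ifelse(ai + bj - k > 0, k / (ai + bj - k), NA_real_)
  genera <- taxon_ids(filt)
  phyla <- filt$taxonomy$phylum
  sign <- ifelse(is_co, "copresence", "exclusion")[keep]
  edges <- data.frame(
    genus_a = genera[ij[keep, 1]], genus_b = genera[ij[keep, 2]],
    phylum_a = phyla[ij[keep, 1]], phylum_b = phyla[ij[keep, 2]],
    jaccard = J[keep], sign = sign,
    strength = ifelse(sign == "copresence", J[keep], 1 - J[keep]),
    p_raw = ifelse(is_co, p_co, p_ex)[keep],
    p_adj = ifelse(is_co, adj_co, adj_ex)[keep],
    stringsAsFactors = FALSE)
  node_names <- sort(unique(c(edges$genus_a, edges$genus_b)))
  graph <- igraph::graph_from_data_frame(
    edges[c("genus_a", "genus_b")], directed = FALSE,
    vertices = data.frame(name = node_names))
  nodes <- data.frame(
    genus = node_names,
    phylum = phyla[match(node_names, genera)],
    degree = if (length(node_names)) igraph::degree(graph)[node_names]
             else integer(0),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  net <- structure(list(nodes = nodes, edges = edges, clustering = NA_real_,
                        n_genera_tested = g, n_tests = n_tests,
                        alpha = alpha, graph = graph),
                   class = "cooccurrence_network")
  net$clustering <- if (nrow(nodes)) clustering_coefficient(net) else NA_real_
  net
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "cooccurrence network: %d genera tested, %d edges among %d nodes (C = %s)\n",
    x$n_genera_tested, nrow(x$edges), nrow(x$nodes),
    format(x$clustering, digits = 3)))
  invisible(x)
}

#' Average local clustering coefficient
#'
#' Mean over nodes of the fraction of a node's neighbor pairs that are
#' themselves connected; nodes of degree < 2 contribute 0. Edge signs are
#' ignored.
#'
#' @param network a `cooccurrence_network` or an igraph graph.
#' @return C in `[0, 1]`.
#' @export
clustering_coefficient <- function(network) {
  g <- if (inherits(network, "cooccurrence_network")) network$graph
       else network
  if (igraph::vcount(g) == 0) stop("empty node set")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Random-graph null test for network clustering
#'
#' Compares the observed average clustering coefficient with `R` uniform
#' G(n, m) random graphs on the same node and edge counts:
#' `p = (1 + #{C_null >= C_obs}) / (R + 1)`. A degree-preserving rewiring
#' null is available behind `null_model = "rewire"`.
#'
#' @param network a `cooccurrence_network` (>= 3 nodes, >= 1 edge).
#' @param R number of random networks (default 10000, minimum 100).
#' @param null_model `"gnm"` or `"rewire"`.
#' @param seed RNG seed.
#' @return list of class `null_network_test`: `C_obs`, `p_value`, `R`,
#'   `null_model`, `seed`, `null_summary` (quantiles of the null C).
#' @export
null_network_test <- function(network, R = 10000,
                              null_model = c("gnm", "rewire"), seed = NULL) {
  null_model <- match.arg(null_model)
  if (R < 100) stop("R must be at least 100")
  g <- if (inherits(network, "cooccurrence_network")) network$graph
       else network
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n < 3 || m < 1) stop("need at least 3 nodes and 1 edge")
  C_obs <- clustering_coefficient(g)
  C_null <- with_seed(seed, vapply(seq_len(R), function(r) {
    gr <- if (null_model == "gnm") igraph::sample_gnm(n, m)
          else igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
    igraph::transitivity(gr, type = "localaverage", isolates = "zero")
  }, numeric(1)))
  structure(list(C_obs = C_obs,
                 p_value = (1 + sum(C_null >= C_obs - 1e-12)) / (R + 1),
                 R = R, null_model = null_model, seed = seed,
                 null_summary = stats::quantile(C_null,
                                                c(0, .25, .5, .75, .95, 1))),
            class = "null_network_test")
}

#' @export
print.null_network_test <- function(x, ...) {
  cat(sprintf("clustering null test: C = %.3f vs %d %s graphs, p = %.4g\n",
              x$C_obs, x$R, x$null_model, x$p_value))
  invisible(x)
}

#' All intra-phylum pairwise Jaccard indices of a cohort
#'
#' @param table genus-level `abundance_table`.
#' @param phylum phylum name.
#' @param min_mean_rel rare filter threshold.
#' @param detection_threshold presence threshold.
#' @return numeric vector of Jaccard indices, one per unordered genus pair
#'   within the phylum (pairs where neither genus occurs are dropped).
#' @export
intra_phylum_jaccard <- function(table, phylum, min_mean_rel = 0.001,
                                 detection_threshold = 0) {
  stopifnot(inherits(table, "abundance_table"))
  filt <- if (min_mean_rel > 0) filter_rare(table, min_mean_rel) else table
  sel <- !is.na(filt$taxonomy$phylum) & filt$taxonomy$phylum == phylum
  if (sum(sel) < 2)
    stop("fewer than 2 genera of phylum '", phylum, "' after filtering")
  P <- presence_matrix(
    abundance_table(filt$values[, sel, drop = FALSE],
                    filt$taxonomy[sel, , drop = FALSE], mode = filt$mode),
    detection_threshold)
  K <- crossprod(P)
  a <- colSums(P)
  ij <- which(upper.tri(K), arr.ind = TRUE)
  k <- K[ij]
  u <- a[ij[, 1]] + a[ij[, 2]] - k
  (k / u)[u > 0]
}

#' Compare intra-phylum cooccurrence between two cohorts
#'
#' Two-sided Wilcoxon rank-sum test on the two cohorts' sets of
#' intra-phylum pairwise Jaccard indices.
#'
#' @param table_a,table_b genus-level `abundance_table`s for the cohorts.
#' @param phylum phylum name.
#' @param ... passed to [intra_phylum_jaccard()].
#' @return list: `statistic`, `p_value`, `n_pairs_a`, `n_pairs_b`,
#'   `median_a`, `median_b`.
#' @export
intra_phylum_comparison <- function(table_a, table_b, phylum, ...) {
  ja <- intra_phylum_jaccard(table_a, phylum, ...)
  jb <- intra_phylum_jaccard(table_b, phylum, ...)
  if (length(ja) < 2 || length(jb) < 2)
    stop("fewer than 2 intra-phylum pairs in a cohort")
  wt <- wilcoxon_rank_sum(ja, jb)
  list(statistic = wt$statistic, p_value = wt$p_value,
       n_pairs_a = length(ja), n_pairs_b = length(jb),
       median_a = stats::median(ja), median_b = stats::median(jb))
}

#' Write a network's edge list as TSV and the graph as GraphML
#'
#' @param network a `cooccurrence_network`.
#' @param edges_path TSV output path for the edge list.
#' @param graphml_path optional GraphML output path.
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(network, edges_path, graphml_path = NULL) {
  stopifnot(inherits(network, "cooccurrence_network"))
  utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- network$graph
    if (nrow(network$edges)) {
      igraph::E(g)$sign <- network$edges$sign
      igraph::E(g)$jaccard <- network$edges$jaccard
      igraph::E(g)$strength <- network$edges$strength
      igraph::V(g)$phylum <- network$nodes$phylum[
        match(igraph::V(g)$name, network$nodes$genus)]
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edges_path)
}
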