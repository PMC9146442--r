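#' Shannon diversity of one sample
#'
#' `H = -sum p_i log(p_i)` over taxa with positive abundance. Works on raw
#' counts or relative abundances (internally normalized). Natural log by
#' default; the base is a parameter and is recorded on the result.
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon entropy, with attribute `log_base`.
#' @export
shannon <- function(x, base = exp(1)) {
  check_abundance_vector(x)
  h <- unname(vegan::diversity(rbind(x), index = "shannon", base = base))
  structure(h, log_base = base)
}

#' Gini-Simpson diversity of one sample
#'
#' `D = 1 - sum p_i^2`. The Simpson dominance `sum p_i^2` is attached as an
#' attribute.
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @return Gini-Simpson index in `[0, 1)`, attribute `dominance`.
#' @export
simpson <- function(x) {
  check_abundance_vector(x)
  d <- unname(vegan::diversity(rbind(x), index = "simpson"))
  structure(d, dominance = 1 - d)
}

#' Chao1 richness estimate of one sample
#'
#' Classic estimator `S_obs + F1^2 / (2 F2)` where `F1`/`F2` are singleton
#' and doubleton counts; when `F2 = 0` the fallback `S_obs + F1 (F1 - 1) / 2`
#' is used. The bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is
#' available behind a flag.
#'
#' @param x integer count vector.
#' @param bias_corrected use the bias-corrected estimator.
#' @return estimate with attributes `s_obs`, `f1`, `f2`.
#' @export
chao1 <- function(x, bias_corrected = FALSE) {
  check_abundance_vector(x)
  if (any(abs(x - round(x)) > 1e-8))
    stop("chao1 requires integer counts (singletons undefined otherwise)")
  x <- round(x)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  est <- if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
         else if (f2 > 0)    s_obs + f1^2 / (2 * f2)
         else                s_obs + f1 * (f1 - 1) / 2
  structure(est, s_obs = s_obs, f1 = f1, f2 = f2)
}

check_abundance_vector <- function(x) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x < 0))
    stop("abundances must be finite and non-negative")
  if (all(x == 0)) stop("all-zero abundance vector")
  invisible(x)
}

#' Per-sample alpha diversity table
#'
#' @param table an `abundance_table` in counts mode (Chao1 needs counts).
#' @param base Shannon log base.
#' @return data.frame: `sample_id`, `shannon`, `simpson`, `dominance`,
#'   `chao1`, `s_obs`, `f1`, `f2`, plus a `log_base` attribute.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "counts") stop("alpha_diversity requires counts mode")
  rows <- lapply(seq_len(nrow(table$values)), function(i) {
    x <- table$values[i, ]
    ch <- chao1(x)
    data.frame(sample_id = rownames(table$values)[i],
               shannon = as.numeric(shannon(x, base = base)),
               simpson = as.numeric(simpson(x)),
               dominance = sum((x / sum(x))^2),
               chao1 = as.numeric(ch),
               s_obs = attr(ch, "s_obs"), f1 = attr(ch, "f1"),
               f2 = attr(ch, "f2"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "log_base") <- base
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = 1 - 2 sum min(u_i, v_i) / (sum u + sum v)`, computed on the
#' table's values as given (counts or relative).
#'
#' @param table an `abundance_table` with positive sample totals.
#' @return a `dist_matrix`: symmetric numeric matrix with zero diagonal and
#'   sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  tot <- rowSums(table$values)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(rownames(table$values)[tot == 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(table$values, method = "bray"))
  dist_matrix(d)
}

#' Construct a validated distance matrix
#' @param m square symmetric numeric matrix with zero diagonal and dimnames.
#' @return object of class `dist_matrix` (a plain matrix underneath).
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix needs sample ids")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix needs a zero diagonal")
  colnames(m) <- rownames(m)
  structure(m, class = c("dist_matrix", "matrix"))
}

#' Principal coordinates analysis
#'
#' Classical scaling (Gower double-centering of `-d^2/2` followed by an
#' eigendecomposition). Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues are reported
#' but excluded from the coordinates and from the proportion-explained
#' denominator.
#'
#' @param dist a `dist_matrix`.
#' @return list with `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, non-increasing), `proportion_explained` (per positive axis).
#' @export
pcoa_ordination <- function(dist) {
  if (!inherits(dist, "dist_matrix")) dist <- dist_matrix(dist)
  n <- nrow(dist)
  # negative eigenvalues (non-Euclidean dissimilarities) are expected and
  # handled below, so cmdscale's warning about them is muted
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dist), k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1)
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  rownames(coords) <- rownames(dist)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  prop <- eig[seq_len(ncol(coords))] / sum(eig[eig > 0])
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all `M = n(n-1)/2` pairwise dissimilarities (average ranks on ties)
#' and contrasts mean between-group against mean within-group rank:
#' `R = (mean_rank_between - mean_rank_within) / (M / 2)`. Significance is
#' one-sided (large `R`) by permuting group labels: when the number of
#' distinct label arrangements is at most 10,000 all arrangements are
#' enumerated (the observed labeling included), otherwise `B` random
#' permutations give `p = (1 + #{R_perm >= R_obs}) / (B + 1)`.
#'
#' @param dist a `dist_matrix`.
#' @param grouping group label per sample (at least 2 groups, each of size
#'   at least 2).
#' @param B number of random permutations when enumeration is infeasible.
#' @param seed RNG seed for the permutations (recorded in the result).
#' @return list of class `anosim_result`: `R`, `p_value`, `B` (permutations
#'   actually used), `exhaustive`, `seed`, `perm_R` (null statistics).
#' @export
anosim_test <- function(dist, grouping, B = 999, seed = NULL) {
  if (!inherits(dist, "dist_matrix")) dist <- dist_matrix(dist)
  n <- nrow(dist)
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping length must match the matrix")
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("ANOSIM needs at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  dvec <- stats::as.dist(dist)
  r <- rank(dvec)             # average ranks on ties
  M <- length(r)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  R_of <- function(lab) {
    within <- lab[pair_i] == lab[pair_j]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R_obs <- R_of(grouping)
  n_arr <- n_label_arrangements(grouping)
  if (n_arr <= 10000) {
    perms <- enumerate_label_arrangements(grouping)
    perm_R <- vapply(perms, R_of, numeric(1))
    p <- mean(perm_R >= R_obs - 1e-12)
    B_used <- length(perm_R)
    exhaustive <- TRUE
  } else {
    perm_R <- with_seed(seed, {
      vapply(seq_len(B), function(b) R_of(sample(grouping)), numeric(1))
    })
    p <- (1 + sum(perm_R >= R_obs - 1e-12)) / (B + 1)
    B_used <- B
    exhaustive <- FALSE
  }
  structure(list(R = R_obs, p_value = p, B = B_used,
                 exhaustive = exhaustive, seed = seed, perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d arrangements)\n", x$R,
              x$p_value, if (x$exhaustive) "exhaustive" else "sampled", x$B))
  invisible(x)
}

# All distinct assignments of a label multiset to positions.
enumerate_label_arrangements <- function(labels) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  counts <- as.integer(table(factor(labels, levels = uniq)))
  n <- length(labels)
  out <- list()
  rec <- function(assigned, remaining) {
    if (length(assigned) == n) {
      out[[length(out) + 1L]] <<- assigned
      return(invisible())
    }
    for (g in seq_along(uniq)) if (remaining[g] > 0L) {
      remaining[g] <- remaining[g] - 1L
      rec(c(assigned, uniq[g]), remaining)
      remaining[g] <- remaining[g] + 1L
    }
  }
  rec(character(0), counts)
  out
}
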