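#' Spearman rank correlation
#'
#' Pearson correlation of average ranks.
#'
#' @param x,y numeric vectors of equal length >= 3, each with >= 2 distinct
#'   values.
#' @return rho in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("spearman is undefined for a constant vector")
  stats::cor(rank(x), rank(y))
}

#' Permutation p-value for a Spearman correlation
#'
#' Two-sided: the proportion of label shuffles whose `|rho|` reaches the
#' observed `|rho|`. When `n! <= 10000` (n <= 7) all permutations are
#' enumerated and the p-value is exact; otherwise `B` random shuffles give
#' `p = (1 + #{|rho_perm| >= |rho_obs|}) / (B + 1)`.
#'
#' @param x,y as in [spearman()].
#' @param B number of random shuffles (default 5000).
#' @param seed RNG seed.
#' @return list: `rho`, `p_value`, `B` (shuffles used), `exhaustive`, `seed`.
#' @export
permutation_pvalue <- function(x, y, B = 5000, seed = NULL) {
  if (B < 1) stop("B must be at least 1")
  rho <- spearman(x, y)
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (factorial(n) <= 10000) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, B = nrow(perms), exhaustive = TRUE,
         seed = seed)
  } else {
    count <- with_seed(seed, {
      sum(vapply(seq_len(B),
                 function(b) abs(stats::cor(rx, ry[sample.int(n)])),
                 numeric(1)) >= abs(rho) - 1e-12)
    })
    list(rho = rho, p_value = (1 + count) / (B + 1), B = B,
         exhaustive = FALSE, seed = seed)
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values vector of p-values in (0, 1].
#' @param fdr target false discovery rate (default 0.05).
#' @return list: `q_values` (monotone BH-adjusted), `reject` (`q <= fdr`).
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector")
  stopifnot_scalar_prob(fdr, "fdr")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= fdr)
}

#' Covariate-adjusted partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and every covariate, projects the ranks of `x`
#' and `y` onto the covariate ranks (plus intercept) by least squares, and
#' correlates the residuals. The p-value uses the t approximation with
#' `n - k - 2` degrees of freedom (`k` covariates); with no covariates this
#' reduces to the plain Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame (binary covariates coded
#'   0/1), or `NULL`.
#' @return list: `rho`, `p_value`, `df`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  k <- 0L
  rx <- rank(x)
  ry <- rank(y)
  if (!is.null(covariates)) {
    cz <- as.matrix(covariates)
    if (nrow(cz) != n) stop("covariates must match x in length")
    if (any(apply(cz, 2, function(v) length(unique(v)) < 2)))
      stop("constant covariate column")
    k <- ncol(cz)
    if (n <= k + 2) stop("need n > #covariates + 2")
    Z <- cbind(1, apply(cz, 2, rank))
    if (qr(Z)$rank < ncol(Z)) stop("rank-deficient covariates")
    rx <- stats::lm.fit(Z, rx)$residuals
    ry <- stats::lm.fit(Z, ry)$residuals
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("degenerate ranks after projection")
  rho <- stats::cor(rx, ry)
  df <- n - k - 2
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(rho = rho, p_value = min(p, 1), df = df, n = n)
}

#' Taxa x clinical-variable association grid
#'
#' Screens every (taxon, variable) pair with Spearman correlation. Without
#' covariates the p-values come from a permutation test that shuffles the
#' clinical variable `B` times (vectorized across taxa); with
#' `adjust_for` set, covariate-adjusted partial Spearman correlations with
#' analytic t p-values are used instead. One BH family spans the whole grid.
#' Missing metadata values are handled by pairwise-complete deletion; cells
#' with fewer than 10 complete pairs are flagged and excluded from the BH
#' family.
#'
#' @param table `abundance_table` in relative mode.
#' @param metadata data.frame with `sample_id` plus the listed variables,
#'   aligned to the table's samples.
#' @param variables character vector of metadata columns to screen.
#' @param B permutation count (default 5000).
#' @param fdr BH false discovery rate (default 0.05).
#' @param adjust_for optional character vector of metadata columns used as
#'   covariates (e.g. `c("age", "sex", "bmi")`).
#' @param seed RNG seed, recorded on the result.
#' @return long data.frame of class `association_matrix`: `taxon`,
#'   `variable`, `rho`, `p_value`, `q_value`, `n_pairs`, `significant`;
#'   attributes `B`, `fdr`, `seed`, `adjust_for`.
#' @export
association_grid <- function(table, metadata, variables, B = 5000,
                             fdr = 0.05, adjust_for = NULL, seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative") stop("association_grid requires relative mode")
  if (!"sample_id" %in% names(metadata)) stop("metadata needs 'sample_id'")
  missing_v <- setdiff(c(variables, adjust_for), names(metadata))
  if (length(missing_v)) stop("metadata lacks: ", paste(missing_v, collapse = ", "))
  idx <- match(sample_ids(table), metadata$sample_id)
  if (any(is.na(idx))) stop("metadata is missing samples present in the table")
  meta <- metadata[idx, , drop = FALSE]
  taxa <- taxon_ids(table)
  cells <- with_seed(seed, {
    do.call(rbind, lapply(variables, function(v) {
      grid_column(table, meta, v, B, adjust_for)
    }))
  })
  ok <- !is.na(cells$p_value)
  cells$q_value <- NA_real_
  if (any(ok)) cells$q_value[ok] <- bh_adjust(cells$p_value[ok], fdr)$q_values
  cells$significant <- !is.na(cells$q_value) & cells$q_value <= fdr
  attr(cells, "B") <- B
  attr(cells, "fdr") <- fdr
  attr(cells, "seed") <- seed
  attr(cells, "adjust_for") <- adjust_for
  class(cells) <- c("association_matrix", "data.frame")
  cells
}

# one variable's column of the grid; assumes RNG already seeded
grid_column <- function(table, meta, v, B, adjust_for) {
  taxa <- taxon_ids(table)
  y <- meta[[v]]
  keep <- !is.na(y)
  if (!is.null(adjust_for))
    for (a in adjust_for) keep <- keep & !is.na(meta[[a]])
  n <- sum(keep)
  blank <- data.frame(taxon = taxa, variable = v, rho = NA_real_,
                      p_value = NA_real_, n_pairs = n,
                      stringsAsFactors = FALSE)
  if (n < 10) return(blank)
  X <- table$values[keep, , drop = FALSE]
  yv <- y[keep]
  if (length(unique(yv)) < 2) return(blank)
  const_taxa <- apply(X, 2, function(col) length(unique(col)) < 2)
  if (!is.null(adjust_for)) {
    cz <- as.matrix(meta[keep, adjust_for, drop = FALSE])
    res <- lapply(which(!const_taxa), function(j)
      partial_spearman(X[, j], yv, cz))
    blank$rho[!const_taxa] <- vapply(res, `[[`, numeric(1), "rho")
    blank$p_value[!const_taxa] <- vapply(res, `[[`, numeric(1), "p_value")
    return(blank)
  }
  # vectorized permutation Spearman: correlate standardized rank matrices
  Xr <- scale(apply(X[, !const_taxa, drop = FALSE], 2, rank))
  yr <- as.vector(scale(rank(yv)))
  rho_obs <- as.vector(crossprod(Xr, yr)) / (n - 1)
  Yperm <- vapply(seq_len(B), function(b) yr[sample.int(n)],
                  numeric(n))
  rho_perm <- crossprod(Xr, Yperm) / (n - 1)       # taxa x B
  exceed <- rowSums(abs(rho_perm) >= abs(rho_obs) - 1e-12)
  blank$rho[!const_taxa] <- rho_obs
  blank$p_value[!const_taxa] <- (1 + exceed) / (B + 1)
  blank
}

#' Canonical correlation analysis between two variable blocks
#'
#' Standardizes both blocks and computes canonical correlations and weight
#' vectors (via the QR-based solution of the whitened cross-covariance
#' problem), ordered by decreasing correlation, together with the Wilks'
#' lambda significance chain from [wilks_test()].
#'
#' @param X,Y numeric matrices/data.frames with the same rows (samples);
#'   requires `n > p + q + 1` and no constant columns.
#' @return list of class `cca_result`: `correlations`, `x_weights`,
#'   `y_weights`, `wilks` (data.frame from [wilks_test()]), `n`, `p`, `q`.
#' @export
cca_blocks <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("blocks must share samples")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n <= p + q + 1) stop("need n > p + q + 1")
  if (any(apply(X, 2, stats::sd) == 0) || any(apply(Y, 2, stats::sd) == 0))
    stop("constant column in a block")
  Xs <- scale(X); Ys <- scale(Y)
  fit <- stats::cancor(Xs, Ys)
  r <- pmin(pmax(fit$cor, 0), 1)
  structure(list(correlations = r, x_weights = fit$xcoef,
                 y_weights = fit$ycoef,
                 wilks = wilks_test(r, n, p, q), n = n, p = p, q = q),
            class = "cca_result")
}

#' Wilks' lambda chain for canonical correlations
#'
#' For component `k`, `Lambda_k = prod_{i >= k} (1 - r_i^2)` tests that the
#' k-th and all later canonical correlations are zero, using Bartlett's
#' chi-square approximation
#' `-(n - 1 - (p + q + 1) / 2) log(Lambda_k)` on `(p - k + 1)(q - k + 1)`
#' degrees of freedom.
#'
#' @param r canonical correlations in `[0, 1]`, non-increasing.
#' @param n sample size; `p`, `q` block widths.
#' @param p,q numbers of variables in the two blocks.
#' @return data.frame: `component`, `lambda`, `chi_sq`, `df`, `p_value`,
#'   `degenerate` (`TRUE` where some `r = 1` forces `Lambda = 0`).
#' @export
wilks_test <- function(r, n, p, q) {
  if (any(r < 0 | r > 1)) stop("canonical correlations must lie in [0, 1]")
  s <- length(r)
  scale_f <- n - 1 - (p + q + 1) / 2
  out <- lapply(seq_len(s), function(k) {
    lam <- prod(1 - r[k:s]^2)
    degen <- any(r[k:s] >= 1)
    chi <- if (degen) Inf else -scale_f * log(lam)
    df <- (p - k + 1) * (q - k + 1)
    data.frame(component = k, lambda = lam, chi_sq = chi, df = df,
               p_value = if (degen) 0 else
                 stats::pchisq(chi, df, lower.tail = FALSE),
               degenerate = degen)
  })
  do.call(rbind, out)
}

#' @export
print.cca_result <- function(x, ...) {
  cat("Canonical correlation analysis:", x$p, "x", x$q, "variables, n =",
      x$n, "\n")
  print(data.frame(r = round(x$correlations, 4),
                   round(x$wilks[c("lambda", "chi_sq", "df", "p_value")], 4)))
  invisible(x)
}
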