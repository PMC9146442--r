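test_that("spearman matches rank-Pearson and its closed cases", {
  expect_equal(spearman(1:6, c(2, 4, 9, 11, 30, 31)), 1)
  expect_equal(spearman(1:6, rev(1:6)), -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # invariance under strictly monotone transforms
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman(exp(x), y^3 + 5 * y), spearman(x, y),
               tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("permutation p-values are exact for small n and reproducible", {
  # perfectly monotone, n = 7: only the two signed identities reach |rho|=1
  res <- permutation_pvalue(1:7, c(3, 5, 8, 9, 12, 20, 44))
  expect_true(res$exhaustive)
  expect_equal(res$p_value, 2 / 5040)
  # exhaustive result equals the independent full-enumeration oracle
  set.seed(10)
  for (n in c(5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(permutation_pvalue(x, y)$p_value,
                 bruteforce_spearman_perm(x, y), tolerance = 1e-12)
  }
  # sampled branch: same seed, same answer
  x <- rnorm(20); y <- rnorm(20)
  p1 <- permutation_pvalue(x, y, B = 299, seed = 5)
  p2 <- permutation_pvalue(x, y, B = 299, seed = 5)
  expect_false(p1$exhaustive)
  expect_identical(p1$p_value, p2$p_value)
  expect_error(permutation_pvalue(x, y, B = 0), "at least 1")
})

test_that("permutation p-values are uniform under independence", {
  set.seed(61)
  hits <- vapply(seq_len(500), function(i) {
    permutation_pvalue(rnorm(12), rnorm(12), B = 399)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("benjamini-hochberg step-up behaves as specified", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.5), fdr = 0.05)
  expect_equal(sum(r$reject), 3)
  expect_equal(sum(bh_adjust(rep(1, 6))$reject), 0)
  one <- bh_adjust(0.04)
  expect_equal(one$q_values, 0.04)
  expect_true(one$reject)
  expect_error(bh_adjust(numeric(0)), "empty")
  # BH never rejects fewer than Bonferroni at the same level
  set.seed(9)
  for (i in 1:20) {
    p <- runif(25)^2
    bh <- sum(bh_adjust(p, 0.05)$reject)
    bonf <- sum(p <= 0.05 / length(p))
    expect_gte(bh, bonf)
  }
})

test_that("partial spearman removes covariate-driven association", {
  set.seed(14)
  x <- rnorm(50); y <- rnorm(50)
  # no covariates: identical to plain spearman
  expect_equal(partial_spearman(x, y)$rho, spearman(x, y), tolerance = 1e-12)
  # y equal to a covariate: residual correlation vanishes
  cv <- rnorm(200)
  ps <- partial_spearman(rnorm(200), cv + rnorm(200, sd = 1e-6),
                         covariates = cbind(cv))
  expect_lt(abs(ps$rho), 0.1)
  # x and y linked only through a covariate: adjusted rho is attenuated
  atten <- vapply(seq_len(100), function(s) {
    set.seed(s)
    c0 <- rnorm(80)
    x0 <- c0 + rnorm(80); y0 <- c0 + rnorm(80)
    abs(partial_spearman(x0, y0, covariates = cbind(c0))$rho) <
      abs(spearman(x0, y0))
  }, logical(1))
  expect_gte(mean(atten), 0.95)
  expect_error(partial_spearman(x, y, covariates = cbind(rep(1, 50))),
               "constant covariate")
  expect_error(partial_spearman(x, y, covariates = cbind(x, x)),
               "rank-deficient")
})

test_that("association grid finds a planted correlation without flooding nulls", {
  spec <- default_spec()
  outcomes <- vapply(seq_len(20), function(s) {
    st <- generate_cohort(spec, "obese", 5000 + s)
    gen <- to_relative(filter_rare(collapse_taxa(st$table, "genus"), 0.001))
    keep <- unique(c("Bifidobacterium", taxon_ids(gen)[1:10]))
    sub <- abundance_table(gen$values[, keep, drop = FALSE] /
                             rowSums(gen$values[, keep, drop = FALSE]),
                           gen$taxonomy[match(keep, gen$taxonomy$taxon_id), ],
                           mode = "relative")
    grid <- association_grid(sub, st$metadata,
                             variables = c("hdl_c", "age", "sbp"),
                             B = 2000, seed = s)
    hit <- grid$significant[grid$taxon == "Bifidobacterium" &
                              grid$variable == "hdl_c"]
    null_cells <- grid[!(grid$taxon == "Bifidobacterium" &
                           grid$variable == "hdl_c"), ]
    c(hit = hit, null_ok = mean(!null_cells$significant) >= 0.9)
  }, logical(2))
  expect_gte(mean(outcomes["hit", ]), 0.9)
  expect_gte(mean(outcomes["null_ok", ]), 0.9)
})

test_that("association grid output carries signs, pair counts and metadata", {
  spec <- default_spec()
  st <- generate_cohort(spec, "obese", 321)
  gen <- to_relative(filter_rare(collapse_taxa(st$table, "genus"), 0.001))
  meta <- st$metadata
  meta$hdl_c[1:8] <- NA    # pairwise-complete deletion
  grid <- association_grid(gen, meta, variables = c("hdl_c", "age"),
                           B = 200, seed = 2)
  expect_s3_class(grid, "association_matrix")
  expect_equal(nrow(grid), 2 * ncol(gen$values))
  expect_equal(unique(grid$n_pairs[grid$variable == "hdl_c"]),
               nrow(gen$values) - 8)
  # planted positive link carries a positive rho
  expect_gt(grid$rho[grid$taxon == "Bifidobacterium" &
                       grid$variable == "hdl_c"], 0)
  # cells with < 10 complete pairs are flagged and excluded from BH
  meta$age[-(1:5)] <- NA
  grid2 <- association_grid(gen, meta, variables = c("hdl_c", "age"),
                            B = 200, seed = 2)
  age_cells <- grid2[grid2$variable == "age", ]
  expect_true(all(is.na(age_cells$p_value)))
  expect_true(all(!age_cells$significant))
})

test_that("cca recovers definitional and degenerate geometries", {
  set.seed(18)
  x <- rnorm(60); y <- 0.6 * x + rnorm(60)
  fit <- cca_blocks(cbind(x), cbind(y))
  expect_equal(fit$correlations, abs(cor(x, y)), tolerance = 1e-10)
  # invertible transform of the same block: all canonical correlations 1
  X <- matrix(rnorm(150), 50, 3)
  A <- matrix(c(2, 0.5, 0, 1, 3, 0.2, 0, 1, 1), 3, 3)
  fit2 <- cca_blocks(X, X %*% A)
  expect_equal(fit2$correlations, rep(1, 3), tolerance = 1e-8)
  # invariance to invertible affine transforms
  Y <- matrix(rnorm(100), 50, 2)
  r0 <- cca_blocks(X, Y)$correlations
  B2 <- matrix(c(1, 0.3, -0.5, 2), 2, 2)
  r1 <- cca_blocks(sweep(X %*% A, 2, c(1, -2, 3), `+`),
                   sweep(Y %*% B2, 2, c(5, 1), `+`))$correlations
  expect_equal(r0, r1, tolerance = 1e-8)
  expect_error(cca_blocks(cbind(rep(1, 50)), Y), "constant")
  expect_error(cca_blocks(X[1:5, ], Y[1:5, ]), "n > p")
})

test_that("a planted canonical pair near 0.64 is recovered", {
  # one shared latent links x1 and y1: cor(x1, y1) = 1 / (1 + s^2) = 0.64
  s <- sqrt(1 / 0.64 - 1)
  recovered <- vapply(seq_len(50), function(sd) {
    set.seed(sd)
    u <- rnorm(164)
    X <- cbind(u + rnorm(164, sd = s), matrix(rnorm(164 * 4), 164))
    Y <- cbind(u + rnorm(164, sd = s), matrix(rnorm(164 * 2), 164))
    r1 <- cca_blocks(X, Y)$correlations[1]
    abs(r1 - 0.64) <= 0.10
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("wilks lambda chain matches its closed form", {
  w0 <- wilks_test(c(0, 0), n = 40, p = 2, q = 2)
  expect_equal(w0$lambda, c(1, 1))
  expect_equal(w0$chi_sq, c(0, 0))
  expect_equal(w0$p_value, c(1, 1))
  w1 <- wilks_test(0.5, n = 50, p = 1, q = 1)
  expect_equal(w1$lambda, 0.75)
  expect_equal(w1$chi_sq, -47.5 * log(0.75), tolerance = 1e-12)
  expect_equal(w1$df, 1)
  # lambda is non-decreasing in the component index
  r <- c(0.9, 0.6, 0.3, 0.1)
  wl <- wilks_test(r, n = 100, p = 4, q = 5)
  expect_true(all(diff(wl$lambda) >= 0))
  # degenerate r = 1 flagged with p = 0
  wd <- wilks_test(c(1, 0.2), n = 30, p = 2, q = 2)
  expect_true(wd$degenerate[1])
  expect_equal(wd$p_value[1], 0)
  expect_equal(wd$lambda[1], 0)
})
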