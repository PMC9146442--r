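test_that("wilcoxon rank-sum matches exact enumeration and handles shifts", {
  res <- wilcoxon_rank_sum(1:3, 4:6)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)       # 2 of C(6,3)=20 arrangements
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  # arrangement-enumeration oracle on tie-free draws
  set.seed(8)
  for (sizes in list(c(5, 5), c(6, 4), c(8, 8))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2], 0.5)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, bruteforce_wilcoxon(x, y),
                 tolerance = 1e-12)
  }
  # strongly shifted large groups are detected
  set.seed(42)
  big <- wilcoxon_rank_sum(rnorm(164, 1), rnorm(45, 0))
  expect_lt(big$p_value, 0.001)
  expect_false(big$exact)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("wilcoxon type-I error is nominal under the null", {
  set.seed(123)
  rejections <- vapply(seq_len(2000), function(i) {
    wilcoxon_rank_sum(rnorm(20), rnorm(20))$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("per-taxon screen flags only the shifted taxon and tracks direction", {
  tab <- toy_table()
  rel <- to_relative(tab)
  id <- per_taxon_group_test(rel, rel)
  expect_true(all(id$p_value >= 0.99))
  # direction matches the sign of the median difference
  set.seed(15)
  a <- random_counts_table(n = 10, m = 6, seed = 15)
  b <- random_counts_table(n = 12, m = 6, seed = 16)
  res <- per_taxon_group_test(to_relative(a), to_relative(b))
  ra <- to_relative(a)$values; rb <- to_relative(b)$values
  for (i in seq_len(nrow(res))) {
    dm <- median(ra[, res$taxon[i]]) - median(rb[, res$taxon[i]])
    want <- if (dm > 0) "a" else if (dm < 0) "b" else "none"
    expect_equal(res$direction[i], want)
  }
  # invariance to sample ordering
  perm <- sample(nrow(a$values))
  a2 <- subset_samples(a, perm)
  expect_equal(per_taxon_group_test(to_relative(a2), to_relative(b))$p_value,
               res$p_value)
  # mismatched taxa are reported
  expect_error(per_taxon_group_test(rel, to_relative(a)), "taxon sets differ")
})

test_that("a planted 4x phylum shift is the only BH discovery", {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Fusobacteria")
  base_pm <- c(0.35, 0.30, 0.20, 0.10, 0.05)
  names(base_pm) <- phyla
  genera <- data.frame(genus = paste0(phyla, "_g"), phylum = phyla,
                       weight = 1)
  hits <- vapply(seq_len(50), function(s) {
    spec <- cohort_spec(
      cohorts = list(a = list(n = 50, phylum_means = base_pm),
                     b = list(n = 50, phylum_means = base_pm)),
      genera = genera, concentration = 80, depth_median = 5000,
      zi_cap = 1, zi_intercept = 50,   # no zero inflation
      planted_diff = data.frame(genus = "Actinobacteria_g", fold = 4,
                                cohort = "a"))
    pair <- generate_paired_study(spec, s)
    cmb <- bind_cohorts(pair$a$table, pair$b$table, "phylum")
    rel_a <- to_relative(subset_samples(cmb$table, cmb$grouping == "a"))
    rel_b <- to_relative(subset_samples(cmb$table, cmb$grouping == "b"))
    res <- per_taxon_group_test(rel_a, rel_b, adjust = "BH")
    sig <- res$taxon[res$q_value < 0.05]
    ("Actinobacteria" %in% sig)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ancom couples both taxa at m = 2 and respects its W threshold", {
  set.seed(77)
  vals <- cbind(g1 = rpois(20, 50), g2 = rpois(20, 50))
  rownames(vals) <- paste0("s", 1:20)
  tab <- abundance_table(vals, data.frame(taxon_id = c("g1", "g2"),
                                          kingdom = "Bacteria",
                                          phylum = "Firmicutes",
                                          genus = c("g1", "g2")),
                         mode = "counts")
  res <- ancom(tab, rep(c("a", "b"), each = 10))
  expect_equal(res$W[1], res$W[2])
  expect_true(all(res$W %in% 0:1))
  expect_true(all(res$reject == (res$W >= attr(res, "w_threshold"))))
  expect_error(ancom(tab, rep("a", 20)), "2 groups")
})

test_that("ancom W is invariant to per-sample scaling", {
  tab <- random_counts_table(n = 14, m = 8, seed = 31)
  grp <- rep(c("a", "b"), each = 7)
  # log-ratio cancellation: multiplying a sample's counts by a constant
  # leaves every pairwise log-ratio unchanged (up to the pseudocount, which
  # is negligible at large counts), so W must not move
  tab3 <- abundance_table(tab$values * 1000, tab$taxonomy, mode = "counts")
  tab4 <- abundance_table(tab$values * 5000, tab$taxonomy, mode = "counts")
  expect_equal(ancom(tab3, grp)$W, ancom(tab4, grp)$W)
})

test_that("ancom detects a planted 8x taxon and controls the null", {
  genera <- data.frame(genus = sprintf("g%02d", 1:10), phylum = "Firmicutes",
                       weight = 1)
  pm <- c(Firmicutes = 1)
  hits <- vapply(seq_len(50), function(s) {
    spec <- cohort_spec(
      cohorts = list(a = list(n = 50, phylum_means = pm),
                     b = list(n = 50, phylum_means = pm)),
      genera = genera, concentration = 60, depth_median = 5000,
      zi_cap = 1, zi_intercept = 50,
      planted_diff = data.frame(genus = "g03", fold = 8, cohort = "a"))
    pair <- generate_paired_study(spec, s)
    cmb <- bind_cohorts(pair$a$table, pair$b$table, "genus")
    res <- ancom(cmb$table, cmb$grouping)
    res$reject[res$taxon == "g03"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # identical distributions: per-taxon rejection rate within nominal error
  rej <- vapply(seq_len(100), function(s) {
    spec <- cohort_spec(
      cohorts = list(a = list(n = 25, phylum_means = pm),
                     b = list(n = 25, phylum_means = pm)),
      genera = genera, concentration = 60, depth_median = 5000,
      zi_cap = 1, zi_intercept = 50)
    pair <- generate_paired_study(spec, 1000 + s)
    cmb <- bind_cohorts(pair$a$table, pair$b$table, "genus")
    ancom(cmb$table, cmb$grouping)$reject
  }, logical(10))
  expect_lte(max(rowMeans(rej)), 0.05)
})

test_that("F/B ratio computes per sample and flags zero denominators", {
  vals <- rbind(s1 = c(50, 25), s2 = c(30, 0))
  colnames(vals) <- c("Firmicutes", "Bacteroidetes")
  tax <- data.frame(taxon_id = colnames(vals), kingdom = "Bacteria",
                    phylum = colnames(vals))
  tab <- abundance_table(vals, tax, "counts")
  fb <- fb_ratio(tab)
  expect_equal(fb$fb_ratio[1], 2)
  expect_true(is.na(fb$fb_ratio[2]) && !fb$defined[2])
  # cohort comparison runs on the defined values only
  cmp <- wilcoxon_rank_sum(fb$fb_ratio[fb$defined], c(1.5, 2.5))
  expect_true(is.finite(cmp$p_value))
  bad <- abundance_table(vals[, 1, drop = FALSE],
                         tax[1, , drop = FALSE], "counts")
  expect_error(fb_ratio(bad), "Bacteroidetes")
})
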