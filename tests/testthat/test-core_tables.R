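test_that("feature-table TSV round-trips counts and parses lineages", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#Constructed from biom file",
    paste("#OTU ID", "s1", "s2", "taxonomy", sep = "\t"),
    paste("otu1", 3, 1,
          "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Lactobacillus",
          sep = "\t"),
    paste("otu2", 4, 0, "Bacteria;Firmicutes;Clostridia;Eubacteriales;Lachnospiraceae;Blautia",
          sep = "\t"),
    paste("otu3", 5, 2, "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Prevotellaceae",
          sep = "\t")), tsv)
  tab <- read_feature_table(tsv)
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(tab$mode, "counts")
  expect_equal(unname(tab$values["s1", ]), c(3, 4, 5))
  expect_equal(unname(tab$values["s2", ]), c(1, 0, 2))
  # prefixed and plain dialects both yield the genus name
  expect_equal(tab$taxonomy$genus[1:2], c("Lactobacillus", "Blautia"))
  # lineage truncated at family leaves genus unassigned
  expect_true(is.na(tab$taxonomy$genus[3]))
  expect_equal(tab$taxonomy$family[3], "Prevotellaceae")
  # write -> read reproduces counts exactly
  out <- tempfile(fileext = ".tsv")
  write_feature_table(tab, out)
  back <- read_feature_table(out)
  expect_identical(back$values, tab$values)
  expect_identical(back$taxonomy$genus, tab$taxonomy$genus)
})

test_that("taxa-in-columns orientation is auto-detected", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("sample_id", "Bacteria;Firmicutes;Clostridia;Eubacteriales;Lachnospiraceae;Blautia",
          "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides",
          sep = "\t"),
    paste("s1", 7, 2, sep = "\t"),
    paste("s2", 0, 9, sep = "\t")), tsv)
  tab <- read_feature_table(tsv)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(tab$taxonomy$genus, c("Blautia", "Bacteroides"))
  expect_equal(unname(tab$values[, 1]), c(7, 0))
})

test_that("relative tables round-trip through TSV to 1e-12", {
  rel <- to_relative(toy_table())
  out <- tempfile(fileext = ".tsv")
  write_feature_table(rel, out)
  back <- read_feature_table(out)
  expect_equal(back$mode, "relative")
  expect_equal(back$values, rel$values, tolerance = 1e-12)
})

test_that("malformed tables are rejected", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste("id", "s1", "taxonomy", sep = "\t"),
               paste("o1", -3, "Bacteria;Firmicutes", sep = "\t")), tsv)
  expect_error(read_feature_table(tsv), "negative")
  vals <- rbind(s1 = c(1, 2))
  colnames(vals) <- c("a", "a")
  expect_error(abundance_table(vals, data.frame(taxon_id = c("a", "a")),
                               "counts"), "duplicate taxon")
})

test_that("uncultured and empty lineage tokens are unassigned and propagate", {
  lin <- parse_lineage(c(
    "Bacteria;Firmicutes;Clostridia;Eubacteriales;uncultured;Blautia",
    "k__Bacteria; p__; c__Bacilli"))
  # unassigned family forces genus unassigned
  expect_true(is.na(lin$family[1]) && is.na(lin$genus[1]))
  # unassigned phylum wipes everything below
  expect_true(is.na(lin$phylum[2]) && is.na(lin$class[2]))
  expect_equal(lin$kingdom[2], "Bacteria")
})

test_that("collapse_taxa sums counts, drops rank-unassigned taxa, keeps them higher up", {
  vals <- rbind(s1 = c(3, 4, 2), s2 = c(1, 1, 1))
  colnames(vals) <- c("o1", "o2", "o3")
  tax <- data.frame(taxon_id = c("o1", "o2", "o3"), kingdom = "Bacteria",
                    phylum = c("Firmicutes", "Firmicutes", "Firmicutes"),
                    class = c("Clostridia", "Clostridia", "Clostridia"),
                    order = c("Eubacteriales", "Eubacteriales", "Eubacteriales"),
                    family = c("Lachnospiraceae", "Lachnospiraceae",
                               "Lachnospiraceae"),
                    genus = c("Blautia", "Blautia", NA))
  tab <- abundance_table(vals, tax, "counts")
  phy <- collapse_taxa(tab, "phylum")
  expect_equal(unname(phy$values[, "Firmicutes"]), c(9, 3))  # 3+4+2
  gen <- collapse_taxa(tab, "genus")
  # genus-unassigned OTU is present at phylum level, absent at genus level
  expect_equal(taxon_ids(gen), "Blautia")
  expect_equal(unname(gen$values[, "Blautia"]), c(7, 2))
  expect_error(collapse_taxa(tab, "kingdom"), "rank")
})

test_that("collapsing never increases per-sample totals", {
  tab <- random_counts_table(n = 6, m = 40, seed = 11)
  tab$taxonomy$genus[c(3, 9, 17)] <- NA    # some unassigned genera
  before <- rowSums(tab$values)
  after <- rowSums(collapse_taxa(tab, "genus")$values)
  # direct summation oracle: totals over assigned columns only
  oracle <- rowSums(tab$values[, !is.na(tab$taxonomy$genus), drop = FALSE])
  expect_true(all(after <= before))
  expect_equal(unname(after), unname(oracle))
})

test_that("to_relative normalizes rows and flags empty samples", {
  tab <- toy_table(values = rbind(s1 = c(2, 2, 0), s2 = c(1, 0, 3)))
  rel <- to_relative(tab)
  expect_equal(unname(rel$values["s1", ]), c(0.5, 0.5, 0))
  expect_equal(unname(rel$values["s2", ]), c(0.25, 0, 0.75))
  expect_true(all(abs(rowSums(rel$values) - 1) <= 1e-9))
  bad <- toy_table(values = rbind(s1 = c(1, 1, 1), s2 = c(0, 0, 0)))
  expect_error(to_relative(bad), "s2")
})

test_that("collapse then normalize commutes with normalize then group-sum", {
  tab <- random_counts_table(n = 7, m = 30, seed = 5)
  a <- to_relative(collapse_taxa(tab, "phylum"))$values
  rel <- to_relative(tab)$values
  phyla <- tab$taxonomy$phylum
  b <- sapply(colnames(a), function(ph) rowSums(rel[, phyla == ph, drop = FALSE]))
  expect_equal(a, b[, colnames(a)], tolerance = 1e-12)
})

test_that("rare filter keeps the boundary, matches brute-force means, is idempotent", {
  # means 0.0005 / 0.001 / 0.9985 -> boundary taxon kept
  vals <- rbind(s1 = c(5, 10, 9985), s2 = c(5, 10, 9985))
  tab <- toy_table(values = vals)
  filt <- filter_rare(tab, 0.001)
  expect_equal(taxon_ids(filt), c("Lactobacillus", "Bacteroides"))
  # threshold 0 keeps everything
  expect_equal(ncol(filter_rare(tab, 0)$values), 3L)
  expect_error(filter_rare(tab, 1), "min_mean_relative")
  # brute-force recomputation of per-taxon mean relative abundance
  rnd <- random_counts_table(n = 9, m = 20, seed = 3)
  thr <- 0.02
  kept <- taxon_ids(filter_rare(rnd, thr))
  man <- colMeans(rnd$values / rowSums(rnd$values))
  expect_identical(kept, names(man)[man >= thr])
  # idempotence
  once <- filter_rare(rnd, thr)
  twice <- filter_rare(once, thr)
  expect_identical(taxon_ids(once), taxon_ids(twice))
  expect_identical(once$values, twice$values)
})

test_that("clinical derivations follow the standard formulas", {
  meta <- data.frame(sample_id = "p1", weight = 65.25, height = 150,
                     fm = 29, fi = 14.5, fpg = 82.6)
  out <- derive_clinical(meta)
  expect_equal(out$bmi, 65.25 / 1.5^2)
  expect_equal(out$fmi, 12.888889, tolerance = 1e-6)
  expect_equal(out$ffmi, (65.25 - 29) / 1.5^2)
  # HOMA-IR with mg/dL glucose converted by /18
  expect_equal(out$homa_ir, 14.5 * (82.6 / 18) / 22.5)
  expect_equal(round(out$homa_ir, 1), 3.0)
  expect_equal(homa_ir(0, 90), 0)
  expect_equal(homa_ir(10, 5, fpg_unit = "mmol/L"), 10 * 5 / 22.5)
  expect_error(derive_clinical(transform(meta, height = 0)), "height")
  expect_error(derive_clinical(transform(meta, fi = -1)), "negative")
})
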