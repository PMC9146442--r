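Package: gutcohort
Title: Gut Microbiome Cohort Comparison and Cooccurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for comparing gut-microbiome cohorts from
    16S feature tables: taxonomy collapsing and rare-taxon filtering, alpha
    diversity (Shannon, Gini-Simpson, Chao1), Bray-Curtis beta diversity with
    PCoA and ANOSIM, per-taxon Wilcoxon screens and ANCOM compositional
    differential abundance, Firmicutes/Bacteroidetes ratios, taxon-clinical
    association grids (permutation Spearman with Benjamini-Hochberg FDR,
    covariate-adjusted partial Spearman, canonical correlation with Wilks'
    lambda), and presence/absence cooccurrence networks (Jaccard index,
    hypergeometric copresence/exclusion tests, Bonferroni control, clustering
    coefficient against a random-graph null). Includes a synthetic cohort
    generator with plantable cooccurrence, differential-abundance and
    correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
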