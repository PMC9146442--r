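#' Combine two cohorts at a taxonomic rank
#'
#' Collapses both tables to `rank` and stacks them over the union of taxon
#' names (absent taxa zero-filled), returning the combined counts table and
#' the cohort label per sample.
#'
#' @param table_a,table_b counts-mode `abundance_table`s.
#' @param rank collapse rank.
#' @param labels length-2 character labels for the cohorts.
#' @return list: `table` (combined counts `abundance_table`), `grouping`
#'   (label per sample).
#' @export
bind_cohorts <- function(table_a, table_b, rank,
                         labels = c("a", "b")) {
  ca <- collapse_taxa(table_a, rank)
  cb <- collapse_taxa(table_b, rank)
  taxa <- union(taxon_ids(ca), taxon_ids(cb))
  fill <- function(tb) {
    m <- matrix(0, nrow(tb$values), length(taxa),
                dimnames = list(rownames(tb$values), taxa))
    m[, taxon_ids(tb)] <- tb$values
    m
  }
  tax <- rbind(ca$taxonomy, cb$taxonomy)
  tax <- tax[!duplicated(tax$taxon_id), , drop = FALSE]
  tax <- tax[match(taxa, tax$taxon_id), , drop = FALSE]
  comb <- abundance_table(rbind(fill(ca), fill(cb)), tax, mode = "counts")
  list(table = comb,
       grouping = rep(labels, c(nrow(ca$values), nrow(cb$values))))
}

#' Pipeline configuration
#'
#' @param table,metadata input TSV paths for the primary cohort (ignored in
#'   simulate mode).
#' @param table_b optional feature table of a reference cohort; two-cohort
#'   analyses (ANOSIM, per-taxon tests, ANCOM, network contrast) need it.
#' @param simulate generate the cohorts with [generate_paired_study()]
#'   instead of reading files.
#' @param spec `cohort_spec` used in simulate mode (default
#'   [default_spec()]).
#' @param ranks taxonomic ranks analysed (default phylum + genus).
#' @param min_mean_rel rare-genus filter threshold for the network.
#' @param alpha Bonferroni-adjusted edge cutoff.
#' @param fdr association-grid BH level.
#' @param assoc_B association permutation count.
#' @param anosim_B ANOSIM permutation count.
#' @param null_R number of random networks for the clustering null.
#' @param variables metadata variables screened in the association grid
#'   (default: all clinical template variables present).
#' @param adjust_for optional covariates for partial Spearman.
#' @param cca_groups named list of variable groups for CCA against the
#'   phylum relative abundances.
#' @param out_dir output directory.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(table = NULL, metadata = NULL, table_b = NULL,
                            simulate = is.null(table), spec = NULL,
                            ranks = c("phylum", "genus"),
                            min_mean_rel = 0.001, alpha = 0.05, fdr = 0.05,
                            assoc_B = 5000, anosim_B = 999, null_R = 10000,
                            variables = NULL, adjust_for = NULL,
                            cca_groups = list(
                              metabolic = c("fpg", "tg", "hdl_c", "ldl_c",
                                            "alt"),
                              lifestyle = c("screen_weekday",
                                            "screen_weekend", "sedentary",
                                            "exercise")),
                            out_dir = "gutcohort_out", seed = 1L) {
  stopifnot(all(ranks %in% TAXONOMY_RANKS[-1]))
  structure(list(table = table, metadata = metadata, table_b = table_b,
                 simulate = simulate, spec = spec, ranks = ranks,
                 min_mean_rel = min_mean_rel, alpha = alpha, fdr = fdr,
                 assoc_B = assoc_B, anosim_B = anosim_B, null_R = null_R,
                 variables = variables, adjust_for = adjust_for,
                 cca_groups = cca_groups, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full cohort-comparison pipeline
#'
#' Executes, in order: taxonomy collapsing and relative abundance, alpha
#' diversity, Bray-Curtis + PCoA + ANOSIM per rank (when two cohorts are
#' available), per-taxon Wilcoxon screens and ANCOM, the F/B ratio,
#' the taxon-clinical association grid and CCA with Wilks' lambda, and the
#' cooccurrence network with its random-graph clustering null. All
#' artifacts are written under `config$out_dir` together with a JSON run
#' manifest recording seeds, thresholds and filtering counts.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package = "gutcohort",
                   version = as.character(utils::packageVersion("gutcohort")),
                   seed = config$seed,
                   thresholds = config[c("min_mean_rel", "alpha", "fdr",
                                         "assoc_B", "anosim_B", "null_R")],
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # ---- inputs -------------------------------------------------------------
  if (config$simulate) {
    spec <- config$spec %||% default_spec()
    pair <- stage("simulate", generate_paired_study(spec, config$seed))
    study_a <- pair[[1]]; study_b <- pair[[2]]
    for (s in pair) write_cohort(s, out("inputs"))
    tab_a <- study_a$table; meta_a <- study_a$metadata
    tab_b <- study_b$table
    labels <- c(study_a$label, study_b$label)
  } else {
    tab_a <- stage("read", read_feature_table(config$table))
    meta_a <- if (!is.null(config$metadata))
      derive_clinical(read_metadata(config$metadata)) else NULL
    tab_b <- if (!is.null(config$table_b))
      read_feature_table(config$table_b) else NULL
    labels <- c("cohort_a", "cohort_b")
  }
  two <- !is.null(tab_b)
  # ---- per-rank diversity and composition --------------------------------
  for (rank in config$ranks) {
    coll_a <- stage("collapse", collapse_taxa(tab_a, rank))
    manifest$stages[[paste0("collapse_", rank)]] <-
      list(taxa_a = ncol(coll_a$values))
    utils::write.table(
      alpha_diversity(coll_a),
      out(paste0("alpha_", labels[1], "_", rank, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (two) {
      comb <- stage("bind", bind_cohorts(tab_a, tab_b, rank, labels))
      rel <- to_relative(comb$table)
      bc <- stage("bray_curtis", bray_curtis_matrix(rel))
      utils::write.table(as.data.frame(unclass(bc)),
                         out(paste0("bray_", rank, ".tsv")),
                         sep = "\t", quote = FALSE)
      ord <- stage("pcoa", pcoa_ordination(bc))
      utils::write.table(
        data.frame(sample_id = rownames(ord$coordinates),
                   cohort = comb$grouping, ord$coordinates),
        out(paste0("pcoa_", rank, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(eigenvalues = ord$eigenvalues,
             proportion_explained = ord$proportion_explained),
        out(paste0("pcoa_", rank, "_eig.json")), digits = NA)
      an_seed <- derive_seed(config$seed, match(rank, config$ranks) + 10)
      an <- stage("anosim",
                  anosim_test(bc, comb$grouping, B = config$anosim_B,
                              seed = an_seed))
      jsonlite::write_json(
        list(R = an$R, p_value = an$p_value, B = an$B,
             exhaustive = an$exhaustive, seed = an_seed),
        out(paste0("anosim_", rank, ".json")), auto_unbox = TRUE,
        digits = NA)
      gt <- stage("group_test", {
        rel_a <- to_relative(subset_samples(comb$table,
                                            comb$grouping == labels[1]))
        rel_b <- to_relative(subset_samples(comb$table,
                                            comb$grouping == labels[2]))
        per_taxon_group_test(rel_a, rel_b, adjust = "BH")
      })
      utils::write.table(gt, out(paste0("group_test_", rank, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      anc <- stage("ancom", ancom(comb$table, comb$grouping))
      utils::write.table(anc, out(paste0("ancom_", rank, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  # ---- F/B ratio ----------------------------------------------------------
  phy_a <- collapse_taxa(tab_a, "phylum")
  if (all(c("Firmicutes", "Bacteroidetes") %in% taxon_ids(phy_a))) {
    fb <- stage("fb_ratio", fb_ratio(phy_a))
    utils::write.table(fb, out("fb_ratio.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  # ---- associations -------------------------------------------------------
  if (!is.null(meta_a)) {
    gen_a <- to_relative(filter_rare(collapse_taxa(tab_a, "genus"),
                                     config$min_mean_rel))
    vars <- config$variables %||%
      intersect(clinical_template()$variable, names(meta_a))
    vars <- setdiff(vars, config$adjust_for)
    as_seed <- derive_seed(config$seed, 20)
    grid <- stage("association",
                  association_grid(gen_a, meta_a, vars, B = config$assoc_B,
                                   fdr = config$fdr,
                                   adjust_for = config$adjust_for,
                                   seed = as_seed))
    utils::write.table(as.data.frame(grid), out("association_genus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$association <- list(seed = as_seed,
                                        cells = nrow(grid))
    rel_phy <- to_relative(phy_a)
    cca_out <- list()
    for (grp in names(config$cca_groups)) {
      gv <- intersect(config$cca_groups[[grp]], names(meta_a))
      ok <- length(gv) >= 2 &&
        all(!vapply(meta_a[gv], function(v) any(is.na(v)), logical(1)))
      if (!ok) next
      fit <- stage(paste0("cca_", grp),
                   cca_blocks(rel_phy$values, as.matrix(meta_a[gv])))
      cca_out[[grp]] <- list(variables = gv,
                             correlations = fit$correlations,
                             wilks = fit$wilks)
    }
    jsonlite::write_json(cca_out, out("cca.json"), digits = NA,
                         dataframe = "columns")
  }
  # ---- cooccurrence networks ----------------------------------------------
  tabs <- list(tab_a, if (two) tab_b)
  for (i in seq_len(1 + two)) {
    lab <- labels[i]
    gen <- collapse_taxa(tabs[[i]], "genus")
    before <- ncol(gen$values)
    net <- stage(paste0("network_", lab),
                 build_network(gen, min_mean_rel = config$min_mean_rel,
                               alpha = config$alpha))
    write_network(net, out(paste0("network_", lab, "_edges.tsv")),
                  out(paste0("network_", lab, ".graphml")))
    manifest$stages[[paste0("network_", lab)]] <-
      list(genera_before_filter = before,
           genera_after_filter = net$n_genera_tested,
           n_tests = net$n_tests, n_edges = nrow(net$edges),
           n_nodes = nrow(net$nodes), clustering = net$clustering)
    if (nrow(net$nodes) >= 3 && nrow(net$edges) >= 1) {
      nn_seed <- derive_seed(config$seed, 30 + i)
      nn <- stage(paste0("null_test_", lab),
                  null_network_test(net, R = config$null_R, seed = nn_seed))
      jsonlite::write_json(
        list(C_obs = nn$C_obs, p_value = nn$p_value, R = nn$R,
             null_model = nn$null_model, seed = nn_seed),
        out(paste0("null_test_", lab, ".json")), auto_unbox = TRUE,
        digits = NA)
      manifest$stages[[paste0("null_test_", lab)]] <-
        list(p_value = nn$p_value, seed = nn_seed)
    }
  }
  if (two) {
    ipc <- lapply(c("Firmicutes", "Bacteroidetes"), function(ph) {
      tryCatch(
        c(list(phylum = ph),
          intra_phylum_comparison(collapse_taxa(tab_a, "genus"),
                                  collapse_taxa(tab_b, "genus"), ph,
                                  min_mean_rel = config$min_mean_rel)),
        error = function(e) list(phylum = ph,
                                 error = conditionMessage(e)))
    })
    jsonlite::write_json(ipc, out("intra_phylum.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Subset an abundance table to selected samples
#' @param table an `abundance_table`.
#' @param keep logical or character vector of samples.
#' @return the subset `abundance_table`.
#' @export
subset_samples <- function(table, keep) {
  stopifnot(inherits(table, "abundance_table"))
  abundance_table(table$values[keep, , drop = FALSE], table$taxonomy,
                  mode = table$mode)
}
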