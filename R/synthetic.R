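#' Specification of a synthetic two-cohort microbiome study
#'
#' Low-level constructor for the parameter object consumed by
#' [generate_cohort()]. Most users want [default_spec()], which instantiates
#' the pediatric obesity study conditions; this constructor exists so small
#' custom designs (fewer taxa, different sample sizes, planted effects) can
#' be built for focused simulations.
#'
#' @param cohorts named list; each element a list with `n` (samples) and
#'   `phylum_means` (named numeric summing to 1 after renormalization).
#' @param genera data.frame with `genus`, `phylum`, `weight` (share of the
#'   genus within its phylum's budget; weights are normalized per phylum).
#' @param concentration Dirichlet concentration of per-sample genus
#'   compositions around the cohort template (larger = less dispersion).
#' @param depth_median,depth_sdlog log-normal sequencing depth parameters.
#' @param zi_intercept,zi_slope,zi_cap presence probability of a genus is
#'   `min(zi_cap, plogis(zi_intercept + zi_slope * log10(template_mean)))`,
#'   a monotone zero-inflation curve (rarer genera are absent more often).
#' @param planted_pairs data.frame(`genus_a`, `genus_b`, `rho`, `cohort`):
#'   latent (tetrachoric) presence correlations planted per cohort.
#' @param planted_diff data.frame(`genus`, `fold`, `cohort`): multiplicative
#'   fold changes applied to the cohort template before renormalization.
#' @param planted_assoc data.frame(`genus`, `variable`, `rho`, `cohort`):
#'   target Spearman correlations between a genus's relative abundance and
#'   a clinical variable.
#' @param clinical_marginals data.frame(`variable`, `dist`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `prob`, `floor`) describing each variable's
#'   marginal (`normal`, `lognormal_q` matched to median/Q3, `bernoulli`).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohorts, genera, concentration = 50,
                        depth_median = 20000, depth_sdlog = 0.4,
                        zi_intercept = 4.37, zi_slope = 1.49, zi_cap = 0.98,
                        planted_pairs = NULL, planted_diff = NULL,
                        planted_assoc = NULL, clinical_marginals = NULL) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1, is.data.frame(genera))
  for (nm in names(cohorts)) {
    pm <- cohorts[[nm]]$phylum_means
    if (any(pm < 0) || sum(pm) <= 0) stop("invalid phylum means for ", nm)
    cohorts[[nm]]$phylum_means <- pm / sum(pm)
  }
  if (anyDuplicated(genera$genus)) stop("duplicate genus names")
  if (!is.null(planted_pairs) && nrow(planted_pairs) &&
      any(abs(planted_pairs$rho) >= 1))
    stop("planted latent correlations must satisfy |rho| < 1")
  if (!is.null(planted_diff) && nrow(planted_diff) &&
      any(planted_diff$fold <= 0))
    stop("planted fold changes must be positive")
  structure(list(cohorts = cohorts, genera = genera,
                 concentration = concentration,
                 depth_median = depth_median, depth_sdlog = depth_sdlog,
                 zi_intercept = zi_intercept, zi_slope = zi_slope,
                 zi_cap = zi_cap,
                 planted_pairs = planted_pairs %||% empty_pairs(),
                 planted_diff = planted_diff %||% empty_diff(),
                 planted_assoc = planted_assoc %||% empty_assoc(),
                 clinical_marginals = clinical_marginals %||%
                   table1_marginals()),
            class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
empty_pairs <- function() data.frame(genus_a = character(0),
                                     genus_b = character(0),
                                     rho = numeric(0), cohort = character(0))
empty_diff <- function() data.frame(genus = character(0), fold = numeric(0),
                                    cohort = character(0))
empty_assoc <- function() data.frame(genus = character(0),
                                     variable = character(0),
                                     rho = numeric(0), cohort = character(0))

#' Clinical marginal distributions of the obese cohort template
#'
#' Means/SDs (or median and quartiles for the skewed activity variables)
#' of the anthropometric, dietary, activity and fasting blood-chemistry
#' variables used by the synthetic generator. Screen-time marginals are
#' artificial placeholders with plausible pediatric values.
#'
#' @return data.frame usable as `clinical_marginals` in [cohort_spec()].
#' @export
table1_marginals <- function() {
  nrm <- function(v, m, s, floor = -Inf)
    data.frame(variable = v, dist = "normal", mean = m, sd = s,
               median = NA, q1 = NA, q3 = NA, prob = NA, floor = floor)
  lnq <- function(v, med, q1, q3)
    data.frame(variable = v, dist = "lognormal_q", mean = NA, sd = NA,
               median = med, q1 = q1, q3 = q3, prob = NA, floor = 0)
  brn <- function(v, p)
    data.frame(variable = v, dist = "bernoulli", mean = NA, sd = NA,
               median = NA, q1 = NA, q3 = NA, prob = p, floor = NA)
  rbind(
    nrm("age", 10.4, 2.2, floor = 7),
    brn("sex", 0.59),
    nrm("height", 145, 10, floor = 110),
    nrm("bmi_z", 3.2, 1),
    nrm("waist", 89.7, 10.7, floor = 50),
    nrm("sbp", 116, 10, floor = 80),
    brn("acanthosis", 0.80),
    nrm("fmi", 11.8, 2.9, floor = 3),
    nrm("ffmi", 16.1, 2.1, floor = 8),
    nrm("body_fat_pct", 41.7, 5.5, floor = 15),
    nrm("trunk_fmi", 5.7, 1.4, floor = 1),
    nrm("vfa", 129.4, 40.3, floor = 20),
    nrm("energy", 1450, 537.9, floor = 400),
    nrm("fiber", 2.8, 2, floor = 0),
    nrm("fat_pct", 36, 6, floor = 10),
    lnq("screen_weekday", 3, 2, 5),
    lnq("screen_weekend", 5, 3, 8),
    lnq("sedentary", 4, 2, 7),
    lnq("exercise", 60, 5.5, 150),
    nrm("tc", 189.6, 31.7, floor = 80),
    nrm("ldl_c", 128.9, 31.6, floor = 30),
    nrm("hdl_c", 51.2, 9.6, floor = 15),
    nrm("tg", 101.6, 41.8, floor = 20),
    nrm("alt", 30.4, 24.9, floor = 5),
    nrm("fpg", 82.6, 5.9, floor = 55),
    nrm("fi", 14.5, 13.4, floor = 0.5))
}

#' Default synthetic study specification
#'
#' Instantiates the study conditions the pipeline is validated against: an
#' obese cohort of 164 children with phylum means Firmicutes 47.1%,
#' Bacteroidetes 34.4%, Proteobacteria 14.0%, Actinobacteria 2.4%,
#' Fusobacteria 1.0%, and a nonobese cohort of 45 with Firmicutes and
#' Bacteroidetes both 46.0%, Actinobacteria 5.2%, Proteobacteria 2.7%,
#' Fusobacteria 0.8% (renormalized to sum to one). A 70-genus catalogue is
#' spread across the five phyla with per-phylum Dirichlet weights (drawn
#' once from a fixed catalogue seed; a handful of anchor genera carry real
#' names, the rest are explicitly artificial `<Phylum>_gNN` placeholders).
#' By default the obese cohort carries 10 planted copresence pairs at
#' latent correlation 0.8 among mid-abundance genera and one planted
#' Bifidobacterium ~ HDL-C Spearman correlation of 0.4; the nonobese cohort
#' carries no planted structure.
#'
#' @param n_obese,n_nonobese cohort sizes.
#' @param n_pairs number of planted copresence pairs in the obese cohort.
#' @param pair_rho latent correlation of planted pairs.
#' @param assoc_rho target Spearman correlation of the planted
#'   Bifidobacterium ~ HDL-C link (set `n_pairs = 0` and `assoc_rho = 0`
#'   for a fully null generator).
#' @param catalogue_seed seed fixing the genus catalogue weights.
#' @return a `cohort_spec`.
#' @export
default_spec <- function(n_obese = 164, n_nonobese = 45, n_pairs = 10,
                         pair_rho = 0.8, assoc_rho = 0.4,
                         catalogue_seed = 20170801) {
  obese_pm <- c(Firmicutes = 0.471, Bacteroidetes = 0.344,
                Proteobacteria = 0.140, Actinobacteria = 0.024,
                Fusobacteria = 0.010)
  nonobese_pm <- c(Firmicutes = 0.460, Bacteroidetes = 0.460,
                   Actinobacteria = 0.052, Proteobacteria = 0.027,
                   Fusobacteria = 0.008)
  anchors <- list(
    Firmicutes = c("Blautia", "Faecalibacterium", "Lactobacillus",
                   "Agathobacter", "Anaerostipes", "Roseburia"),
    Bacteroidetes = c("Bacteroides", "Prevotella", "Alistipes"),
    Proteobacteria = c("Escherichia", "Sutterella"),
    Actinobacteria = c("Bifidobacterium", "Collinsella"),
    Fusobacteria = "Fusobacterium")
  n_per <- c(Firmicutes = 40, Bacteroidetes = 14, Proteobacteria = 8,
             Actinobacteria = 5, Fusobacteria = 3)
  genera <- with_seed(catalogue_seed, {
    do.call(rbind, lapply(names(n_per), function(ph) {
      k <- n_per[[ph]]
      w <- sort(rgamma(k, shape = 1), decreasing = TRUE)
      w <- w / sum(w)
      nm <- c(anchors[[ph]], sprintf("%s_g%02d", ph,
                                     seq_len(k - length(anchors[[ph]]))))
      data.frame(genus = nm, phylum = ph, weight = w,
                 stringsAsFactors = FALSE)
    }))
  })
  spec <- cohort_spec(
    cohorts = list(obese = list(n = n_obese, phylum_means = obese_pm),
                   nonobese = list(n = n_nonobese,
                                   phylum_means = nonobese_pm)),
    genera = genera)
  if (n_pairs > 0) {
    tmpl <- genus_template(spec, "obese")
    cand <- names(tmpl)[tmpl >= 0.004 & tmpl <= 0.05]
    cand <- setdiff(cand, "Bifidobacterium")
    cand <- cand[order(tmpl[cand], decreasing = TRUE)]
    if (length(cand) < 2 * n_pairs)
      stop("catalogue has too few mid-abundance genera for ", n_pairs,
           " planted pairs")
    sel <- cand[seq_len(2 * n_pairs)]
    spec$planted_pairs <- data.frame(
      genus_a = sel[seq(1, 2 * n_pairs, 2)],
      genus_b = sel[seq(2, 2 * n_pairs, 2)],
      rho = pair_rho, cohort = "obese", stringsAsFactors = FALSE)
  }
  if (assoc_rho != 0)
    spec$planted_assoc <- data.frame(genus = "Bifidobacterium",
                                     variable = "hdl_c", rho = assoc_rho,
                                     cohort = "obese",
                                     stringsAsFactors = FALSE)
  spec
}

# Cohort's genus-level template means (phylum budget x in-phylum weight),
# with planted fold changes applied and renormalized.
genus_template <- function(spec, cohort) {
  pm <- spec$cohorts[[cohort]]$phylum_means
  g <- spec$genera
  w <- g$weight
  for (ph in unique(g$phylum)) {
    sel <- g$phylum == ph
    w[sel] <- w[sel] / sum(w[sel])
  }
  tmpl <- ifelse(g$phylum %in% names(pm), pm[g$phylum], 0) * w
  names(tmpl) <- g$genus
  pd <- spec$planted_diff
  pd <- pd[pd$cohort == cohort, , drop = FALSE]
  if (nrow(pd)) {
    idx <- match(pd$genus, names(tmpl))
    if (any(is.na(idx))) stop("planted_diff names unknown genera")
    tmpl[idx] <- tmpl[idx] * pd$fold
  }
  tmpl / sum(tmpl)
}

presence_probs <- function(spec, tmpl) {
  p <- stats::plogis(spec$zi_intercept + spec$zi_slope * log10(pmax(tmpl, 1e-8)))
  pmin(spec$zi_cap, p)
}

#' Generate one synthetic cohort
#'
#' Per sample: sequencing depth is drawn log-normally; genus proportions
#' come from a Dirichlet around the cohort template (planted fold changes
#' applied first); presence/absence is overlaid by thresholding correlated
#' latent Gaussians (a Gaussian copula, so planted pairs achieve their
#' tetrachoric correlation); counts are multinomial at the drawn depth on
#' the presence-masked, renormalized proportions. Clinical variables are
#' drawn from the spec's marginals through a Gaussian copula; planted
#' taxon links tie a variable's latent to the normal scores of the genus's
#' relative abundance at `2 sin(pi rho / 6)` latent correlation (the
#' bivariate-normal inverse of the target Spearman rho).
#'
#' @param spec a `cohort_spec`.
#' @param cohort cohort name in `spec$cohorts`.
#' @param seed RNG seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @return list of class `cohort_study`: `label`, `table` (counts
#'   `abundance_table`), `metadata` (data.frame incl. derived indices),
#'   `truth` (a `synthetic_truth` list).
#' @export
generate_cohort <- function(spec, cohort, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!cohort %in% names(spec$cohorts))
    stop("unknown cohort '", cohort, "'")
  with_seed(seed, {
    n <- spec$cohorts[[cohort]]$n
    m <- nrow(spec$genera)
    tmpl <- genus_template(spec, cohort)
    depth <- pmax(1000, round(stats::rlnorm(n, log(spec$depth_median),
                                            spec$depth_sdlog)))
    p_pres_cal <- presence_probs(spec, tmpl)
    # calibrate the Dirichlet template for presence masking so the expected
    # observed composition (and hence the phylum sums) matches the template
    tmpl_adj <- (tmpl / p_pres_cal) / sum(tmpl / p_pres_cal)
    alpha <- spec$concentration * tmpl_adj
    props <- matrix(stats::rgamma(n * m, shape = rep(alpha, each = n)),
                    n, m)
    props <- props / rowSums(props)
    p_pres <- presence_probs(spec, tmpl)
    pp <- spec$planted_pairs
    pp <- pp[pp$cohort == cohort, , drop = FALSE]
    Sigma <- diag(m)
    if (nrow(pp)) {
      ia <- match(pp$genus_a, spec$genera$genus)
      ib <- match(pp$genus_b, spec$genera$genus)
      if (any(is.na(ia)) || any(is.na(ib)))
        stop("planted_pairs name unknown genera")
      Sigma[cbind(ia, ib)] <- Sigma[cbind(ib, ia)] <- pp$rho
    }
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) {
      warning("planted correlation matrix not positive definite; ",
              "applying nearest-PD repair")
      Sigma <- as.matrix(Matrix::nearPD(Sigma, corr = TRUE)$mat)
      R <- tryCatch(chol(Sigma), error = function(e)
        stop("infeasible planted correlations for pairs: ",
             paste(pp$genus_a, pp$genus_b, sep = "~", collapse = ", ")))
    }
    Z <- matrix(stats::rnorm(n * m), n, m) %*% R
    present <- sweep(Z, 2, stats::qnorm(p_pres), `<=`)
    # a sample must keep at least its most abundant genus
    none <- rowSums(present) == 0
    if (any(none)) present[none, which.max(tmpl)] <- TRUE
    masked <- props * present
    empty <- rowSums(masked) == 0
    if (any(empty)) masked[cbind(which(empty), which.max(tmpl))] <- 1
    masked <- masked / rowSums(masked)
    counts <- vapply(seq_len(n), function(i)
      stats::rmultinom(1, depth[i], masked[i, ])[, 1], numeric(m))
    counts <- t(counts)
    ids <- sprintf("%s_%03d", toupper(substr(cohort, 1, 2)), seq_len(n))
    dimnames(counts) <- list(ids, spec$genera$genus)
    # intermediate ranks get synthetic placeholder names so that the
    # "unassigned propagates downwards" invariant keeps the genus names
    tax <- data.frame(taxon_id = spec$genera$genus, kingdom = "Bacteria",
                      phylum = spec$genera$phylum,
                      class = paste0(spec$genera$phylum, "_class"),
                      order = paste0(spec$genera$phylum, "_order"),
                      family = paste0(spec$genera$genus, "_family"),
                      genus = spec$genera$genus, stringsAsFactors = FALSE)
    table <- abundance_table(counts, tax, mode = "counts")
    meta <- generate_clinical(spec, cohort, table, ids)
    truth <- structure(list(
      cohort = cohort, seed = seed,
      planted_pairs = pp,
      planted_diff = spec$planted_diff[
        spec$planted_diff$cohort == cohort, , drop = FALSE],
      planted_assoc = spec$planted_assoc[
        spec$planted_assoc$cohort == cohort, , drop = FALSE],
      template = as.list(tmpl), presence_prob = as.list(p_pres),
      depth = depth), class = "synthetic_truth")
    structure(list(label = cohort, table = table, metadata = meta,
                   truth = truth), class = "cohort_study")
  })
}

# clinical variables via Gaussian copula; assumes RNG already seeded
generate_clinical <- function(spec, cohort, table, ids) {
  n <- length(ids)
  marg <- spec$clinical_marginals
  pa <- spec$planted_assoc
  pa <- pa[pa$cohort == cohort, , drop = FALSE]
  rel <- to_relative(table)$values
  meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(marg))) {
    v <- marg$variable[i]
    z <- stats::rnorm(n)
    hit <- which(pa$variable == v)
    if (length(hit)) {
      g <- pa$genus[hit[1]]
      if (!g %in% colnames(rel)) stop("planted_assoc names unknown genus ", g)
      zt <- stats::qnorm((rank(rel[, g]) - 0.5) / n)
      rl <- 2 * sin(pi * pa$rho[hit[1]] / 6)   # Spearman -> latent Pearson
      z <- rl * zt + sqrt(1 - rl^2) * z
    }
    u <- stats::pnorm(z)
    val <- switch(marg$dist[i],
      normal = stats::qnorm(u, marg$mean[i], marg$sd[i]),
      lognormal_q = {
        med <- marg$median[i]
        sdlog <- if (!is.na(marg$q3[i]) && marg$q3[i] > med)
          log(marg$q3[i] / med) / stats::qnorm(0.75) else 0.5
        stats::qlnorm(u, log(med), sdlog)
      },
      bernoulli = as.numeric(u < marg$prob[i]),
      stop("unknown marginal distribution ", marg$dist[i]))
    if (!is.na(marg$floor[i]) && is.finite(marg$floor[i]))
      val <- pmax(marg$floor[i], val)
    meta[[v]] <- val
  }
  if (all(c("fmi", "ffmi", "height") %in% names(meta))) {
    h2 <- (meta$height / 100)^2
    meta$fm <- meta$fmi * h2
    meta$weight <- (meta$fmi + meta$ffmi) * h2
  }
  derive_clinical(meta)
}

#' Generate the paired obese / nonobese study
#'
#' Draws the two cohorts from seeds derived from a master seed. Under
#' [default_spec()] the obese cohort carries the planted cooccurrence and
#' taxon-clinical structure while the nonobese cohort carries none.
#'
#' @param spec a `cohort_spec` with both cohorts.
#' @param seed master seed.
#' @return named list of two `cohort_study` objects (`obese`, `nonobese`).
#' @export
generate_paired_study <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  labs <- names(spec$cohorts)
  out <- lapply(seq_along(labs), function(i)
    generate_cohort(spec, labs[i], derive_seed(seed, i)))
  names(out) <- labs
  out
}

#' Write / read the planted-truth object as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON path.
#' @return `path` invisibly; [read_truth()] returns the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("planted_pairs", "planted_diff", "planted_assoc"))
    x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  structure(x, class = "synthetic_truth")
}

#' Write a generated cohort to disk in the pipeline's input formats
#'
#' @param study a `cohort_study`.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_cohort <- function(study, dir) {
  stopifnot(inherits(study, "cohort_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table = file.path(dir, paste0(study$label, "_feature_table.tsv")),
    metadata = file.path(dir, paste0(study$label, "_metadata.tsv")),
    truth = file.path(dir, paste0(study$label, "_truth.json")))
  write_feature_table(study$table, paths["table"])
  write_metadata(study$metadata, paths["metadata"])
  write_truth(study$truth, paths["truth"])
  paths
}
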