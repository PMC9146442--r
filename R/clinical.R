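#' Clinical variable template
#'
#' The per-sample variables the pipeline expects for a pediatric obesity
#' cohort: anthropometry, body composition (bioelectrical impedance), dietary
#' intake, activity, and fasting blood chemistry. Used to validate metadata
#' and to drive the synthetic generator's marginals.
#'
#' @return data.frame with columns `variable`, `type`
#'   (`continuous`/`binary`/`ordinal`) and `unit`.
#' @export
clinical_template <- function() {
  data.frame(
    variable = c("age", "sex", "weight", "height", "bmi_z", "waist", "sbp",
                 "acanthosis", "fm", "fmi", "ffmi", "body_fat_pct",
                 "trunk_fmi", "vfa", "energy", "fiber", "fat_pct",
                 "screen_weekday", "screen_weekend", "sedentary", "exercise",
                 "tc", "ldl_c", "hdl_c", "tg", "alt", "fpg", "fi", "homa_ir"),
    type = c("continuous", "binary", "continuous", "continuous", "continuous",
             "continuous", "continuous", "binary", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous", "continuous"),
    unit = c("yr", "0/1 (1 = male)", "kg", "cm", "z", "cm", "mmHg", "0/1",
             "kg", "kg/m2", "kg/m2", "%", "kg/m2", "cm2", "kcal/d",
             "g/1000 kcal", "% of energy", "h/d", "h/d", "h/d", "min/wk",
             "mg/dL", "mg/dL", "mg/dL", "mg/dL", "U/L", "mg/dL", "mU/L", ""),
    stringsAsFactors = FALSE)
}

#' Read per-sample clinical metadata from TSV
#'
#' @param path TSV with a header row and a `sample_id` key column.
#' @return data.frame with `sample_id` first.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a 'sample_id' column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df[, c("sample_id", setdiff(names(df), "sample_id"))]
}

#' Write clinical metadata to TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive anthropometric and metabolic indices
#'
#' Adds (or overwrites) four standard derived columns:
#' \itemize{
#'   \item `bmi` = weight (kg) / height (m)^2
#'   \item `fmi` = fat mass (kg) / height (m)^2
#'   \item `ffmi` = (weight - fat mass) (kg) / height (m)^2
#'   \item `homa_ir` = fasting insulin (mU/L) x fasting glucose (mmol/L) /
#'     22.5, with glucose supplied in mg/dL and converted by /18.0
#' }
#' Columns are only derived when their source columns are present; all other
#' columns pass through untouched.
#'
#' @param meta data.frame with `height` (cm) and any of `weight` (kg), `fm`
#'   (fat mass, kg), `fi` (mU/L), `fpg` (mg/dL).
#' @return `meta` with the derived columns appended.
#' @export
derive_clinical <- function(meta) {
  stopifnot(is.data.frame(meta))
  if (any(c("weight", "fm") %in% names(meta))) {
    if (!"height" %in% names(meta)) stop("height (cm) required to derive indices")
    h <- meta$height / 100
    if (any(!is.na(h) & h <= 0)) stop("non-positive height")
    if ("weight" %in% names(meta)) meta$bmi <- meta$weight / h^2
    if ("fm" %in% names(meta)) {
      meta$fmi <- meta$fm / h^2
      if ("weight" %in% names(meta)) meta$ffmi <- (meta$weight - meta$fm) / h^2
    }
  }
  if (all(c("fi", "fpg") %in% names(meta))) {
    if (any(!is.na(meta$fi) & meta$fi < 0) ||
        any(!is.na(meta$fpg) & meta$fpg < 0))
      stop("negative fasting insulin or glucose")
    meta$homa_ir <- homa_ir(meta$fi, meta$fpg)
  }
  meta
}

#' Homeostatic model assessment of insulin resistance
#'
#' `HOMA-IR = FI (mU/L) x FPG (mmol/L) / 22.5`; glucose given in mg/dL is
#' converted to mmol/L by dividing by 18.0.
#'
#' @param fi fasting insulin, mU/L.
#' @param fpg fasting plasma glucose, in the unit named by `fpg_unit`.
#' @param fpg_unit `"mg/dL"` (default, converted by /18) or `"mmol/L"`.
#' @return numeric vector of HOMA-IR values.
#' @export
homa_ir <- function(fi, fpg, fpg_unit = c("mg/dL", "mmol/L")) {
  fpg_unit <- match.arg(fpg_unit)
  if (any(!is.na(fi) & fi < 0) || any(!is.na(fpg) & fpg < 0))
    stop("negative fasting insulin or glucose")
  glu <- if (fpg_unit == "mg/dL") fpg / 18.0 else fpg
  fi * glu / 22.5
}
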