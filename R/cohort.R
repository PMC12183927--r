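#' Cohort table: ingestion, validation, derived ratios, reference labels
#'
#' A cohort table holds one row per subject: demographics (age, sex,
#' education, MMSE, ApoE e4 carrier status, clinical diagnosis), CSF
#' biomarkers (Abeta42, Abeta40, tTau, pTau181) and plasma biomarkers
#' (Abeta42, Abeta40, pTau181, pTau217, NfL), all concentrations in pg/ml.
#' Dimensionless ratio columns (`csf_ab42_40`, `csf_ab42_ttau`,
#' `csf_ab42_ptau`, `plasma_ab42_40`) are always recomputed from the raw
#' concentrations, never trusted from the input file.
#'
#' @name cohort
NULL

#' Required biomarker columns of a cohort table
#' @keywords internal
biomarker_columns <- function() {
  c("csf_ab42", "csf_ab40", "csf_ttau", "csf_ptau181",
    "plasma_ab42", "plasma_ab40", "plasma_ptau181", "plasma_ptau217",
    "plasma_nfl")
}

cohort_required_columns <- function() {
  c("id", "age", "sex", "apoe_e4", biomarker_columns())
}

cohort_optional_columns <- function() {
  c("education", "mmse", "diagnosis")
}

#' Add derived ratio columns to a cohort table
#'
#' Ratios are computed from raw concentrations so they can never disagree
#' with their parts.
#'
#' @param cohort a cohort tibble with the raw biomarker columns
#' @return the cohort with `csf_ab42_40`, `csf_ab42_ttau`, `csf_ab42_ptau`
#'   and `plasma_ab42_40` columns (re)computed
#' @export
add_derived_ratios <- function(cohort) {
  dplyr::mutate(
    cohort,
    csf_ab42_40    = .data$csf_ab42 / .data$csf_ab40,
    csf_ab42_ttau  = .data$csf_ab42 / .data$csf_ttau,
    csf_ab42_ptau  = .data$csf_ab42 / .data$csf_ptau181,
    plasma_ab42_40 = .data$plasma_ab42 / .data$plasma_ab40
  )
}

validate_cohort <- function(cohort, check_mmse_range = TRUE) {
  for (col in biomarker_columns()) {
    v <- cohort[[col]]
    abort_if(!is.numeric(v),
             sprintf("column '%s' is not numeric", col), "bbadx_validation")
    bad <- which(!is.na(v) & v <= 0)
    abort_if(length(bad) > 0,
             sprintf("nonpositive concentration in column '%s', row %d",
                     col, bad[1]), "bbadx_validation")
  }
  abort_if(anyDuplicated(cohort$id) > 0, "duplicate subject ids",
           "bbadx_validation")
  abort_if(any(!is.na(cohort$age) & cohort$age <= 0),
           "nonpositive age", "bbadx_validation")
  if (check_mmse_range && "mmse" %in% names(cohort)) {
    abort_if(any(!is.na(cohort$mmse) & (cohort$mmse < 0 | cohort$mmse > 30)),
             "mmse outside [0, 30]", "bbadx_validation")
  }
  invisible(cohort)
}

#' Read a subject-level cohort CSV
#'
#' Reads a comma-separated, headered, UTF-8 cohort file, validates it, applies
#' the completeness rule (subjects are retained only with complete data on all
#' nine biomarkers, age and sex), and computes derived ratio columns.
#'
#' @param path path to the CSV file
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(csf_ab42 = "CSF_AB42")`
#' @return a tibble of retained subjects with attribute `n_excluded` counting
#'   rows dropped by the completeness rule
#' @export
read_cohort <- function(path, schema = NULL) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path), "bbadx_io")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      idx <- match(schema[[canonical]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- canonical
    }
  }
  missing_cols <- setdiff(cohort_required_columns(), names(raw))
  abort_if(length(missing_cols) > 0,
           sprintf("missing required columns: %s",
                   paste(missing_cols, collapse = ", ")), "bbadx_validation")
  for (col in cohort_optional_columns()) {
    if (!col %in% names(raw)) raw[[col]] <- NA
  }
  for (col in c(biomarker_columns(), "age", "education", "mmse")) {
    v <- raw[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      abort_if(length(bad) > 0,
               sprintf("non-numeric value in column '%s', row %d",
                       col, bad[1]), "bbadx_validation")
      v <- conv
    }
    raw[[col]] <- as.numeric(v)
  }
  raw$diagnosis <- normalize_diagnosis(raw$diagnosis)

  complete <- stats::complete.cases(
    raw[, c(biomarker_columns(), "age", "sex")]) & raw$sex != ""
  n_excluded <- sum(!complete)
  cohort <- tibble::as_tibble(raw[complete, , drop = FALSE])
  validate_cohort(cohort)
  cohort <- add_derived_ratios(cohort)
  attr(cohort, "n_excluded") <- n_excluded
  cohort
}

normalize_diagnosis <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "missing"
  out <- ifelse(toupper(x) == "MCI", "MCI",
                ifelse(tolower(x) == "dementia", "dementia", "missing"))
  out
}

#' Write a cohort table to CSV
#'
#' Numeric columns are serialized with 15 significant digits so a write/read
#' round trip is lossless well beyond 12 significant digits.
#'
#' @param cohort cohort tibble
#' @param path output path
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], format = "g", digits = 15)
      out[[col]][out[[col]] %in% c("NA", " NA")] <- NA
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Construct a reference standard for amyloid status
#'
#' The reference standard names the CSF measure, the cut-off, and which side
#' of the cut-off is *normal*. The study's assay reference ranges define
#' normality by strict inequality (e.g. Abeta42/40 ratio > 0.069 is normal),
#' so a value exactly at the cut-off is classified abnormal (A+).
#'
#' @param measure `"csf_ab42_40"` (cut-off 0.069) or `"csf_ab42_ptau"`
#'   (cut-off 8.1)
#' @param cutoff positive threshold; defaults to the assay value for `measure`
#' @param normal_direction side that is normal, `"above"` or `"below"`
#' @return a `reference_standard` object
#' @export
reference_standard <- function(measure = c("csf_ab42_40", "csf_ab42_ptau"),
                               cutoff = NULL,
                               normal_direction = "above") {
  measure <- match.arg(measure)
  if (is.null(cutoff)) {
    cutoff <- switch(measure, csf_ab42_40 = 0.069, csf_ab42_ptau = 8.1)
  }
  abort_if(!is.numeric(cutoff) || cutoff <= 0, "cutoff must be positive",
           "bbadx_validation")
  normal_direction <- match.arg(normal_direction, c("above", "below"))
  structure(list(measure = measure, cutoff = cutoff,
                 normal_direction = normal_direction),
            class = "reference_standard")
}

#' Classify amyloid status from a CSF ratio
#'
#' A subject is A- (amyloid negative) iff the ratio lies strictly on the
#' normal side of the cut-off; boundary values are abnormal (A+).
#'
#' @param ratio positive ratio value(s)
#' @param standard a [reference_standard()]
#' @return character vector of `"Apos"` / `"Aneg"`
#' @export
classify_amyloid <- function(ratio, standard = reference_standard()) {
  abort_if(any(!is.na(ratio) & ratio <= 0), "ratio must be positive",
           "bbadx_validation")
  normal <- if (standard$normal_direction == "above") {
    ratio > standard$cutoff
  } else {
    ratio < standard$cutoff
  }
  ifelse(normal, "Aneg", "Apos")
}

#' AT profile from CSF Abeta42/40 and CSF pTau181
#'
#' A status from the CSF Abeta42/40 ratio at 0.069 (strictly above = normal);
#' T status positive iff CSF pTau181 >= 56.5 pg/ml (the assay's normal range
#' is pTau < 56.5, so the boundary is abnormal).
#'
#' @param csf_ab42_40 ratio value(s)
#' @param csf_ptau181 pTau181 concentration(s), pg/ml
#' @return tibble with columns `a_status`, `t_status`
#' @export
classify_at <- function(csf_ab42_40, csf_ptau181) {
  abort_if(any(is.na(csf_ab42_40)) || any(is.na(csf_ptau181)),
           "missing inputs to AT classification", "bbadx_validation")
  tibble::tibble(
    a_status = classify_amyloid(csf_ab42_40),
    t_status = ifelse(csf_ptau181 >= 56.5, "Tpos", "Tneg")
  )
}

#' Attach the binary reference label to a cohort
#'
#' @param cohort cohort tibble with derived ratios
#' @param standard a [reference_standard()]
#' @param subset `"all"` or `"MCI"` (keeps only subjects with an MCI
#'   diagnosis, mirroring the MCI-only sensitivity analysis)
#' @return the (possibly subset) cohort with a logical `a_positive` column
#'   and character `a_status`
#' @export
label_cohort <- function(cohort, standard = reference_standard(),
                         subset = c("all", "MCI")) {
  subset <- match.arg(subset)
  if (subset == "MCI") {
    cohort <- dplyr::filter(cohort, .data$diagnosis == "MCI")
  }
  abort_if(nrow(cohort) == 0, "empty cohort after subsetting", "bbadx_validation")
  status <- classify_amyloid(cohort[[standard$measure]], standard)
  cohort$a_status <- status
  cohort$a_positive <- status == "Apos"
  cohort
}
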