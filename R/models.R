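#' Per-biomarker logistic models and MMSE linear models
#'
#' @name model_fits
NULL

#' Logistic model of amyloid status on one standardized biomarker
#'
#' Fits `a_positive ~ z(biomarker)` by maximum likelihood (IRLS, tolerance
#' 1e-10, at most 100 iterations). The predictor is z-scored on the analysis
#' sample, so the coefficient is log-odds per predictor SD and magnitudes are
#' comparable across biomarkers. With `exclude_outliers = TRUE`, values
#' outside mean +/- 3 SD (computed once on the full sample) are dropped
#' before standardization and refitting — the rule under which the plasma
#' Abeta42/40 ratio's performance recovers in this population.
#'
#' @param cohort labeled cohort
#' @param biomarker column name
#' @param exclude_outliers apply the one-pass +/- 3 SD exclusion
#' @return tibble row: standardized coefficient, Wald p, n_used,
#'   outliers_excluded, separation flag
#' @export
logistic_biomarker_model <- function(cohort, biomarker,
                                     exclude_outliers = FALSE) {
  x <- cohort[[biomarker]]
  y <- cohort$a_positive
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n_total <- length(x)
  excluded <- 0L
  if (exclude_outliers) {
    mu <- mean(x)
    s <- stats::sd(x)
    inlier <- abs(x - mu) <= 3 * s
    excluded <- sum(!inlier)
    x <- x[inlier]
    y <- y[inlier]
  }
  abort_if(length(unique(y)) < 2, "one class absent after exclusions",
           "bbadx_validation")
  z <- (x - mean(x)) / stats::sd(x)
  fit <- suppressWarnings(stats::glm(
    y ~ z, family = stats::binomial(),
    control = list(epsilon = 1e-10, maxit = 100)))
  abort_if(!fit$converged, "logistic fit did not converge", "bbadx_fit")
  co <- summary(fit)$coefficients
  beta <- co["z", "Estimate"]
  separation <- abs(beta) > 15 || co["z", "Std. Error"] > 100
  tibble::tibble(
    biomarker = biomarker,
    standardized_coefficient = beta,
    p = co["z", "Pr(>|z|)"],
    n_used = length(x),
    outliers_excluded = excluded,
    exclusion_rule = if (exclude_outliers) "mean +/- 3 SD, one pass" else "none",
    separation_flagged = separation
  )
}

#' Linear model of MMSE on one plasma biomarker
#'
#' Least-squares fit
#' `mmse ~ biomarker + diagnosis + age + apoe_e4 + sex + biomarker:diagnosis`
#' (optionally `+ education`) on subjects with known MMSE and diagnosis;
#' coefficients are unstandardized. Diagnosis is coded with dementia as the
#' reference level, so the MCI indicator's coefficient is the MMSE advantage
#' of the MCI stage. Subjects with missing diagnosis are excluded (and
#' counted) from these models only.
#'
#' @param cohort cohort tibble (label not required)
#' @param biomarker column name
#' @param include_education add education as a covariate
#' @return list with `terms` (tibble of coefficient/SE/p per term),
#'   `model_p` (overall F-test), `n_used`, `n_excluded`
#' @export
mmse_linear_model <- function(cohort, biomarker, include_education = FALSE) {
  dat <- tibble::tibble(
    mmse = cohort$mmse,
    biomarker = cohort[[biomarker]],
    diagnosis = cohort$diagnosis,
    age = cohort$age,
    apoe_e4 = cohort$apoe_e4,
    sex = cohort$sex,
    education = cohort$education
  )
  n_input <- nrow(dat)
  dat <- dat[dat$diagnosis %in% c("MCI", "dementia") & !is.na(dat$mmse), ]
  if (include_education) dat <- dat[!is.na(dat$education), ]
  n_used <- nrow(dat)
  abort_if(n_used < 10, "too few subjects with MMSE and known diagnosis",
           "bbadx_validation")
  dat$diagnosis <- factor(dat$diagnosis, levels = c("dementia", "MCI"))
  f <- mmse ~ biomarker + diagnosis + age + apoe_e4 + sex +
    biomarker:diagnosis
  if (include_education) {
    f <- mmse ~ biomarker + diagnosis + age + apoe_e4 + sex + education +
      biomarker:diagnosis
  }
  fit <- stats::lm(f, data = dat)
  abort_if(any(is.na(stats::coef(fit))),
           paste("rank-deficient model; aliased terms:",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")),
           "bbadx_fit")
  s <- summary(fit)
  co <- s$coefficients
  fstat <- s$fstatistic
  model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  terms <- tibble::tibble(
    term = rownames(co),
    coefficient = co[, "Estimate"],
    se = co[, "Std. Error"],
    p = co[, "Pr(>|t|)"]
  )
  list(terms = terms, model_p = unname(model_p),
       n_used = n_used, n_excluded = n_input - n_used, fit = fit)
}
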