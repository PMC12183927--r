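#' Two-group contrasts between amyloid-positive and -negative subjects
#'
#' The descriptive machinery of the study's biomarker table: Shapiro-Wilk
#' routed t/Wilcoxon tests, chi-square for categoricals, percent median
#' difference, pooled-SD Cohen's d with a normal-approximation CI, ANCOVA
#' adjustment for age and sex, and BH/Bonferroni multiplicity control.
#'
#' @name group_comparison
NULL

#' Cohen's d from group summary statistics
#'
#' `d = (mean_pos - mean_neg) / pooled_sd` with
#' `pooled_sd^2 = ((n_neg-1) sd_neg^2 + (n_pos-1) sd_pos^2) / (n_neg+n_pos-2)`,
#' standard error
#' `sqrt((n_neg+n_pos)/(n_neg n_pos) + d^2 / (2 (n_neg+n_pos)))`,
#' and a 95% CI of `d +/- 1.96 se`. The sign convention is positive group
#' minus negative group, so biomarkers elevated in A+ give d > 0.
#'
#' @param mean_neg,sd_neg,n_neg negative-group moments and size
#' @param mean_pos,sd_pos,n_pos positive-group moments and size
#' @return list with `d`, `se`, `ci95_low`, `ci95_high`
#' @export
cohen_d <- function(mean_neg, sd_neg, n_neg, mean_pos, sd_pos, n_pos) {
  abort_if(n_neg < 2 || n_pos < 2, "need n >= 2 per group", "bbadx_validation")
  abort_if(sd_neg < 0 || sd_pos < 0, "sds must be nonnegative",
           "bbadx_validation")
  pooled2 <- ((n_neg - 1) * sd_neg^2 + (n_pos - 1) * sd_pos^2) /
    (n_neg + n_pos - 2)
  abort_if(pooled2 <= 0, "degenerate pooled sd", "bbadx_validation")
  d <- (mean_pos - mean_neg) / sqrt(pooled2)
  se <- sqrt((n_neg + n_pos) / (n_neg * n_pos) + d^2 / (2 * (n_neg + n_pos)))
  list(d = d, se = se, ci95_low = d - 1.96 * se, ci95_high = d + 1.96 * se)
}

#' Compare one biomarker between reference-standard groups
#'
#' Shapiro-Wilk at alpha = 0.05 in each group decides the test: both groups
#' normal gives a Welch t-test, otherwise a Wilcoxon rank-sum test. The
#' percent median difference is `100 (median_pos - median_neg) / median_neg`.
#' Effect size from [cohen_d()] on the group summary statistics.
#'
#' @param cohort labeled cohort (see [label_cohort()])
#' @param biomarker column name
#' @return tibble row: biomarker, test used, normality p-values, raw p,
#'   percent median difference, d and its CI
#' @export
compare_groups <- function(cohort, biomarker) {
  x_neg <- cohort[[biomarker]][!cohort$a_positive]
  x_pos <- cohort[[biomarker]][cohort$a_positive]
  x_neg <- x_neg[!is.na(x_neg)]
  x_pos <- x_pos[!is.na(x_pos)]
  abort_if(length(x_neg) < 3 || length(x_pos) < 3,
           "need >= 3 subjects per group", "bbadx_validation")
  sw_neg <- stats::shapiro.test(x_neg)$p.value
  sw_pos <- stats::shapiro.test(x_pos)$p.value
  normal <- sw_neg >= 0.05 && sw_pos >= 0.05
  if (normal) {
    p_raw <- stats::t.test(x_pos, x_neg)$p.value
    test_used <- "t"
  } else {
    p_raw <- suppressWarnings(stats::wilcox.test(x_pos, x_neg))$p.value
    test_used <- "wilcoxon"
  }
  eff <- cohen_d(mean(x_neg), stats::sd(x_neg), length(x_neg),
                 mean(x_pos), stats::sd(x_pos), length(x_pos))
  tibble::tibble(
    biomarker = biomarker,
    test_used = test_used,
    shapiro_p_neg = sw_neg,
    shapiro_p_pos = sw_pos,
    p_raw = p_raw,
    pct_median_diff = 100 * (stats::median(x_pos) - stats::median(x_neg)) /
      stats::median(x_neg),
    d = eff$d, d_se = eff$se,
    d_ci_low = eff$ci95_low, d_ci_high = eff$ci95_high
  )
}

#' Age- and sex-adjusted group difference (ANCOVA)
#'
#' Least-squares model `biomarker ~ group + age + sex`; returns the Wald
#' p-value for the group indicator.
#'
#' @param cohort labeled cohort
#' @param biomarker column name
#' @param covariates covariate column names (default age and sex)
#' @return p-value for the group term
#' @export
ancova_adjusted_p <- function(cohort, biomarker, covariates = c("age", "sex")) {
  dat <- cohort[, c(biomarker, "a_positive", covariates)]
  dat <- dat[stats::complete.cases(dat), ]
  abort_if(nrow(dat) < length(covariates) + 3, "too few complete cases",
           "bbadx_validation")
  f <- stats::as.formula(paste0(
    "`", biomarker, "` ~ a_positive + ",
    paste(covariates, collapse = " + ")))
  fit <- stats::lm(f, data = dat)
  abort_if(any(is.na(stats::coef(fit))),
           paste("collinear covariates:",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")),
           "bbadx_validation")
  s <- summary(fit)$coefficients
  s["a_positiveTRUE", "Pr(>|t|)"]
}

#' Multiplicity adjustment
#'
#' Thin, validating wrapper over [stats::p.adjust()] restricted to the two
#' procedures used here: Benjamini-Hochberg (`"BH"`) and `"bonferroni"`.
#'
#' @param p vector of p-values in \[0, 1\]
#' @param method `"BH"` or `"bonferroni"`
#' @return adjusted p-values, order-preserving
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  abort_if(any(is.na(p)) || any(p < 0 | p > 1), "p-values must be in [0, 1]",
           "bbadx_validation")
  stats::p.adjust(p, method = method)
}

#' Group-contrast table over a panel of biomarkers
#'
#' Runs [compare_groups()] and [ancova_adjusted_p()] for each biomarker and
#' attaches BH and Bonferroni flags at alpha = 0.05 computed over the panel's
#' raw p-values.
#'
#' @param cohort labeled cohort
#' @param biomarkers character vector of column names
#' @param alpha significance level for the flags
#' @return tibble, one row per biomarker
#' @export
group_comparison_table <- function(cohort, biomarkers, alpha = 0.05) {
  rows <- dplyr::bind_rows(lapply(biomarkers, function(b) {
    row <- compare_groups(cohort, b)
    row$p_adjusted_age_sex <- ancova_adjusted_p(cohort, b)
    row
  }))
  rows$p_fdr <- adjust_pvalues(rows$p_raw, "BH")
  rows$p_bonferroni <- adjust_pvalues(rows$p_raw, "bonferroni")
  rows$fdr_significant <- rows$p_fdr < alpha
  rows$bonferroni_significant <- rows$p_bonferroni < alpha
  rows
}
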