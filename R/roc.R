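#' From-scratch ROC machinery with DeLong inference
#'
#' Empirical ROC curves over observed thresholds, Mann-Whitney AUC with
#' half-credit ties, DeLong structural-component variance and paired
#' covariance (midrank formulation), Youden and dual
#' 95%-sensitivity/specificity cut-off selection, and prevalence-dependent
#' predictive values. After orientation the positivity predicate is
#' `score >= threshold`, consistent with the boundary-abnormal convention of
#' the reference standard.
#'
#' @name roc_toolkit
NULL

check_labels <- function(labels) {
  abort_if(!is.logical(labels), "labels must be logical (TRUE = positive)",
           "bbadx_validation")
  abort_if(!any(labels) || all(labels), "both classes must be present",
           "bbadx_validation")
}

# Mann-Whitney AUC via midranks: half credit for ties.
auc_rank <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  m <- sum(labels)
  n <- sum(!labels)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

#' Orient scores so the AUC is at least 0.5
#'
#' Biomarkers depressed in the positive class (Abeta42 and the ratios) are
#' negated so that "higher is positive" holds internally; the orientation is
#' recorded so cut-offs can be reported on the original scale. An AUC of
#' exactly 0.5 defaults to `higher_is_positive` and is flagged.
#'
#' @param scores numeric vector
#' @param labels logical vector, TRUE = reference positive
#' @return list with `scores` (oriented), `orientation`, `tied` flag
#' @export
orient_scores <- function(scores, labels) {
  check_labels(labels)
  a <- auc_rank(scores, labels)
  if (a < 0.5) {
    list(scores = -scores, orientation = "lower_is_positive", tied = FALSE)
  } else {
    list(scores = scores, orientation = "higher_is_positive",
         tied = (a == 0.5))
  }
}

#' Empirical ROC curve
#'
#' Thresholds are placed at the observed (oriented) score values plus `Inf`,
#' so the operating points include both the all-positive (SE = 1) and the
#' all-negative (SP = 1) corners. Positivity is `oriented score >= threshold`.
#'
#' @param scores numeric vector
#' @param labels logical vector, TRUE = reference positive
#' @param orientation `"auto"` (Mann-Whitney AUC >= 0.5), or fixed
#' @return object of class `roc_curve`
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("auto", "higher_is_positive",
                                      "lower_is_positive")) {
  orientation <- match.arg(orientation)
  check_labels(labels)
  abort_if(any(is.na(scores)), "scores must not contain NA",
           "bbadx_validation")
  if (orientation == "auto") {
    o <- orient_scores(scores, labels)
    oriented <- o$scores
    orientation <- o$orientation
  } else {
    oriented <- if (orientation == "lower_is_positive") -scores else scores
  }
  thr <- c(sort(unique(oriented)), Inf)
  sens <- vapply(thr, function(t) mean(oriented[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(oriented[!labels] < t), numeric(1))
  structure(list(
    thresholds = thr,
    cutpoints = if (orientation == "lower_is_positive") -thr else thr,
    sensitivity = sens,
    specificity = spec,
    orientation = orientation,
    n_pos = sum(labels),
    n_neg = sum(!labels),
    oriented_scores = oriented,
    labels = labels
  ), class = "roc_curve")
}

# DeLong structural components (midrank formulation).
# V10[i] = placement of positive i among negatives; V01[j] analogous.
delong_components <- function(scores, labels) {
  m <- sum(labels)
  n <- sum(!labels)
  r_all <- rank(scores, ties.method = "average")
  r_pos <- rank(scores[labels], ties.method = "average")
  r_neg <- rank(scores[!labels], ties.method = "average")
  v10 <- (r_all[labels] - r_pos) / n
  v01 <- 1 - (r_all[!labels] - r_neg) / m
  # exact pair-count numerator (an integer or half-integer) divided once,
  # so the AUC agrees bit-for-bit with exhaustive pair counting
  auc <- (sum(r_all[labels]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc, m = m, n = n)
}

#' Mann-Whitney AUC with DeLong variance
#'
#' AUC is the tie-half-credit pair-counting statistic; the standard error is
#' DeLong's structural-component estimator, and the 95% CI is Wald on the AUC
#' scale, clipped to \[0, 1\].
#'
#' @param scores numeric vector
#' @param labels logical vector, TRUE = reference positive
#' @param orientation `"auto"` or fixed (see [roc_curve()])
#' @param variance compute the DeLong variance (requires >= 2 per class)
#' @return list with `auc`, `se_delong`, `ci95_low`, `ci95_high`,
#'   `orientation`, `n_pos`, `n_neg`
#' @export
auc_mann_whitney <- function(scores, labels, orientation = "auto",
                             variance = TRUE) {
  check_labels(labels)
  if (orientation == "auto") {
    o <- orient_scores(scores, labels)
    oriented <- o$scores
    orientation <- o$orientation
  } else {
    oriented <- if (orientation == "lower_is_positive") -scores else scores
  }
  comp <- delong_components(oriented, labels)
  if (!variance) {
    return(list(auc = comp$auc, se_delong = NA_real_,
                ci95_low = NA_real_, ci95_high = NA_real_,
                orientation = orientation, n_pos = comp$m, n_neg = comp$n))
  }
  abort_if(comp$m < 2 || comp$n < 2,
           "DeLong variance needs >= 2 subjects per class", "bbadx_validation")
  v <- stats::var(comp$v10) / comp$m + stats::var(comp$v01) / comp$n
  se <- sqrt(max(v, 0))
  list(auc = comp$auc, se_delong = se,
       ci95_low = max(0, comp$auc - 1.96 * se),
       ci95_high = min(1, comp$auc + 1.96 * se),
       orientation = orientation, n_pos = comp$m, n_neg = comp$n)
}

#' Positive and negative predictive values from SE, SP and prevalence
#'
#' Bayes' formula: `PPV = SE pi / (SE pi + (1-SP)(1-pi))`,
#' `NPV = SP (1-pi) / (SP (1-pi) + (1-SE) pi)`. An undefined value (zero
#' denominator) is returned as NA.
#'
#' @param sensitivity,specificity,prevalence all in \[0, 1\]
#' @return list with `ppv`, `npv`
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity, specificity, prevalence)
  abort_if(any(args < 0 | args > 1), "arguments must be in [0, 1]",
           "bbadx_validation")
  num_p <- sensitivity * prevalence
  den_p <- num_p + (1 - specificity) * (1 - prevalence)
  num_n <- specificity * (1 - prevalence)
  den_n <- num_n + (1 - sensitivity) * prevalence
  list(ppv = if (den_p == 0) NA_real_ else num_p / den_p,
       npv = if (den_n == 0) NA_real_ else num_n / den_n)
}

#' Youden-optimal cut-off
#'
#' Maximizes `J = SE + SP - 1` over the curve's observed thresholds; ties are
#' broken toward higher specificity (the rule-in framing of a confirmatory
#' biomarker). Predictive values use the supplied prevalence.
#'
#' @param curve a [roc_curve()]
#' @param prevalence prior probability of reference positivity; defaults to
#'   the curve's sample prevalence
#' @return tibble row: cutoff (original scale), orientation, sensitivity,
#'   specificity, youden_j, ppv, npv, prevalence
#' @export
youden_cutoff <- function(curve, prevalence = NULL) {
  if (is.null(prevalence)) {
    prevalence <- curve$n_pos / (curve$n_pos + curve$n_neg)
  }
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(curve$specificity[best])]
  pv <- predictive_values(curve$sensitivity[best], curve$specificity[best],
                          prevalence)
  tibble::tibble(
    cutoff = curve$cutpoints[best],
    orientation = curve$orientation,
    sensitivity = curve$sensitivity[best],
    specificity = curve$specificity[best],
    youden_j = j[best],
    ppv = pv$ppv, npv = pv$npv,
    prevalence = prevalence
  )
}

#' Dual rule-in / rule-out cut-offs
#'
#' The rule-in cut-off is the least extreme observed threshold whose
#' empirical specificity reaches `spec_target`; the rule-out cut-off the
#' least extreme threshold whose sensitivity reaches `sens_target`. Subjects
#' scoring between the two fall in the intermediate zone. An unattainable
#' target yields an NA cut-off with a flag, not an error.
#'
#' @param curve a [roc_curve()]
#' @param sens_target,spec_target targets in (0.5, 1\]
#' @param prevalence for predictive values; defaults to sample prevalence
#' @return tibble with one row per rule (`rule_in`, `rule_out`) plus the
#'   intermediate fraction as an attribute `intermediate_fraction`
#' @export
two_cutoffs <- function(curve, sens_target = 0.95, spec_target = 0.95,
                        prevalence = NULL) {
  abort_if(sens_target <= 0.5 || sens_target > 1 ||
             spec_target <= 0.5 || spec_target > 1,
           "targets must be in (0.5, 1]", "bbadx_validation")
  if (is.null(prevalence)) {
    prevalence <- curve$n_pos / (curve$n_pos + curve$n_neg)
  }
  # Oriented thresholds are ascending; SE nonincreasing, SP nondecreasing.
  in_ok <- which(curve$specificity >= spec_target & is.finite(curve$thresholds))
  out_ok <- which(curve$sensitivity >= sens_target & is.finite(curve$thresholds))
  idx_in <- if (length(in_ok)) min(in_ok) else NA_integer_
  idx_out <- if (length(out_ok)) max(out_ok) else NA_integer_

  one <- function(idx, rule, target) {
    if (is.na(idx)) {
      return(tibble::tibble(rule = rule, target = target,
                            cutoff = NA_real_, attained = FALSE,
                            sensitivity = NA_real_, specificity = NA_real_,
                            ppv = NA_real_, npv = NA_real_))
    }
    pv <- predictive_values(curve$sensitivity[idx], curve$specificity[idx],
                            prevalence)
    tibble::tibble(rule = rule, target = target,
                   cutoff = curve$cutpoints[idx], attained = TRUE,
                   sensitivity = curve$sensitivity[idx],
                   specificity = curve$specificity[idx],
                   ppv = pv$ppv, npv = pv$npv)
  }
  out <- dplyr::bind_rows(one(idx_in, "rule_in", spec_target),
                          one(idx_out, "rule_out", sens_target))
  inter <- NA_real_
  if (!is.na(idx_in) && !is.na(idx_out)) {
    lo <- curve$thresholds[idx_out]
    hi <- curve$thresholds[idx_in]
    inter <- mean(curve$oriented_scores >= lo & curve$oriented_scores < hi)
  }
  attr(out, "intermediate_fraction") <- inter
  attr(out, "orientation") <- curve$orientation
  attr(out, "prevalence") <- prevalence
  out
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both markers are measured on the same subjects with the same reference
#' labels. Each is oriented independently (AUC >= 0.5) and
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)` with the DeLong
#' structural covariance; two-sided p from the standard normal. A degenerate
#' variance of the difference (e.g. one marker a monotone transform of the
#' other) is flagged and returns p = 1 when the AUCs are equal.
#'
#' @param scores_a,scores_b numeric vectors over the same subjects
#' @param labels logical vector, TRUE = reference positive
#' @return tibble row: auc_a, auc_b, z, p, degenerate flag
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  check_labels(labels)
  abort_if(length(scores_a) != length(scores_b) ||
             length(scores_a) != length(labels),
           "score vectors and labels must have equal length",
           "bbadx_validation")
  abort_if(sum(labels) < 2 || sum(!labels) < 2,
           "need >= 2 subjects per class", "bbadx_validation")
  oa <- orient_scores(scores_a, labels)
  ob <- orient_scores(scores_b, labels)
  ca <- delong_components(oa$scores, labels)
  cb <- delong_components(ob$scores, labels)
  var_a <- stats::var(ca$v10) / ca$m + stats::var(ca$v01) / ca$n
  var_b <- stats::var(cb$v10) / cb$m + stats::var(cb$v01) / cb$n
  cov_ab <- stats::cov(ca$v10, cb$v10) / ca$m +
    stats::cov(ca$v01, cb$v01) / ca$n
  var_diff <- var_a + var_b - 2 * cov_ab
  diff <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps^0.5) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
    p <- if (abs(diff) < 1e-12) 1 else 0
    degenerate <- TRUE
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
    degenerate <- FALSE
  }
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, z = z, p = p,
                 degenerate = degenerate)
}

#' All-pairs DeLong comparison with FDR control
#'
#' Tests every unordered pair of biomarkers on the same labeled cohort and
#' applies Benjamini-Hochberg over the pairwise p-values (15 tests for the
#' six-plasma-marker panel).
#'
#' @param cohort labeled cohort
#' @param biomarkers character vector (>= 2) of score columns
#' @param alpha FDR level for the significance flag
#' @return list with `pairs` (long tibble) and symmetric `p_matrix`,
#'   `z_matrix`, plus per-marker `auc`
#' @export
auc_comparison_matrix <- function(cohort, biomarkers, alpha = 0.05) {
  abort_if(length(biomarkers) < 2, "need >= 2 biomarkers", "bbadx_validation")
  labels <- cohort$a_positive
  pairs <- utils::combn(biomarkers, 2, simplify = FALSE)
  rows <- dplyr::bind_rows(lapply(pairs, function(pr) {
    res <- delong_paired_test(cohort[[pr[1]]], cohort[[pr[2]]], labels)
    tibble::tibble(biomarker_a = pr[1], biomarker_b = pr[2],
                   auc_a = res$auc_a, auc_b = res$auc_b,
                   z = res$z, p = res$p, degenerate = res$degenerate)
  }))
  rows$p_fdr <- adjust_pvalues(rows$p, "BH")
  rows$fdr_significant <- rows$p_fdr < alpha
  k <- length(biomarkers)
  p_matrix <- matrix(NA_real_, k, k, dimnames = list(biomarkers, biomarkers))
  z_matrix <- p_matrix
  for (i in seq_len(nrow(rows))) {
    a <- rows$biomarker_a[i]
    b <- rows$biomarker_b[i]
    p_matrix[a, b] <- p_matrix[b, a] <- rows$p[i]
    z_matrix[a, b] <- rows$z[i]
    z_matrix[b, a] <- -rows$z[i]
  }
  aucs <- vapply(biomarkers, function(b) {
    auc_mann_whitney(cohort[[b]], labels, variance = FALSE)$auc
  }, numeric(1))
  list(pairs = rows, p_matrix = p_matrix, z_matrix = z_matrix, auc = aucs)
}
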