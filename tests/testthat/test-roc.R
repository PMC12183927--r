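test_that("AUC matches hand-worked examples including ties", {
  expect_equal(auc_mann_whitney(c(3, 4, 5, 1, 2),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE),
                                variance = FALSE)$auc, 1)
  expect_equal(auc_mann_whitney(c(2, 3, 5, 1, 3, 4),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                                variance = FALSE)$auc, 5.5 / 9)
  expect_equal(auc_mann_whitney(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                                orientation = "higher_is_positive",
                                variance = FALSE)$auc, 0.5)
})

test_that("AUC equals the exhaustive pair-counting oracle on random instances", {
  set.seed(14)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # coarse -> ties
    a <- auc_mann_whitney(scores, labels, orientation = "higher_is_positive",
                          variance = FALSE)$auc
    expect_identical(a, oracle_auc(scores, labels))
    # flip symmetry
    b <- auc_mann_whitney(-scores, labels, orientation = "higher_is_positive",
                          variance = FALSE)$auc
    expect_equal(a + b, 1, tolerance = 1e-12)
  }
})

test_that("orientation is chosen so the AUC is at least 0.5", {
  labels <- rep(c(TRUE, FALSE), c(30, 20))
  lowered <- c(rnorm(30, 5), rnorm(20, 8))  # positives lower
  o <- orient_scores(lowered, labels)
  expect_equal(o$orientation, "lower_is_positive")
  expect_gte(auc_rank_check <- auc_mann_whitney(lowered, labels)$auc, 0.5)
  o2 <- orient_scores(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(o2$orientation, "higher_is_positive")
  expect_true(o2$tied)
  expect_error(orient_scores(1:4, rep(TRUE, 4)), class = "bbadx_validation")
})

test_that("DeLong variance and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    labels <- rep(c(TRUE, FALSE), c(60, 40))
    a_scores <- ifelse(labels, rnorm(100, 1), rnorm(100))
    b_scores <- 0.6 * a_scores + rnorm(100, 0, 0.8)
    mine <- auc_mann_whitney(a_scores, labels)
    ref <- pROC::roc(labels, a_scores, quiet = TRUE, direction = "<")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(mine$se_delong, sqrt(pROC::var(ref)), tolerance = 1e-10)
    mine_t <- delong_paired_test(a_scores, b_scores, labels)
    ref_t <- pROC::roc.test(
      ref, pROC::roc(labels, b_scores, quiet = TRUE, direction = "<"),
      method = "delong")
    expect_equal(mine_t$p, ref_t$p.value, tolerance = 1e-10)
    expect_equal(mine_t$z, as.numeric(ref_t$statistic), tolerance = 1e-10)
  }
})

test_that("paired DeLong degeneracies and symmetry behave", {
  labels <- rep(c(TRUE, FALSE), c(25, 25))
  set.seed(31)
  s <- rnorm(50) + labels
  same <- delong_paired_test(s, s, labels)
  expect_equal(same$p, 1)
  expect_equal(same$z, 0)
  expect_true(same$degenerate)
  mono <- delong_paired_test(s, exp(2 * s) + 5, labels)
  expect_equal(mono$p, 1)
  s2 <- rnorm(50) + 0.5 * labels
  ab <- delong_paired_test(s, s2, labels)
  ba <- delong_paired_test(s2, s, labels)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("rank invariance: monotone transforms preserve AUC and operating points", {
  set.seed(41)
  labels <- rep(c(TRUE, FALSE), c(30, 30))
  scores <- rnorm(60) + labels
  trans <- function(x) exp(1.7 * x) + 3
  a1 <- auc_mann_whitney(scores, labels)
  a2 <- auc_mann_whitney(trans(scores), labels)
  expect_equal(a1$auc, a2$auc, tolerance = 1e-12)
  y1 <- youden_cutoff(roc_curve(scores, labels))
  y2 <- youden_cutoff(roc_curve(trans(scores), labels))
  expect_equal(y1$youden_j, y2$youden_j, tolerance = 1e-12)
  expect_equal(y1$sensitivity, y2$sensitivity)
  expect_equal(y2$cutoff, trans(y1$cutoff), tolerance = 1e-9)
})

test_that("Youden cut-off equals the brute-force threshold sweep", {
  set.seed(52)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)
    curve <- roc_curve(scores, labels, orientation = "higher_is_positive")
    got <- youden_cutoff(curve)
    want <- oracle_youden(scores, labels)
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$se)
    expect_equal(got$specificity, want$sp)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("Youden ties break toward the more specific threshold", {
  # perfectly separated: J = 1 anywhere in the gap; pick the most specific
  labels <- rep(c(FALSE, TRUE), each = 3)
  scores <- c(1, 2, 3, 10, 11, 12)
  got <- youden_cutoff(roc_curve(scores, labels))
  expect_equal(got$youden_j, 1)
  expect_equal(got$cutoff, 10)  # highest threshold achieving J = 1
  expect_equal(got$specificity, 1)
})

test_that("predictive values follow Bayes' formula and conserve counts", {
  pv <- predictive_values(1, 1, 0.5)
  expect_equal(c(pv$ppv, pv$npv), c(1, 1))
  pv <- predictive_values(0.8, 0.9, 0.3)
  expect_equal(pv$ppv, 0.8 * 0.3 / (0.8 * 0.3 + 0.1 * 0.7), tolerance = 1e-12)
  # degenerate denominator flagged as missing
  expect_true(is.na(predictive_values(0, 1, 1)$ppv))
  expect_error(predictive_values(1.2, 0.5, 0.5), class = "bbadx_validation")
  # count conservation: TP+FP+TN+FN = N at any (SE, SP, pi)
  set.seed(61)
  for (i in 1:20) {
    se <- runif(1); sp <- runif(1); pi <- runif(1); N <- 1000
    tp <- se * pi * N; fn <- (1 - se) * pi * N
    tn <- sp * (1 - pi) * N; fp <- (1 - sp) * (1 - pi) * N
    expect_equal(tp + fp + tn + fn, N, tolerance = 1e-9)
    pv <- predictive_values(se, sp, pi)
    if (!is.na(pv$ppv)) expect_equal(pv$ppv, tp / (tp + fp), tolerance = 1e-9)
    if (!is.na(pv$npv)) expect_equal(pv$npv, tn / (tn + fn), tolerance = 1e-9)
  }
})

test_that("two-cut-off selection matches enumeration and handles edge cases", {
  # perfect separation: both cut-offs coincide, no intermediate zone
  labels <- rep(c(FALSE, TRUE), each = 4)
  scores <- c(1, 2, 3, 4, 10, 11, 12, 13)
  tc <- two_cutoffs(roc_curve(scores, labels))
  expect_equal(tc$cutoff[tc$rule == "rule_in"],
               tc$cutoff[tc$rule == "rule_out"])
  expect_equal(attr(tc, "intermediate_fraction"), 0)

  # worked example: SP >= 0.95 requires SP = 1 at n_neg = 4, so rule-in > 4
  labels2 <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  scores2 <- c(2, 3, 5, 7, 1, 2, 3, 4)
  tc2 <- two_cutoffs(roc_curve(scores2, labels2,
                               orientation = "higher_is_positive"))
  expect_gt(tc2$cutoff[tc2$rule == "rule_in"], 4)
  expect_equal(tc2$cutoff[tc2$rule == "rule_in"], 5)
  expect_equal(tc2$cutoff[tc2$rule == "rule_out"], 2)
  # intermediate zone [2, 5): positives {2, 3} and negatives {2, 3, 4}
  expect_equal(attr(tc2, "intermediate_fraction"), 5 / 8)
  expect_true(tc2$cutoff[tc2$rule == "rule_out"] <=
                tc2$cutoff[tc2$rule == "rule_in"])

  # unattainable specificity target: flagged missing, not an error
  labels3 <- rep(c(TRUE, FALSE), 10)
  scores3 <- rep(1, 20)
  tc3 <- two_cutoffs(roc_curve(scores3, labels3,
                               orientation = "higher_is_positive"))
  expect_false(tc3$attained[tc3$rule == "rule_in"])
  expect_true(is.na(tc3$cutoff[tc3$rule == "rule_in"]))
  expect_error(two_cutoffs(roc_curve(scores2, labels2), sens_target = 0.4),
               class = "bbadx_validation")
})

test_that("at large n the Youden cut-off stabilizes near the group-density crossing", {
  cfg <- default_generator_config(seed = 19, n_neg = 5000, n_pos = 5000)
  cohort <- generate_cohort(cfg)
  got <- youden_cutoff(roc_curve(cohort$plasma_ptau217, cohort$a_positive))
  # oracle: J is maximized where the two class densities cross; solve
  # f_neg(x) = f_pos(x) for the configured moment-matched lognormals
  par_of <- function(m, s) lognormal_from_moments(m, s)
  pn <- par_of(0.18, 0.11)
  pp <- par_of(0.83, 0.56)
  crossing <- uniroot(function(x) {
    dlnorm(x, pn$mu, pn$sigma) - dlnorm(x, pp$mu, pp$sigma)
  }, c(0.2, 0.8))$root
  expect_lt(abs(got$cutoff - crossing) / crossing, 0.15)
})

test_that("the rule-in cut-off distribution brackets the negative-group upper quantile", {
  # at 95% specificity the rule-in threshold tracks the 95th percentile of
  # the A- distribution; check the median over repeated study-sized cohorts
  # against the config-derived quantile bracket [q90, q99]
  cuts <- vapply(1:100, function(s) {
    cohort <- generate_cohort(default_generator_config(seed = 500 + s))
    tc <- two_cutoffs(roc_curve(cohort$plasma_ptau181, cohort$a_positive))
    tc$cutoff[tc$rule == "rule_in"]
  }, numeric(1))
  par <- lognormal_from_moments(1.68, 0.64)
  bracket <- qlnorm(c(0.90, 0.99), par$mu, par$sigma)
  med <- median(cuts, na.rm = TRUE)
  expect_gt(med, bracket[1])
  expect_lt(med, bracket[2])
})

test_that("the all-pairs AUC comparison is symmetric with a 15-test FDR family", {
  cohort <- generate_cohort(default_generator_config(seed = 17, n_neg = 400,
                                                     n_pos = 400))
  labeled <- label_cohort(cohort)
  cmp <- auc_comparison_matrix(labeled, plasma_panel())
  expect_equal(nrow(cmp$pairs), 15)
  expect_true(isSymmetric(cmp$p_matrix))
  expect_true(all(is.na(diag(cmp$p_matrix))))
  expect_equal(cmp$z_matrix, -t(cmp$z_matrix))
  # qualitative pattern: pTau217 beats NfL decisively; pTau217 vs pTau181
  # is the closest head-to-head among the pTau markers
  pick <- function(a, b) cmp$pairs$p_fdr[
    (cmp$pairs$biomarker_a == a & cmp$pairs$biomarker_b == b) |
      (cmp$pairs$biomarker_a == b & cmp$pairs$biomarker_b == a)]
  expect_lt(pick("plasma_ptau217", "plasma_nfl"), 0.05)
  expect_gt(pick("plasma_ptau217", "plasma_ptau181"),
            pick("plasma_ptau217", "plasma_nfl"))
  # two identical markers: p = 1, never significant
  labeled$dup <- labeled$plasma_ptau217
  cmp2 <- auc_comparison_matrix(labeled, c("plasma_ptau217", "dup"))
  expect_equal(cmp2$pairs$p, 1)
  expect_false(cmp2$pairs$fdr_significant)
})

test_that("ROC curves include both trivial corners and are monotone", {
  set.seed(71)
  labels <- rep(c(TRUE, FALSE), c(40, 30))
  scores <- rnorm(70) + labels
  curve <- roc_curve(scores, labels)
  expect_true(any(curve$sensitivity == 1))
  expect_true(any(curve$specificity == 1))
  expect_true(all(diff(curve$sensitivity) <= 1e-12))
  expect_true(all(diff(curve$specificity) >= -1e-12))
  expect_true(all(curve$sensitivity >= 0 & curve$sensitivity <= 1))
  expect_true(all(curve$specificity >= 0 & curve$specificity <= 1))
})
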