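test_that("perturbation preserves moments at the requested CV", {
  x <- rep(1, 10000)
  expect_identical(perturb_measurements(x, 0), x)
  set.seed(202)
  y <- perturb_measurements(x, 0.25)
  expect_lt(abs(mean(y) - 1), 3 * 0.25 / sqrt(10000))
  expect_gt(sd(y) / mean(y), 0.24)
  expect_lt(sd(y) / mean(y), 0.26)
  # clipping is a tail event: engages only for noise below -99%
  expect_lt(mean(y == 0.01), 1e-3)
  z <- perturb_measurements(rep(1, 2000), 3)  # huge noise: clip must engage
  expect_gt(mean(z == 0.01), 0)
  expect_true(all(z > 0))
  expect_error(perturb_measurements(x, -0.1), class = "bbadx_validation")
})

test_that("independent perturbation of ratio components amplifies the ratio CV by ~sqrt(2)", {
  set.seed(301)
  n <- 50000
  cv <- 0.1
  num <- perturb_measurements(rep(1, n), cv)
  den <- perturb_measurements(rep(1, n), cv)
  ratio_cv <- sd(num / den) / mean(num / den)
  expect_gt(ratio_cv, sqrt(2) * cv * 0.92)
  expect_lt(ratio_cv, sqrt(2) * cv * 1.12)
})

test_that("robustness curves are reproducible, anchored at cv = 0, and bounded", {
  set.seed(7)
  labels <- rep(c(TRUE, FALSE), c(60, 40))
  scores <- ifelse(labels, rlnorm(100, 0.5, 0.5), rlnorm(100, 0, 0.5))
  base <- auc_mann_whitney(scores, labels, variance = FALSE)$auc
  c1 <- robustness_curve(scores, labels, cv_grid = c(0, 0.1, 0.25),
                         replicates = 100, seed = 3)
  c2 <- robustness_curve(scores, labels, cv_grid = c(0, 0.1, 0.25),
                         replicates = 100, seed = 3)
  expect_identical(c1, c2)
  expect_equal(c1$mean_auc[c1$cv == 0], base)
  expect_equal(c1$sd_auc[c1$cv == 0], 0)
  expect_true(all(c1$mean_auc >= 0 & c1$mean_auc <= 1))
  expect_error(robustness_curve(scores, labels, replicates = 1),
               class = "bbadx_validation")
  expect_error(robustness_curve(scores, labels, cv_grid = c(0.1, 0.2)),
               class = "bbadx_validation")
})

test_that("degenerate and well-separated extremes behave as expected", {
  labels <- rep(c(TRUE, FALSE), 25)
  # no signal: all positives equal all negatives -> AUC 0.5 at every cv
  flat <- robustness_curve(rep(2, 50), labels, cv_grid = c(0, 0.2),
                           replicates = 50, seed = 1)
  expect_true(all(abs(flat$mean_auc - 0.5) < 0.05))
  expect_equal(robustness_verdict(flat)$verdict, "robust")
  # huge separation, tiny noise: AUC stays ~1
  big <- c(rep(1000, 25), rep(1, 25))[order(rep(c(1, 2), 25))]
  scores <- ifelse(labels, 1000, 1)
  wide <- robustness_curve(scores, labels, cv_grid = c(0, 0.01),
                           replicates = 50, seed = 2)
  expect_equal(wide$mean_auc[2], 1, tolerance = 1e-6)
})

test_that("mean AUC degrades toward 0.5 as noise grows, monotonically within MC error", {
  set.seed(8)
  labels <- rep(c(TRUE, FALSE), c(200, 200))
  scores <- ifelse(labels, rlnorm(400, 1, 0.4), rlnorm(400, 0.3, 0.4))
  cur <- robustness_curve(scores, labels,
                          cv_grid = c(0, 0.1, 0.25, 0.5, 1, 3),
                          replicates = 300, seed = 4)
  mc_se <- cur$sd_auc / sqrt(cur$replicates)
  slack <- 3 * pmax(mc_se[-1], mc_se[-length(mc_se)])
  expect_true(all(diff(cur$mean_auc) <= slack))
  # at cv = 3 most of the signal is destroyed; what remains is explained by
  # the positivity clip floor (1% of the original value), which preserves
  # rank information among floored draws — check against the independent
  # pair-probability oracle with the same noise law
  got3 <- cur$mean_auc[cur$cv == 3]
  M <- 400000
  noisy <- function(mu) {
    x <- rlnorm(M, mu, 0.4)
    pmax(x * (1 + rnorm(M, 0, 3)), x * 0.01)
  }
  want3 <- mean(noisy(1) > noisy(0.3))
  expect_lt(abs(got3 - want3), 0.04)
  expect_lt(got3, cur$mean_auc[cur$cv == 0] - 0.15)
  expect_gt(got3, 0.5 - 0.02)
})

test_that("noisy AUC matches an independent pair-probability oracle", {
  # binormal-lognormal biomarker; the oracle estimates P(pos' > neg') by
  # direct large-sample simulation of the noise-convolved pair probability,
  # never touching the package's ROC code.
  set.seed(9)
  n <- 400
  labels <- rep(c(TRUE, FALSE), c(n / 2, n / 2))
  mu_pos <- 0.6; mu_neg <- 0; sig <- 0.45
  scores <- ifelse(labels, rlnorm(n, mu_pos, sig), rlnorm(n, mu_neg, sig))
  for (cv in c(0, 0.25)) {
    cur <- robustness_curve(scores, labels, cv_grid = unique(c(0, cv)),
                            replicates = 400, seed = 5)
    got <- cur$mean_auc[cur$cv == cv]
    M <- 400000
    xp <- rlnorm(M, mu_pos, sig) * (1 + rnorm(M, 0, cv))
    xn <- rlnorm(M, mu_neg, sig) * (1 + rnorm(M, 0, cv))
    want <- mean(xp > xn)
    # the curve conditions on one finite sample; allow sampling error of the
    # n=400 cohort plus oracle MC error
    expect_lt(abs(got - want), 0.035)
  }
})

test_that("verdicts classify flat and steep curves correctly", {
  flat <- tibble::tibble(cv = c(0, 0.25), mean_auc = c(0.9, 0.89),
                         sd_auc = c(0, 0.01), replicates = 100)
  steep <- tibble::tibble(cv = c(0, 0.25), mean_auc = c(0.8, 0.65),
                          sd_auc = c(0, 0.02), replicates = 100)
  expect_equal(robustness_verdict(flat)$verdict, "robust")
  expect_equal(robustness_verdict(steep)$verdict, "fragile")
  expect_equal(robustness_verdict(steep)$auc_drop, 0.15, tolerance = 1e-12)
})
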