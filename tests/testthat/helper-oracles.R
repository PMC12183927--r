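# Independent oracles used across the suite. These never call the package's
# ROC code paths: the AUC oracle counts pairs exhaustively, the Youden oracle
# sweeps thresholds by brute force, and the logistic oracle maximizes the
# likelihood directly.

oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  sum(cmp) / (length(pos) * length(neg))
}

oracle_youden <- function(scores, labels) {
  # assumes higher-is-positive orientation; predicate score >= t
  thr <- c(sort(unique(scores)), Inf)
  best <- list(j = -Inf, se = NA, sp = NA, cutoff = NA)
  for (t in thr) {
    se <- mean(scores[labels] >= t)
    sp <- mean(scores[!labels] < t)
    j <- se + sp - 1
    if (j > best$j || (j == best$j && sp > best$sp)) {
      best <- list(j = j, se = se, sp = sp, cutoff = t)
    }
  }
  best
}

oracle_logistic <- function(x, y) {
  # direct ML: coarse grid then Nelder-Mead polish of the log-likelihood
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(eta))) - sum(eta[y])
  }
  grid <- expand.grid(b0 = seq(-5, 5, by = 0.5), b1 = seq(-5, 5, by = 0.5))
  vals <- apply(grid, 1, nll)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 20000))
  fit <- stats::optim(fit$par, nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  fit$par
}

# Within-class bootstrap variance of the Mann-Whitney AUC (independent of
# the DeLong path: uses the pair-counting rank formula directly).
oracle_bootstrap_auc_var <- function(scores, labels, B = 2000) {
  pos <- scores[labels]
  neg <- scores[!labels]
  rank_auc <- function(p, q) {
    r <- rank(c(p, q), ties.method = "average")
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(q))
  }
  stats::var(vapply(seq_len(B), function(b) {
    rank_auc(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
  }, numeric(1)))
}

# Small well-formed cohort CSV for ingestion tests.
write_toy_cohort_csv <- function(path, rows = NULL) {
  base <- data.frame(
    id = c("a", "b", "c"),
    age = c(70, 65, 80),
    sex = c("male", "female", "female"),
    education = c(10, 12, 8),
    mmse = c(25, 28, 20),
    apoe_e4 = c("carrier", "noncarrier", "carrier"),
    diagnosis = c("MCI", "dementia", ""),
    csf_ab42 = c(500, 900, 600),
    csf_ab40 = c(10000, 9500, 11000),
    csf_ttau = c(600, 300, 500),
    csf_ptau181 = c(100, 40, 80),
    plasma_ab42 = c(20, 31, 24),
    plasma_ab40 = c(300, 340, 310),
    plasma_ptau181 = c(3.2, 1.6, 2.8),
    plasma_ptau217 = c(0.8, 0.2, 0.6),
    plasma_nfl = c(35, 48, 40),
    stringsAsFactors = FALSE
  )
  if (!is.null(rows)) base <- rows
  utils::write.csv(base, path, row.names = FALSE)
  base
}

# Fast generator settings for tests that only need a valid labeled cohort.
small_test_config <- function(seed = 1, n_neg = 33, n_pos = 69) {
  default_generator_config(seed = seed, n_neg = n_neg, n_pos = n_pos)
}
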