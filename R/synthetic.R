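#' Moment-matched synthetic memory-clinic cohort
#'
#' The generator emulates the statistical structure of a memory-clinic
#' amyloid study: two groups defined by CSF amyloid status (A-/A+), group
#' sizes 33/69 by default, group-specific demographics (age, sex, education,
#' MMSE, ApoE e4, MCI/dementia mix with a fraction of missing diagnoses), and
#' nine biomarker concentrations drawn from group-specific moment-matched
#' lognormal marginals coupled through a shared latent Gaussian copula.
#'
#' The CSF Abeta42/40 ratio — the quantity that *defines* the reference label
#' — is drawn per group from a truncated normal restricted to the correct
#' side of the 0.069 cut-off, so classifying generated subjects reproduces
#' their assigned group exactly. CSF Abeta40 is then derived as
#' `csf_ab42 / ratio`, keeping the stored concentrations and the label-defining
#' ratio mutually consistent.
#'
#' @name synthetic_cohort
NULL

#' Lognormal parameters from a target mean and sd
#'
#' Moment matching: `sigma^2 = log(1 + (sd/mean)^2)`,
#' `mu = log(mean) - sigma^2/2`. A lognormal with these parameters has
#' exactly the requested mean and sd.
#'
#' @param mean,sd target moments, both positive (sd may be 0 for a point mass)
#' @return list with `mu` and `sigma`
#' @export
lognormal_from_moments <- function(mean, sd) {
  abort_if(mean <= 0 || sd < 0, "mean must be positive and sd nonnegative",
           "bbadx_validation")
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Specification of one biomarker's group-conditional distribution
#'
#' @param name biomarker column name
#' @param mean_neg,sd_neg,mean_pos,sd_pos group-specific moments (pg/ml)
#' @param family `"lognormal"` (default for concentrations) or `"normal"`
#' @param outlier_rate,outlier_scale Bernoulli rate and multiplicative factor
#'   for heavy-tail contamination (see [inject_outliers()])
#' @export
biomarker_spec <- function(name, mean_neg, sd_neg, mean_pos, sd_pos,
                           family = c("lognormal", "normal"),
                           outlier_rate = 0, outlier_scale = 1) {
  family <- match.arg(family)
  abort_if(sd_neg <= 0 || sd_pos <= 0, "sds must be positive",
           "bbadx_validation")
  abort_if(outlier_rate < 0 || outlier_rate > 0.2,
           "outlier_rate must be in [0, 0.2]", "bbadx_validation")
  list(name = name, mean_neg = mean_neg, sd_neg = sd_neg,
       mean_pos = mean_pos, sd_pos = sd_pos, family = family,
       outlier_rate = outlier_rate, outlier_scale = outlier_scale)
}

#' Default generator configuration
#'
#' Transcribes the study-sized defaults: 33 A- and 69 A+ subjects; age
#' 66.9 +/- 8.6 vs 73.0 +/- 6.1 years; ApoE e4 carrier probability 18% vs
#' 49%; MCI share of known diagnoses 9/25 vs 34/67 with an overall 10/102
#' missing-diagnosis rate; and per-group biomarker moments for all nine
#' concentrations. Plasma Abeta42 and Abeta40 carry a 5% outlier rate at
#' scale 3, reflecting the heavy-tailed plasma Abeta42/40 ratio seen in
#' this population. The latent copula uses correlation 0.7 within an analyte
#' family (amyloid: CSF/plasma Abeta42 and plasma Abeta40; tau: tTau,
#' CSF pTau181, plasma pTau181/pTau217) and 0.3 across families.
#'
#' @param seed master seed for all draws
#' @param n_neg,n_pos group sizes
#' @return a generator configuration list
#' @export
default_generator_config <- function(seed = 1L, n_neg = 33L, n_pos = 69L) {
  list(
    seed = as.integer(seed),
    n_neg = as.integer(n_neg),
    n_pos = as.integer(n_pos),
    age = list(mean_neg = 66.9, sd_neg = 8.6, mean_pos = 73.0, sd_pos = 6.1),
    education = list(mean_neg = 10.4, sd_neg = 3.1,
                     mean_pos = 9.4, sd_pos = 4.2),
    mmse = list(mean_neg = 24.2, sd_neg = 4.16, mean_pos = 22.4, sd_pos = 4.21),
    male_prob = list(neg = 12 / 33, pos = 38 / 69),
    apoe_e4_prob = list(neg = 6 / 33, pos = 34 / 69),
    mci_prob = list(neg = 9 / 25, pos = 34 / 67),
    missing_diagnosis_rate = 10 / 102,
    csf_ratio = list(mean_neg = 0.09, sd_neg = 0.01,
                     mean_pos = 0.05, sd_pos = 0.01,
                     cutoff = 0.069, max_attempts = 10000L),
    biomarkers = list(
      biomarker_spec("csf_ab42",       966.09, 410.34, 555.58, 220.33),
      biomarker_spec("csf_ttau",       335.48, 139.22, 643.63, 294.15),
      biomarker_spec("csf_ptau181",     39.26,  16.14, 113.60,  62.01),
      biomarker_spec("plasma_ab42",     30.91,   7.51,  21.41,   9.56,
                     outlier_rate = 0.05, outlier_scale = 3),
      biomarker_spec("plasma_ab40",    347.99,  83.24, 301.99, 127.55,
                     outlier_rate = 0.05, outlier_scale = 3),
      biomarker_spec("plasma_ptau181",   1.68,   0.64,   3.28,   1.77),
      biomarker_spec("plasma_ptau217",   0.18,   0.11,   0.83,   0.56),
      biomarker_spec("plasma_nfl",      47.73,  34.24,  34.78,  28.84)
    ),
    correlation = list(within = 0.7, across = 0.3),
    mmse_model = NULL
  )
}

#' Read / write a generator configuration as YAML
#' @param path YAML file path
#' @return configuration list
#' @export
read_generator_config <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path), "bbadx_io")
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_neg <- as.integer(cfg$n_neg)
  cfg$n_pos <- as.integer(cfg$n_pos)
  validate_generator_config(cfg)
  cfg
}

#' @rdname read_generator_config
#' @param config configuration list
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_generator_config <- function(config) {
  abort_if(config$n_neg < 2 || config$n_pos < 2,
           "group sizes must be >= 2", "bbadx_validation")
  probs <- c(config$male_prob$neg, config$male_prob$pos,
             config$apoe_e4_prob$neg, config$apoe_e4_prob$pos,
             config$mci_prob$neg, config$mci_prob$pos,
             config$missing_diagnosis_rate)
  abort_if(any(probs < 0 | probs > 1), "probabilities must be in [0, 1]",
           "bbadx_validation")
  for (spec in config$biomarkers) {
    abort_if(spec$sd_neg <= 0 || spec$sd_pos <= 0,
             sprintf("nonpositive sd for %s", spec$name), "bbadx_validation")
    abort_if(spec$outlier_rate < 0 || spec$outlier_rate > 0.2,
             sprintf("outlier_rate out of [0, 0.2] for %s", spec$name),
             "bbadx_validation")
  }
  invisible(config)
}

# Correlation matrix over the biomarker primaries: `within` inside an analyte
# family, `across` between families. Positive definite for within > across
# in [0, 1).
latent_correlation_matrix <- function(names, within, across) {
  families <- list(
    amyloid = c("csf_ab42", "plasma_ab42", "plasma_ab40"),
    tau = c("csf_ttau", "csf_ptau181", "plasma_ptau181", "plasma_ptau217"),
    nfl = c("plasma_nfl")
  )
  fam_of <- function(nm) {
    hit <- names(families)[vapply(families, function(f) nm %in% f, logical(1))]
    if (length(hit) == 0) "other" else hit[1]
  }
  fams <- vapply(names, fam_of, character(1))
  R <- outer(fams, fams, function(a, b) ifelse(a == b, within, across))
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  abort_if(min(ev) <= 1e-10, "latent correlation is not positive definite",
           "bbadx_validation")
  R
}

# Truncated-normal draws by rejection, capped; side = "above" keeps x > bound,
# "below" keeps x < bound.
rtruncnorm_reject <- function(n, mean, sd, bound, side, max_attempts = 10000L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_attempts)) {
      x <- stats::rnorm(1, mean, sd)
      if (x > 0 &&
          ((side == "above" && x > bound) || (side == "below" && x < bound))) {
        out[i] <- x
        ok <- TRUE
        break
      }
    }
    abort_if(!ok, sprintf(
      "rejection sampling failed after %d attempts (mean %.3g, sd %.3g on wrong side of %.3g)",
      max_attempts, mean, sd, bound), "bbadx_validation")
  }
  out
}

#' Inject multiplicative heavy-tail outliers
#'
#' A Bernoulli(`rate`) subset of the values is multiplied by `scale` or
#' divided by it, with equal probability; the rest are returned unchanged.
#'
#' @param values positive numeric vector
#' @param rate outlier probability, in \[0, 0.2\]
#' @param scale multiplicative factor, >= 1
#' @return perturbed vector
#' @export
inject_outliers <- function(values, rate, scale) {
  abort_if(rate < 0 || rate > 0.2, "rate must be in [0, 0.2]",
           "bbadx_validation")
  abort_if(scale < 1, "scale must be >= 1", "bbadx_validation")
  hit <- stats::runif(length(values)) < rate
  up <- stats::runif(length(values)) < 0.5
  factor <- ifelse(hit, ifelse(up, scale, 1 / scale), 1)
  values * factor
}

#' Generate a synthetic cohort
#'
#' Fully deterministic given `config$seed`. Each generation stage
#' (demographics, latent copula, reference ratio, outliers, MMSE) draws from
#' its own substream of the master seed, so changing one stage's parameters
#' does not perturb the draws of the others.
#'
#' If `config$mmse_model` is non-NULL it must be a list with fields
#' `intercept`, `beta_mci`, `biomarker`, `beta_biomarker`, `sd`; MMSE is then
#' generated as
#' `intercept + beta_mci * 1(MCI) + beta_biomarker * biomarker + N(0, sd)`
#' (unclipped, for coefficient-recovery studies) instead of from the group
#' moments.
#'
#' @param config a generator configuration, see [default_generator_config()]
#' @return a labeled cohort tibble (with `group` = assigned truth,
#'   `a_status` from classification, derived ratio columns)
#' @export
generate_cohort <- function(config = default_generator_config()) {
  validate_generator_config(config)
  n_neg <- config$n_neg
  n_pos <- config$n_pos
  n <- n_neg + n_pos
  group <- rep(c("Aneg", "Apos"), c(n_neg, n_pos))
  is_pos <- group == "Apos"
  seed <- config$seed

  demo <- with_stage_seed(seed, "demographics", {
    age <- ifelse(is_pos,
                  stats::rnorm(n, config$age$mean_pos, config$age$sd_pos),
                  stats::rnorm(n, config$age$mean_neg, config$age$sd_neg))
    age <- pmax(age, 40)
    edu <- ifelse(is_pos,
                  stats::rnorm(n, config$education$mean_pos,
                               config$education$sd_pos),
                  stats::rnorm(n, config$education$mean_neg,
                               config$education$sd_neg))
    edu <- pmax(edu, 0)
    male <- stats::runif(n) < ifelse(is_pos, config$male_prob$pos,
                                     config$male_prob$neg)
    apoe <- stats::runif(n) < ifelse(is_pos, config$apoe_e4_prob$pos,
                                     config$apoe_e4_prob$neg)
    mci <- stats::runif(n) < ifelse(is_pos, config$mci_prob$pos,
                                    config$mci_prob$neg)
    miss <- stats::runif(n) < config$missing_diagnosis_rate
    diagnosis <- ifelse(miss, "missing", ifelse(mci, "MCI", "dementia"))
    list(age = age, education = edu,
         sex = ifelse(male, "male", "female"),
         apoe_e4 = ifelse(apoe, "carrier", "noncarrier"),
         diagnosis = diagnosis)
  })

  specs <- config$biomarkers
  nm <- vapply(specs, `[[`, character(1), "name")
  R <- latent_correlation_matrix(nm, config$correlation$within,
                                 config$correlation$across)
  X <- with_stage_seed(seed, "copula", {
    Z <- matrix(stats::rnorm(n * length(nm)), n, length(nm)) %*% chol(R)
    U <- stats::pnorm(Z)
    X <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      for (g in c(FALSE, TRUE)) {
        rows <- is_pos == g
        m <- if (g) sp$mean_pos else sp$mean_neg
        s <- if (g) sp$sd_pos else sp$sd_neg
        if (sp$family == "lognormal") {
          par <- lognormal_from_moments(m, s)
          X[rows, j] <- stats::qlnorm(U[rows, j], par$mu, par$sigma)
        } else {
          X[rows, j] <- stats::qnorm(U[rows, j], m, s)
        }
      }
    }
    X
  })

  X <- with_stage_seed(seed, "outliers", {
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      if (sp$outlier_rate > 0) {
        X[, j] <- inject_outliers(X[, j], sp$outlier_rate, sp$outlier_scale)
      }
    }
    X
  })

  ratio <- with_stage_seed(seed, "reference_ratio", {
    rc <- config$csf_ratio
    r <- numeric(n)
    r[!is_pos] <- rtruncnorm_reject(n_neg, rc$mean_neg, rc$sd_neg,
                                    rc$cutoff, "above", rc$max_attempts)
    r[is_pos] <- rtruncnorm_reject(n_pos, rc$mean_pos, rc$sd_pos,
                                   rc$cutoff, "below", rc$max_attempts)
    r
  })

  mmse <- with_stage_seed(seed, "mmse", {
    mm <- config$mmse_model
    if (is.null(mm)) {
      v <- ifelse(is_pos,
                  stats::rnorm(n, config$mmse$mean_pos, config$mmse$sd_pos),
                  stats::rnorm(n, config$mmse$mean_neg, config$mmse$sd_neg))
      pmin(pmax(v, 0), 30)
    } else {
      mm$intercept + mm$beta_mci * (demo$diagnosis == "MCI") +
        mm$beta_biomarker * X[, mm$biomarker] +
        stats::rnorm(n, 0, mm$sd)
    }
  })

  cohort <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    group = group,
    age = demo$age,
    sex = demo$sex,
    education = demo$education,
    mmse = mmse,
    apoe_e4 = demo$apoe_e4,
    diagnosis = demo$diagnosis
  )
  for (j in seq_along(nm)) cohort[[nm[j]]] <- X[, j]
  # CSF Abeta40 derived so that csf_ab42/csf_ab40 equals the label-defining
  # truncated ratio exactly.
  cohort$csf_ab40 <- cohort$csf_ab42 / ratio
  cohort <- add_derived_ratios(cohort)
  cohort$a_status <- classify_amyloid(cohort$csf_ab42_40)
  cohort$a_positive <- cohort$a_status == "Apos"
  # an injected MMSE model is an unclipped linear score for recovery studies
  validate_cohort(cohort, check_mmse_range = is.null(config$mmse_model))
  cohort
}
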