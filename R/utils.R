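#' @importFrom rlang .data
#' @importFrom stats median sd quantile rnorm runif rbinom qnorm pnorm
#'   shapiro.test t.test wilcox.test chisq.test p.adjust lm glm binomial
#'   coef vcov pf pt complete.cases as.formula predict setNames
#' @importFrom utils read.csv write.csv
NULL

# Deterministic substream seeds: one master seed fans out to named stages so
# that adding a pipeline stage does not perturb the draws of earlier ones.
# Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629L)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(stage_seed(seed, stage))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

abort_if <- function(cond, msg, class = "bbadx_error") {
  if (cond) stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(NULL)
}
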