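#' Full diagnostic-evaluation pipeline
#'
#' Orchestrates the whole analysis on a cohort (read from CSV or generated):
#' reference labeling, group contrasts, per-biomarker logistic models and ROC
#' cut-off reports, all-pairs DeLong comparison of the plasma panel,
#' two-cut-off reports, MMSE linear models, and the measurement-noise
#' robustness simulation. All outputs are plain CSV plus a JSON manifest; two
#' runs with the same configuration and seed produce identical bundles.
#'
#' @name reporting
NULL

#' Plasma and CSF biomarker panels used in the reports
#' @export
plasma_panel <- function() {
  c("plasma_ab42", "plasma_ab40", "plasma_ab42_40",
    "plasma_ptau181", "plasma_ptau217", "plasma_nfl")
}

#' @rdname plasma_panel
#' @export
csf_panel <- function() {
  # csf_ab42_40 is omitted: it defines the reference label, so its ROC
  # against that label is circular.
  c("csf_ab42", "csf_ab40", "csf_ttau", "csf_ptau181",
    "csf_ab42_ttau", "csf_ab42_ptau")
}

#' Per-biomarker diagnostic summary (logistic + ROC + Youden cut-off)
#'
#' One row per biomarker: standardized logistic coefficient and Wald p,
#' Youden-optimal cut-off with SE/SP/PPV/NPV, and the DeLong AUC with 95% CI.
#'
#' @param cohort labeled cohort
#' @param biomarkers columns to evaluate
#' @param prevalence prevalence for predictive values (default: sample)
#' @return tibble
#' @export
diagnostic_summary_table <- function(cohort, biomarkers, prevalence = NULL) {
  dplyr::bind_rows(lapply(biomarkers, function(b) {
    lg <- logistic_biomarker_model(cohort, b)
    curve <- roc_curve(cohort[[b]], cohort$a_positive)
    yc <- youden_cutoff(curve, prevalence)
    a <- auc_mann_whitney(cohort[[b]], cohort$a_positive)
    tibble::tibble(
      biomarker = b,
      st_coefficient = lg$standardized_coefficient,
      p = lg$p,
      cutoff = yc$cutoff,
      orientation = yc$orientation,
      auc = a$auc, auc_ci_low = a$ci95_low, auc_ci_high = a$ci95_high,
      sensitivity = yc$sensitivity, specificity = yc$specificity,
      ppv = yc$ppv, npv = yc$npv
    )
  }))
}

#' Run the full pipeline and write a report bundle
#'
#' @param config list with fields:
#'   `input` — either a cohort CSV path (`list(csv = path)`) or a generator
#'   configuration (`list(generator = config)`);
#'   `reference` — `"csf_ab42_40"` (default) or `"csf_ab42_ptau"`;
#'   `subset` — `"all"` (default) or `"MCI"`;
#'   `prevalence` — optional override for predictive values;
#'   `cv_grid`, `replicates` — robustness settings;
#'   `seed` — master seed;
#'   `out_dir` — output directory.
#' @return (invisibly) list of written file paths and the manifest
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  abort_if(is.null(out_dir), "config$out_dir is required", "bbadx_validation")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else config$seed
  subset <- if (is.null(config$subset)) "all" else config$subset
  reference <- if (is.null(config$reference)) "csf_ab42_40" else config$reference
  cv_grid <- if (is.null(config$cv_grid)) seq(0, 0.25, by = 0.025) else config$cv_grid
  replicates <- if (is.null(config$replicates)) 500 else config$replicates

  stage <- "input"
  paths <- list()
  manifest <- list(seed = seed, reference = reference, subset = subset,
                   package_version = as.character(utils::packageVersion("bbadx")))
  tryCatch({
    cohort <- if (!is.null(config$input$csv)) {
      read_cohort(config$input$csv, schema = config$input$schema)
    } else {
      gen <- config$input$generator
      if (is.null(gen)) gen <- default_generator_config(seed = seed)
      generate_cohort(gen)
    }
    manifest$n_input <- nrow(cohort)
    manifest$n_excluded_input <- attr(cohort, "n_excluded")
    if (is.null(manifest$n_excluded_input)) manifest$n_excluded_input <- 0L

    stage <- "label"
    std <- reference_standard(reference)
    labeled <- label_cohort(cohort, std, subset = subset)
    manifest$n_analyzed <- nrow(labeled)
    manifest$n_positive <- sum(labeled$a_positive)
    prevalence <- if (is.null(config$prevalence)) {
      mean(labeled$a_positive)
    } else config$prevalence

    stage <- "group_comparison"
    panel <- c(csf_panel(), plasma_panel())
    gc_tab <- group_comparison_table(labeled, panel)
    paths$group_comparison <- write_report(gc_tab, out_dir,
                                           "group_comparison.csv", "table2")

    stage <- "diagnostics"
    diag_tab <- diagnostic_summary_table(labeled, panel, prevalence)
    paths$diagnostics <- write_report(diag_tab, out_dir,
                                      "diagnostic_summary.csv", "table3")

    stage <- "auc_comparison"
    cmp <- auc_comparison_matrix(labeled, plasma_panel())
    paths$auc_comparison <- write_report(cmp$pairs, out_dir,
                                         "auc_comparisons.csv", "table4")

    stage <- "two_cutoffs"
    tc <- dplyr::bind_rows(lapply(plasma_panel(), function(b) {
      curve <- roc_curve(labeled[[b]], labeled$a_positive)
      r <- two_cutoffs(curve, prevalence = prevalence)
      r$biomarker <- b
      r$intermediate_fraction <- attr(r, "intermediate_fraction")
      r
    }))
    paths$two_cutoffs <- write_report(tc, out_dir, "two_cutoffs.csv", "fig4")

    stage <- "models"
    mmse_tab <- dplyr::bind_rows(lapply(plasma_panel(), function(b) {
      m <- tryCatch(mmse_linear_model(labeled, b), error = function(e) NULL)
      if (is.null(m)) return(NULL)
      m$terms$biomarker_model <- b
      m$terms$model_p <- m$model_p
      m$terms
    }))
    paths$mmse_models <- write_report(mmse_tab, out_dir,
                                      "mmse_models.csv", "table5")

    stage <- "robustness"
    rb <- dplyr::bind_rows(lapply(
      c("plasma_ptau217", "plasma_ptau181", "plasma_ab42_40"), function(b) {
        comp <- if (b == "plasma_ab42_40") {
          cbind(labeled$plasma_ab42, labeled$plasma_ab40)
        } else NULL
        cv <- robustness_curve(labeled[[b]], labeled$a_positive,
                               cv_grid = cv_grid, replicates = replicates,
                               seed = seed, components = comp)
        cv$biomarker <- b
        cv
      }))
    paths$robustness <- write_report(rb, out_dir, "robustness.csv",
                                     "robustness")

    manifest$reports <- vapply(paths, identity, character(1))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths$manifest <- manifest_path
    invisible(list(paths = paths, manifest = manifest))
  }, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
      class = c("bbadx_pipeline_error", "error", "condition")))
  })
}

# Rounding conventions of the printed tables: effect sizes to 1 decimal,
# AUC/SE/SP to 3, PPV/NPV to 2.
style_rounding <- list(
  table2 = c(d = 1, d_ci_low = 1, d_ci_high = 1, pct_median_diff = 1),
  table3 = c(auc = 3, auc_ci_low = 3, auc_ci_high = 3,
             sensitivity = 3, specificity = 3, ppv = 2, npv = 2,
             st_coefficient = 2),
  table4 = c(p = 3, p_fdr = 3, auc_a = 3, auc_b = 3, z = 2),
  table5 = c(coefficient = 3, se = 3, p = 3, model_p = 3),
  fig4 = c(sensitivity = 3, specificity = 3, ppv = 2, npv = 2,
           intermediate_fraction = 3),
  robustness = c(mean_auc = 3, sd_auc = 3),
  table1 = c()
)

#' Render a result tibble as CSV text with table-style rounding
#'
#' @param result a tibble produced by a pipeline stage
#' @param style one of `"table1"` ... `"table5"`, `"fig4"`, `"robustness"`
#' @return CSV text (character scalar)
#' @export
render_table <- function(result, style) {
  abort_if(!style %in% names(style_rounding),
           sprintf("unknown style '%s'", style), "bbadx_validation")
  abort_if(!is.data.frame(result), "result must be a data frame",
           "bbadx_validation")
  digits <- style_rounding[[style]]
  out <- as.data.frame(result)
  for (col in names(digits)) {
    if (col %in% names(out)) out[[col]] <- round(out[[col]], digits[[col]])
  }
  con <- textConnection("csv_text", "w", local = TRUE)
  utils::write.csv(out, con, row.names = FALSE)
  close(con)
  paste0(paste(csv_text, collapse = "\n"), "\n")
}

write_report <- function(result, out_dir, filename, style) {
  path <- file.path(out_dir, filename)
  writeLines(render_table(result, style), path, sep = "")
  path
}
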