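#!/usr/bin/env Rscript
# Per-biomarker diagnostic performance: standardized logistic coefficients,
# DeLong AUC with 95% CI, Youden-optimal cut-offs with predictive values, and
# the dual 95%-sensitivity / 95%-specificity cut-offs for the plasma panel.

suppressPackageStartupMessages(library(bbadx))

labeled <- label_cohort(read_cohort("results/cohort.csv"))
panel <- c(csf_panel(), plasma_panel())

diag_tab <- diagnostic_summary_table(labeled, panel)
writeLines(render_table(diag_tab, "table3"), "results/diagnostic_summary.csv")

# outlier-excluded refit for the plasma ratio, which is outlier-sensitive
raw <- logistic_biomarker_model(labeled, "plasma_ab42_40")
clean <- logistic_biomarker_model(labeled, "plasma_ab42_40",
                                  exclude_outliers = TRUE)
message(sprintf(
  "plasma Abeta42/40 standardized coefficient %.2f -> %.2f after excluding %d outliers",
  raw$standardized_coefficient, clean$standardized_coefficient,
  clean$outliers_excluded))

tc <- dplyr::bind_rows(lapply(plasma_panel(), function(b) {
  curve <- roc_curve(labeled[[b]], labeled$a_positive)
  r <- two_cutoffs(curve)
  r$biomarker <- b
  r$intermediate_fraction <- attr(r, "intermediate_fraction")
  r
}))
writeLines(render_table(tc, "fig4"), "results/two_cutoffs.csv")

best <- diag_tab[which.max(diag_tab$auc), ]
message(sprintf("best plasma/CSF marker: %s, AUC %.3f [%.3f, %.3f]",
                best$biomarker, best$auc, best$auc_ci_low, best$auc_ci_high))
message("wrote results/diagnostic_summary.csv, results/two_cutoffs.csv")
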