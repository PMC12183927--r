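#!/usr/bin/env Rscript
# MMSE linear models: one plasma biomarker per model plus diagnosis, age,
# ApoE, sex, and the biomarker-by-diagnosis interaction; education added as a
# sensitivity check.

suppressPackageStartupMessages(library(bbadx))

cohort <- read_cohort("results/cohort.csv")
tabs <- lapply(plasma_panel(), function(b) {
  m <- mmse_linear_model(cohort, b)
  m$terms$biomarker_model <- b
  m$terms$model_p <- m$model_p
  m$terms
})
tab <- dplyr::bind_rows(tabs)
writeLines(render_table(tab, "table5"), "results/mmse_models.csv")

tab_edu <- dplyr::bind_rows(lapply(plasma_panel(), function(b) {
  m <- mmse_linear_model(cohort, b, include_education = TRUE)
  m$terms$biomarker_model <- b
  m$terms
}))
writeLines(render_table(tab_edu, "table5"), "results/mmse_models_education.csv")

bio <- tab[tab$term == "biomarker", ]
message("plasma biomarker terms (coefficient, p):")
for (i in seq_len(nrow(bio))) {
  message(sprintf("  %-16s %8.3f  p = %.3f", bio$biomarker_model[i],
                  bio$coefficient[i], bio$p[i]))
}
m1 <- mmse_linear_model(cohort, "plasma_ptau217")
message(sprintf("subjects excluded for missing diagnosis: %d", m1$n_excluded))
message("wrote results/mmse_models.csv, results/mmse_models_education.csv")
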