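#!/usr/bin/env Rscript
# Contrast each CSF and plasma biomarker between amyloid groups: normality-
# routed tests, percent median difference, Cohen's d, age/sex-adjusted
# p-values, and FDR/Bonferroni flags.

suppressPackageStartupMessages(library(bbadx))

labeled <- label_cohort(read_cohort("results/cohort.csv"))
panel <- c(csf_panel(), plasma_panel())
tab <- group_comparison_table(labeled, panel)
writeLines(render_table(tab, "table2"), "results/group_differences.csv")

message(sprintf("%d of %d biomarkers significant after FDR",
                sum(tab$fdr_significant), nrow(tab)))
message(sprintf("largest effects: %s",
                paste(tab$biomarker[order(-abs(tab$d))][1:3], collapse = ", ")))
message(sprintf("tests routed to Wilcoxon: %d of %d",
                sum(tab$test_used == "wilcoxon"), nrow(tab)))
message("wrote results/group_differences.csv")
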