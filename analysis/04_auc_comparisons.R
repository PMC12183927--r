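#!/usr/bin/env Rscript
# Head-to-head DeLong comparisons of the six plasma biomarkers' AUCs with
# Benjamini-Hochberg control over the 15 pairwise tests.

suppressPackageStartupMessages(library(bbadx))

labeled <- label_cohort(read_cohort("results/cohort.csv"))
cmp <- auc_comparison_matrix(labeled, plasma_panel())
writeLines(render_table(cmp$pairs, "table4"), "results/auc_comparisons.csv")
write.csv(round(cmp$p_matrix, 4), "results/auc_p_matrix.csv")

message("plasma AUCs (oriented):")
print(round(sort(cmp$auc, decreasing = TRUE), 3))
sig <- cmp$pairs[cmp$pairs$fdr_significant, c("biomarker_a", "biomarker_b")]
message(sprintf("%d of 15 pairwise differences significant after FDR",
                nrow(sig)))
message("wrote results/auc_comparisons.csv, results/auc_p_matrix.csv")
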