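#!/usr/bin/env Rscript
# Reversal-fold analysis: recompute, for every treatment, the fold change in
# daunorubicin IC50 caused by each flavonoid in KB/MDR1 and KB cells, classify
# potential P-gp inhibitors/activators, and diff against the published folds.

suppressPackageStartupMessages(library(flavoqsar))

rt <- reversal_table(load_fixture("cytotoxicity"),
                     printed = load_fixture("reversal_printed"))

dir.create("results", showWarnings = FALSE)
write_table(rt, "results/reversal_report.csv")

flav <- rt[!rt$treatment_id %in% c("negative_control", "elacridar"), ]
top <- flav[order(-flav$rf_mdr1), ][1:3, ]
cat("Top reversal folds in KB/MDR1 cells:\n")
print(top[c("treatment_id", "rf_mdr1", "classification")], row.names = FALSE)

cat("\nPotential activators (RF_KB/MDR1 < 1):",
    paste(flav$treatment_id[flav$classification == "potential_activator"],
          collapse = ", "), "\n")
cat("\nBaseline cross-resistance of KB/MDR1 vs KB (no inhibitor):",
    sprintf("%.3f-fold\n",
            rt$rf_cross[rt$treatment_id == "negative_control"]))
cat("Rows whose published folds cannot be reproduced from the published",
    "IC50 means:", paste(rt$treatment_id[rt$inconsistent], collapse = ", "),
    "\n")
cat("\nWrote results/reversal_report.csv (", nrow(rt), "treatments )\n")
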