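#!/usr/bin/env Rscript
# Step 3: full-scale threshold-grid search. A 100-patient cohort at the
# generator's default conditions (64^3 voxel grid, 49% pCR rate, default
# shrinkage/kinetics) is generated patient-by-patient (streamed; the whole
# cohort is never held in memory) and analyzed end to end: per-patient FTV
# grids -> cohort AUC surface per timepoint and early phase -> optimal
# (PE, SER) pair per surface -> group statistics at that pair.
#
# Output: results/full_report/ (CSV/JSON report files),
#         results/c2_vs_c4.csv, scratch/full_report.rds

library(ftvdce)

cfg <- cohort_config(seed = 20230206)
cat(sprintf("Analyzing a streamed n=%d cohort at %s voxels...\n",
            cfg$n_patients, paste(cfg$grid_shape, collapse = "x")))
report <- analyze_cohort(cfg, refine = FALSE)
write_report(report, "results/full_report")
dir.create("scratch", showWarnings = FALSE)
saveRDS(report, "scratch/full_report.rds")

cmp <- compare_timepoints(report)
write.csv(cmp, "results/c2_vs_c4.csv", row.names = FALSE)

ftv1 <- report$table_ftv[report$table_ftv$measurement == "FTV at 1 min", ]
cat("\nFTV at 1 min, AUC by timepoint:\n")
print(ftv1[, c("timepoint", "pe", "ser", "auc", "ci_low", "ci_high", "p_value")],
      row.names = FALSE, digits = 3)
cat(sprintf(
  "\nOn-treatment FTV discriminates pCR from non-pCR (C4 AUC %.2f, C2 AUC %.2f)\nwhile baseline FTV does not (BL AUC %.2f) -- the generator encodes response\nas volume shrinkage, not a baseline signature.\n",
  ftv1$auc[ftv1$timepoint == "C4"], ftv1$auc[ftv1$timepoint == "C2"],
  ftv1$auc[ftv1$timepoint == "BL"]))
cat("Report written to results/full_report/, C2-vs-C4 table to results/c2_vs_c4.csv\n")
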