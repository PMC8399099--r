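#!/usr/bin/env Rscript
# Step 4: operating characteristics of the optimal-cutpoint screen.
#
# (a) Global-null inflation: on 500 survival-independent genes, how often
#     does each strategy reach raw p < 0.05?
# (b) Cutpoint recovery: with a step effect planted at the 40th percentile
#     (HR 2.5), how close is the selected cut, and does the covariate-
#     adjusted Cox CI at the true split cover the planted HR?
# (c) Consensus operating characteristics over 50 paired-cohort runs.
# Self-contained; uses its own seeds.

library(survscreen)
dir.create("results/characterization", recursive = TRUE, showWarnings = FALSE)

cat("== Minimum-p inflation under the global null ==\n")
inf <- experiment_null_inflation(n_patients = 400, n_genes = 500, seed = 2026)
cat(sprintf("optimal-cut raw p<0.05: %.1f%% of genes (inflation x%.1f); median-cut: %.1f%%\n",
            100 * inf$optimal_fraction, inf$optimal_fraction / 0.05,
            100 * inf$median_fraction))

cat("\n== Cutpoint-location recovery (q = 0.4, HR = 2.5, 200 replicates) ==\n")
rec <- experiment_cut_recovery(seed = 2026)
cat(sprintf("median |cut - 0.4| = %.1f percentile points; 95%% CI coverage of HR 2.5: %.1f%%\n",
            100 * rec$median_abs_error, 100 * rec$ci_coverage))

cat("\n== Two-cohort consensus over 50 runs (3 planted among 300 nulls) ==\n")
cons <- experiment_consensus(seed = 2026)
cat(sprintf("all three recovered with correct direction: %.0f%% of runs\n",
            100 * cons$full_recovery_rate))
cat(sprintf("mean planted genes recovered: %.2f of 3; false positives: mean %.2f, max %d\n",
            cons$mean_recovered, cons$mean_false_positives,
            cons$max_false_positives))
cat("(The gene planted off-median at q = 0.65 is the usual dropout: its\n")
cat(" median-split hazard ratio is attenuated toward the 1.8 gate - see the\n")
cat(" methods vignette on validation-stage attenuation.)\n")

summary_tab <- data.frame(
  quantity = c("null_optimal_sig_fraction", "null_median_sig_fraction",
               "cut_recovery_median_error", "hr_ci_coverage",
               "consensus_full_recovery_rate", "consensus_mean_false_positives"),
  value = c(inf$optimal_fraction, inf$median_fraction, rec$median_abs_error,
            rec$ci_coverage, cons$full_recovery_rate,
            cons$mean_false_positives)
)
write.table(summary_tab, "results/characterization/operating_characteristics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cons$runs, "results/characterization/consensus_runs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nTables written under results/characterization/.\n")
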