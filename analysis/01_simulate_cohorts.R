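#!/usr/bin/env Rscript
# Step 1: generate the paired synthetic cohorts used throughout the analysis.
#
# Two independent 400-patient cohorts share one gene panel: 300 null genes
# plus three planted threshold effects - a protective step (HR 0.4) at the
# 35th expression percentile, and harmful steps (HR 2.5) at the 50th and
# 65th. Cohort 1 plays the discovery role, cohort 2 the validation role.
# The large per-cohort TSVs are regenerable scratch; only summary tables go
# under results/.

library(survscreen)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/cohorts", recursive = TRUE, showWarnings = FALSE)

panel <- gene_effects(300, data.frame(q = c(0.35, 0.50, 0.65),
                                      hr = c(0.4, 2.5, 2.5)))
seed <- 2026L

for (role in c("discovery", "validation")) {
  s <- if (role == "discovery") seed else seed + 1L
  sim <- simulate_dataset(sim_config(400, panel, seed = s))
  write_simulation(sim, file.path("scratch/cohorts", role))
  cat(sprintf("%s cohort: %d patients, %d genes, %.1f%% censored, %d events\n",
              role, nrow(sim$dataset$clinical), nrow(sim$dataset$expression),
              100 * sim$truth$censoring_fraction,
              sum(sim$dataset$clinical$event)))
  summ <- summarize_cohort(sim$dataset$clinical)
  write.table(summ, file.path("results", paste0("cohort_", role, "_summary.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("\nPlanted truth:\n")
print(panel[panel$kind == "threshold", ], row.names = FALSE)
cat("\nCohorts written to scratch/cohorts/{discovery,validation}; summaries in results/.\n")
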