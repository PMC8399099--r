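#!/usr/bin/env Rscript
# Step 3: median-cutpoint validation and two-cohort consensus.
#
# The validation cohort is screened at fixed median cutpoints (no optimal-cut
# optimism) with FDR correction; discovery candidates must independently pass
# FDR < 0.05 plus the same HR gate, with the same effect direction, to enter
# the consensus list. Requires steps 1-2.

library(survscreen)

validation <- filter_dataset_genes(read_dataset("scratch/cohorts/validation"))
disc_tab <- read.delim("results/discovery/candidates.tsv", comment.char = "#")

val <- run_validation(validation, disc_tab, out_dir = "results/validation")
print(val)
cat("\nPer-candidate validation status:\n")
print(val$consensus[, c("gene", "direction", "validation_status",
                        "validation_uni_hr", "validation_multi_hr")],
      row.names = FALSE)

truth <- jsonlite::read_json("scratch/cohorts/discovery/truth.json",
                             simplifyVector = TRUE)
planted <- truth$effects$gene[truth$effects$kind == "threshold"]
cat(sprintf("\nConsensus: %s\nPlanted:   %s\n",
            paste(val$consensus_genes, collapse = ", "),
            paste(planted, collapse = ", ")))

# hazard-ratio concordance between the cohorts over the discovery candidates
both <- merge(disc_tab[, c("gene", "multi_hr")],
              val$results[, c("gene", "multi_hr")], by = "gene",
              suffixes = c("_discovery", "_validation"))
both <- both[complete.cases(both), ]
if (nrow(both) >= 3) {
  r <- hr_concordance(both$multi_hr_discovery, both$multi_hr_validation)
  cat(sprintf("\nHR concordance across cohorts (Pearson r, %d genes): %.2f\n",
              nrow(both), r))
  write.table(both, "results/validation/hr_concordance.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("\nTables written under results/validation/.\n")
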