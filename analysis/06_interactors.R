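#!/usr/bin/env Rscript
# Refine checkpoint-interacting proteins by the four evidence criteria
# (experimental validation, redundancy across checkpoints, OS association,
# lung-tissue support) and summarize the expression-by-outcome quadrants.
# Runs on the synthetic interaction/annotation tables shipped with the
# package; any database export in the same TSV contract drops in.

source("analysis/00_config.R")

it <- read_interactions(system.file("extdata",
                                    "icp_interactions_synthetic.tsv",
                                    package = "icprofiler"))
an <- read_annotations(system.file("extdata",
                                   "icp_annotations_synthetic.tsv",
                                   package = "icprofiler"))
icp_set <- c("PD-1", "PD-L1", "TIM-3", "LAG-3", "BTLA", "TIGIT", "CD26",
             "CD39", "CD73")

ref <- refine_interactors(it, an, icp_set, tissue = "lung")
write.table(ref, file.path(RESULTS, "refined_interactors.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
message(sprintf("candidates: %d; refined by all four criteria: %d",
                nrow(ref), sum(ref$pass)))

qs <- quadrant_summary(ref)
write.csv(as.data.frame.table(qs$counts),
          file.path(RESULTS, "interactor_quadrants.csv"),
          row.names = FALSE)
write.csv(qs$icp_degree, file.path(RESULTS, "icp_degree.csv"),
          row.names = FALSE)
pos <- 100 * sum(qs$counts[, "positive"]) / qs$n
inc <- 100 * qs$counts["increased", "positive"] /
  sum(qs$counts[, "positive"])
message(sprintf(
  "%.1f%% of refined interactors have positive OS association; %.1f%% of those also show increased tumor expression",
  pos, inc))
message(sprintf("most connected checkpoint: %s (%d refined interactors)",
                qs$icp_degree$icp[1], qs$icp_degree$degree[1]))
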