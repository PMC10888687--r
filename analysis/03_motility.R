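#!/usr/bin/env Rscript
# Step 3 -- motility subpopulations.
#
# Classifies per-cell motility (progressive: VCL > 25 um/s and STR > 45%),
# pools motile cells over all samples and extracts swimming-pattern
# subpopulations by the two-stage scheme (k-means compression, Ward linkage
# on the stage-1 centroids, silhouette-selected k). Writes the
# median +/- MAD subpopulation summary and the per-sample percentages.

library(spermchrom)

study <- readRDS("scratch/study.rds")
mot <- analyze_motility(study)

readr::write_csv(mot$cluster_summary, "results/motility_subpopulations.csv")
readr::write_csv(mot$per_sample, "results/motility_per_sample.csv")

message("final number of subpopulations: ", mot$model$final_k)
message("silhouette by candidate k:")
print(round(mot$model$silhouette, 3))
message("subpopulation summary (median per cluster):")
print(tidyr::pivot_wider(mot$cluster_summary[, c("cluster", "variable",
                                                 "median")],
                         names_from = "variable", values_from = "median"))
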