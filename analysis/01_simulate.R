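#!/usr/bin/env Rscript
# Step 1 -- simulate the study.
#
# Generates the full synthetic boar study emulated by the package: 36 boars
# x 3 ejaculates x 2 analysis days (D0 fresh, D11 after cooled storage),
# 5000 cytometry events per sample and assay (SCSA, paired mBBr, CMA3,
# 8-oxo-dG, two physiology panels) and 500 CASA tracks per sample, with
# boar- and ejaculate-level random effects and fixed storage-day shifts on
# every truth parameter. Writes the design and per-sample theoretical truth
# to results/ and caches the event-level study for the later steps.

library(spermchrom)

seed <- 20240206
design <- study_design(seed = seed)
message("simulating ", nrow(design_table(design)), " samples ...")
study <- generate_study(design)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
readr::write_csv(study$samples, "results/design.csv")
readr::write_csv(study$truth, "results/truth.csv")
saveRDS(study, "scratch/study.rds")

message("samples: ", nrow(study$samples))
message("per-sample truth variables: ", ncol(study$truth) - 4)
message("example truth row:")
print(study$truth[1, c("sample_id", "pct_dfi", "pct_hds", "mbbr_mfi",
                       "disulfide", "oxodg_mfi")])
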