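#!/usr/bin/env Rscript
# Step 4 -- factorial mixed-effects models.
#
# For each of the 13 chromatin variables fits
#   value ~ day * boar + (1 | ejaculate)      (REML)
# with storage day and boar as fixed factors and the ejaculate (the AI dose,
# measured on both days) as the random unit, and reports estimated day
# means +/- SEM with type-III Satterthwaite p-values for day, boar and
# day x boar -- the per-variable summary table of the study.

library(spermchrom)

study <- readRDS("scratch/study.rds")
tab <- readr::read_csv("results/sample_table.csv", show_col_types = FALSE)

models <- fit_factorial_mixed_models(tab, chromatin_variables())
readr::write_csv(models, "results/model_table.csv")

message("day means and p-values per chromatin variable:")
print(as.data.frame(models[, c("variable", "mean_day1", "mean_day2",
                               "p_day", "p_boar", "p_day_boar", "model")]),
      digits = 3)
n_day <- sum(models$p_day <= 0.05)
message(n_day, " of ", nrow(models),
        " variables show a significant storage-day effect at alpha = 0.05")
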