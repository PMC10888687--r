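#!/usr/bin/env Rscript
# Step 5 -- correlations, variable clustering and PCA.
#
# Runs the multivariate layer on the per-sample chromatin table:
#  * per-day Pearson correlation matrices with Benjamini-Hochberg masking,
#  * per-day variable clustering on the scaled Hoeffding-D dependence
#    (average linkage on 1 - D),
#  * pooled standardized PCA with loadings (variable-component
#    correlations) and contributions, plus Ward clustering of the
#    observations on the first two components, which should separate the
#    two analysis days along PC1.

library(spermchrom)

tab <- readr::read_csv("results/sample_table.csv", show_col_types = FALSE)
vars <- chromatin_variables()

for (d in unique(tab$day)) {
  cm <- correlation_matrix(tab[tab$day == d, ], vars)
  long <- as.data.frame(as.table(cm$r))
  names(long) <- c("var1", "var2", "r")
  long$p_adjusted <- as.vector(cm$p_adjusted)
  long$significant <- as.vector(cm$significant)
  readr::write_csv(long, sprintf("results/correlations_%s.csv", d))
  message(d, ": ", sum(cm$significant) / 2,
          " significant variable pairs after FDR")
  vc <- cluster_variables(tab[tab$day == d, ], vars)
  merge_tab <- data.frame(vc$hclust$merge, height = vc$hclust$height)
  readr::write_csv(merge_tab, sprintf("results/varclust_%s.csv", d))
}

pca <- principal_components(tab, vars)
message("variance explained by PC1/PC2: ",
        paste(round(100 * pca$prop_variance[1:2], 1), collapse = "% / "), "%")
pca_tab <- data.frame(variable = rep(vars, 2),
                      component = rep(c("PC1", "PC2"), each = length(vars)),
                      loading = c(pca$loadings[, 1], pca$loadings[, 2]),
                      contribution = c(pca$contributions[, 1],
                                       pca$contributions[, 2]))
readr::write_csv(pca_tab, "results/pca_loadings.csv")

cl <- cluster_observations_on_pcs(pca, n_pcs = 2, k = 2)
conf <- table(day = tab$day, cluster = cl)
print(conf)
scores <- data.frame(sample_id = tab$sample_id, day = tab$day,
                     pc1 = pca$scores[, 1], pc2 = pca$scores[, 2],
                     cluster = cl)
readr::write_csv(scores, "results/pca_scores.csv")
message("observation clustering on the first two PCs recovers the day ",
        "split in ", round(100 * sum(apply(conf, 1, max)) / sum(conf)),
        "% of samples")
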