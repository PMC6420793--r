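#!/usr/bin/env Rscript
# Profile-level summaries of the batch-adjusted expression matrix: the 100
# most variable genes, complete-linkage hierarchical clustering of their
# z-scored profiles, and PCA of the sample profiles (the knockdown/rescue
# separation plot).

library(rescuemap)

adj <- read.table("results/preprocess/log_adjusted.tsv", header = TRUE,
                  sep = "\t", check.names = FALSE)
expr <- as.matrix(adj[, -1])
rownames(expr) <- adj[[1]]
samples <- read_samples("results/sim/samples.tsv")

dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)

top <- top_variable_genes(expr, 100)
writeLines(top, "results/profiles/top100_variable_genes.txt")

hc <- hierarchical_cluster(expr[top, ])
ct <- stats::cutree(hc, k = 4)
write_tsv_file(tibble::tibble(gene = names(ct), cluster = unname(ct)),
               "results/profiles/gene_clusters.tsv")

pca <- pca_scores(expr, 2)
scores <- tibble::tibble(sample = rownames(pca$scores),
                         condition = samples$condition[
                           match(rownames(pca$scores), samples$sample)],
                         PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
write_tsv_file(scores, "results/profiles/pca_scores.tsv")

message(sprintf("PC1 %.1f%% / PC2 %.1f%% of variance",
                100 * pca$var_frac[1], 100 * pca$var_frac[2]))
centroid <- function(cond) {
  colMeans(pca$scores[scores$condition == cond, , drop = FALSE])
}
for (cond in c("iLuc", "WT", "DAF", "DEAD")) {
  d_luc <- sqrt(sum((centroid(cond) - centroid("iLuc"))^2))
  d_ief <- sqrt(sum((centroid(cond) - centroid("iEF"))^2))
  message(sprintf("%-4s centroid: distance to iLuc %6.1f, to iEF %6.1f",
                  cond, d_luc, d_ief))
}
message("written to results/profiles/")
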