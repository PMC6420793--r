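#!/usr/bin/env Rscript
# Filter low-count genes, estimate median-of-ratios size factors, and
# batch-adjust the simulated counts with the parametric empirical-Bayes
# location/scale model. Writes the adjusted pseudo-counts used by the DE
# stage and the log-scale adjusted matrix used for clustering and PCA.

library(rescuemap)

counts <- read_counts("results/sim/counts.tsv")
samples <- read_samples("results/sim/samples.tsv")

pp <- preprocess_counts(counts, samples)

dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)
write_counts(pp$pseudo_counts, "results/preprocess/adjusted_counts.tsv")
write_tsv_file(tibble::tibble(sample = names(pp$size_factors),
                              size_factor = pp$size_factors),
               "results/preprocess/size_factors.tsv")

message(sprintf("kept %d of %d genes (mean count >= 1 per sample)",
                nrow(pp$counts), nrow(counts)))
message(sprintf("size factors span %.3f - %.3f (geometric mean 1)",
                min(pp$size_factors), max(pp$size_factors)))
adj <- data.frame(gene = rownames(pp$log_adjusted), pp$log_adjusted,
                  check.names = FALSE)
write.table(adj, "results/preprocess/log_adjusted.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("written to results/preprocess/")
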