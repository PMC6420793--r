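#!/usr/bin/env Rscript
# Negative-binomial Wald differential expression of each construct against
# the iEF knockdown control, plus the endogenous profile (iLuc vs iEF),
# with per-contrast Benjamini-Hochberg adjustment. Prints the DE gene
# counts per construct (the headline table of a knockdown/rescue screen).

library(rescuemap)

counts <- read_counts("results/preprocess/adjusted_counts.tsv")
samples <- read_samples("results/sim/samples.tsv")

sf <- estimate_size_factors(counts)
disp <- estimate_dispersion(counts, sf, samples$condition)

contrasts <- c(endo = "iLuc", WT = "WT", DAF = "DAF", DEAD = "DEAD")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)
for (nm in names(contrasts)) {
  de <- differential_expression(counts, samples, test = contrasts[[nm]],
                                ref = "iEF", size_factors = sf,
                                alphas = disp$alpha)
  write_tsv_file(de, sprintf("results/de/de_%s.tsv", nm))
  sig <- sum(de$padj < 0.05, na.rm = TRUE)
  up <- sum(de$padj < 0.05 & de$log2fc > 0, na.rm = TRUE)
  message(sprintf("%-5s vs iEF: %5d genes at padj < 0.05 (%d up, %d down)",
                  contrasts[[nm]], sig, up, sig - up))
}
message("written to results/de/")
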