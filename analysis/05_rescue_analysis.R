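#!/usr/bin/env Rscript
# The core structure-function analysis: classify every gene's rescue
# status per construct (significant in knockdown and/or rescue profile),
# measure rescue strength (Pearson r, OLS slope of construct log2FC on
# endogenous log2FC over co-significant genes), directional fidelity per
# response-element class, two-fold Venn overlaps with the endogenous
# signature, and recovery of the planted truth.

library(rescuemap)
suppressMessages(library(dplyr))

read_de <- function(nm) {
  tibble::as_tibble(read.table(sprintf("results/de/de_%s.tsv", nm),
                               header = TRUE, sep = "\t"))
}
endo <- read_de("endo")
classes <- tibble::as_tibble(
  read.table("results/elements/gene_classes.tsv", header = TRUE,
             sep = "\t"))
truth <- tibble::as_tibble(
  read.table("results/sim/truth_constructs.tsv", header = TRUE, sep = "\t"))
truth_genes <- tibble::as_tibble(
  read.table("results/sim/truth_genes.tsv", header = TRUE, sep = "\t"))
n_endo_planted <- sum(truth_genes$endo_class != "null")

constructs <- c("WT", "DAF", "DEAD")
calls <- bind_rows(lapply(constructs, function(cn) {
  cl <- classify_rescue_status(endo, read_de(cn))
  cl$construct <- cn
  cl
}))

dir.create("results/rescue", showWarnings = FALSE, recursive = TRUE)
write_tsv_file(calls, "results/rescue/rescue_calls.tsv")

message("construct  rescued%  planted%  slope  r      paradox%")
for (cn in constructs) {
  cc <- calls[calls$construct == cn, ]
  endo_reg <- cc$status %in% c("both_significant", "kd_only")
  frac <- sum(cc$status == "both_significant") / sum(endo_reg)
  st <- rescue_strength(cc)
  both <- cc[cc$status == "both_significant", ]
  planted <- sum(truth$rescued[truth$construct == cn]) / n_endo_planted
  message(sprintf("%-9s  %6.1f    %6.1f   %5.2f  %5.2f  %6.1f", cn,
                  100 * frac, 100 * planted,
                  st$slope, st$pearson_r,
                  100 * mean(!both$concordant)))
}

fidelity <- direction_fidelity(calls, classes)
write_tsv_file(fidelity, "results/rescue/fidelity.tsv")
strata <- strata_rescue_summary(calls, classes)
write_tsv_file(strata, "results/rescue/strata.tsv")

universe <- endo$gene[!is.na(endo$padj)]
endo_sets <- twofold_gene_sets(endo)
venn <- bind_rows(lapply(constructs, function(cn) {
  sets <- twofold_gene_sets(read_de(cn))
  bind_rows(
    mutate(venn_overlap_test(endo_sets$activated, sets$activated, universe),
           construct = cn, direction = "activated"),
    mutate(venn_overlap_test(endo_sets$repressed, sets$repressed, universe),
           construct = cn, direction = "repressed"))
}))
write_tsv_file(venn, "results/rescue/venn.tsv")
message("two-fold Venn overlaps (chi-square p):")
print(as.data.frame(venn[, c("construct", "direction", "nA", "nB",
                             "overlap", "chi2", "p")]), digits = 3)
message("written to results/rescue/")
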