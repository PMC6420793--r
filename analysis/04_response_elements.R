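#!/usr/bin/env Rscript
# Scan the synthetic genome for GGAA-microsatellites and high-affinity ETS
# motifs (ACMGGAARY), then classify every gene by its nearest response
# element: promoter-like (< 5 kb) or enhancer-like (> 5 kb) microsatellite
# crossed with the endogenous direction, or ETS-direct via the strand-aware
# window 5 kb upstream / 1 kb downstream of the TSS.

library(rescuemap)

seqs <- read_fasta("results/sim/genome.fa")
genes <- read_genes_bed("results/sim/genes.bed")
endo <- read.table("results/de/de_endo.tsv", header = TRUE, sep = "\t")

params <- scan_params()
elements <- dplyr::bind_rows(lapply(names(seqs), function(chrom) {
  dplyr::bind_rows(
    find_ggaa_microsatellites(seqs[[chrom]], params, chrom),
    scan_ets_motif(seqs[[chrom]], params, chrom))
}))
elements$element <- sprintf("el%05d", seq_len(nrow(elements)))

classes <- assign_response_classes(genes, elements, endo, params)

dir.create("results/elements", showWarnings = FALSE, recursive = TRUE)
write_tsv_file(elements, "results/elements/elements.tsv")
write_tsv_file(classes, "results/elements/gene_classes.tsv")

ms <- elements[elements$type == "ggaa_ms", ]
message(sprintf("found %d GGAA-microsatellites (max consecutive up to %d) and %d ETS motifs",
                nrow(ms), max(ms$max_consecutive), sum(elements$type == "ets_motif")))
print(table(classes$class))
message("written to results/elements/")
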