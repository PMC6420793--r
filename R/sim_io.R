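#' Write a simulated study to disk
#'
#' Emits the on-disk forms consumed by the pipeline: counts TSV, sample
#' sheet TSV, truth tables TSV, genome FASTA (80-column wrap), gene BED6
#' (TSS as 1-bp intervals) and element BED6 plus a full element TSV with
#' repeat features.
#'
#' @param sim result of [simulate_experiment()].
#' @param ann result of [simulate_annotation()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the directory.
#' @export
write_simulation <- function(sim, ann, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_tsv_file(sim$samples, file.path(dir, "samples.tsv"))
  write_tsv_file(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv_file(sim$truth$constructs, file.path(dir, "truth_constructs.tsv"))
  write_fasta(ann$sequences, file.path(dir, "genome.fa"))
  write_genes_bed(ann$genes, file.path(dir, "genes.bed"))
  el <- ann$elements
  write_bed(tibble::tibble(chrom = el$chrom, start = el$start, end = el$end,
                           name = el$element, score = 0,
                           strand = el$strand),
            file.path(dir, "elements.bed"))
  write_tsv_file(el, file.path(dir, "elements.tsv"))
  invisible(dir)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file may set any subset of [sim_config()] arguments; unset fields
#' keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated [sim_config()].
#' @export
sim_config_from_file <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  num_vec <- function(x) if (is.list(x)) unlist(x) else x
  for (f in c("baseline_mean_log2", "dispersion", "endo_lfc"))
    if (!is.null(vals[[f]])) vals[[f]] <- num_vec(vals[[f]])
  do.call(sim_config, vals)
}
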