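#' Simulate a genome annotation with planted response elements
#'
#' Emits a small synthetic genome (one chromosome per element class so the
#' nearest-element association rules recover the planted classes exactly),
#' 1-bp TSS records for every gene, and the planted GGAA-microsatellites /
#' ETS motifs whose sequence content actually contains the motifs at the
#' recorded coordinates. Promoter-like microsatellites are placed
#' `promoter_distance` bp from their gene's TSS (< 5 kb), enhancer-like
#' ones `enhancer_distance` bp away (> 5 kb); ETS motifs fall in the
#' strand-aware upstream window. Background sequence is scrubbed of
#' spurious scanner calls so that scanning the emitted FASTA recovers the
#' planted elements exactly.
#'
#' @param config a [sim_config()].
#' @param truth optional truth object from [simulate_experiment()]; when
#'   omitted it is re-derived from `config` (same sub-seed), so annotation
#'   and expression stay consistent.
#' @param params [scan_params()] used for the spurious-call scrub.
#' @return list with `sequences` (named character vector of chromosomes),
#'   `genes` (tibble: chrom, tss, strand, gene) and `elements` (tibble:
#'   element, chrom, start, end, strand, type, max_consecutive,
#'   total_repeats, fli_enrichment, gene).
#' @export
simulate_annotation <- function(config, truth = NULL,
                                params = scan_params()) {
  validate_sim_config(config)
  if (is.null(truth)) truth <- simulate_truth(config)
  ec <- config$element_config
  set.seed(derive_seed(config$seed, "annotation"))

  rmax <- ec$repeat_length[["max"]]
  if (ec$gene_spacing / 2 < ec$promoter_distance[["max"]] + 4 * rmax + 100)
    stop("placement error: gene_spacing too small for requested promoter ",
         "distances and repeat lengths")
  if (ec$enhancer_gene_spacing / 2 < ec$enhancer_distance[["max"]] + 4 * rmax + 100)
    stop("placement error: enhancer_gene_spacing too small for requested ",
         "enhancer distances and repeat lengths")

  gt <- truth$genes
  layout <- list(
    chrMSP = list(genes = gt$gene[gt$element_class == "ms_prom"],
                  spacing = ec$gene_spacing),
    chrMSE = list(genes = gt$gene[gt$element_class == "ms_enh"],
                  spacing = ec$enhancer_gene_spacing),
    chrETS = list(genes = gt$gene[gt$element_class == "ets"],
                  spacing = ec$gene_spacing),
    chrFLI = list(genes = gt$gene[gt$element_class == "other"],
                  spacing = ec$gene_spacing),
    chrBG  = list(genes = gt$gene[gt$element_class == "none"],
                  spacing = 1000)
  )

  genes_rows <- list(); el_rows <- list(); seqs <- character(0)
  rand_int <- function(n, range) {
    if (range[["min"]] == range[["max"]]) rep(range[["min"]], n)
    else sample(seq(range[["min"]], range[["max"]]), n, replace = TRUE)
  }

  for (chrom in names(layout)) {
    lg <- layout[[chrom]]
    ng <- length(lg$genes)
    if (!ng && chrom != "chrBG") next
    len <- max(lg$spacing * ng + lg$spacing, 2 * lg$spacing)
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    tss <- as.integer((seq_len(ng) - 1) * lg$spacing + lg$spacing / 2)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    genes_rows[[chrom]] <- tibble::tibble(chrom = rep(chrom, ng), tss = tss,
                                          strand = strand, gene = lg$genes)
    if (ng && chrom %in% c("chrMSP", "chrMSE")) {
      drange <- if (chrom == "chrMSP") ec$promoter_distance else ec$enhancer_distance
      units <- rand_int(ng, ec$repeat_length)
      d <- rand_int(ng, drange)
      left <- sample(c(TRUE, FALSE), ng, replace = TRUE)
      start <- ifelse(left, tss - d - 4 * units, tss + d)  # 0-based
      for (i in seq_len(ng)) {
        el_seq <- strrep("GGAA", units[i])
        chars[(start[i] + 1):(start[i] + 4 * units[i])] <-
          strsplit(el_seq, "")[[1]]
      }
      el_rows[[chrom]] <- tibble::tibble(
        chrom = rep(chrom, ng), start = as.integer(start),
        end = as.integer(start + 4 * units), strand = rep("+", ng),
        type = rep("ggaa_ms", ng), max_consecutive = as.integer(units),
        total_repeats = as.integer(units), gene = lg$genes)
    }
    if (ng && chrom == "chrETS") {
      d <- rand_int(ng, ec$ets_distance)
      el_strand <- sample(c("+", "-"), ng, replace = TRUE)
      # upstream of the TSS in gene orientation
      start <- ifelse(strand == "+", tss - d - 9, tss + d)
      inst <- paste0("AC", sample(c("A", "C"), ng, TRUE), "GGAA",
                     sample(c("A", "G"), ng, TRUE), sample(c("C", "T"), ng, TRUE))
      for (i in seq_len(ng)) {
        s <- if (el_strand[i] == "+") inst[i] else revcomp(inst[i])
        chars[(start[i] + 1):(start[i] + 9)] <- strsplit(s, "")[[1]]
      }
      el_rows[[chrom]] <- tibble::tibble(
        chrom = rep(chrom, ng), start = as.integer(start),
        end = as.integer(start + 9), strand = el_strand,
        type = rep("ets_motif", ng), max_consecutive = rep(NA_integer_, ng),
        total_repeats = rep(NA_integer_, ng), gene = lg$genes)
    }
    if (ng && chrom == "chrFLI") {
      # other FLI-bound loci: interval records only (normally user-supplied
      # ChIP annotation); no literal motif is planted in sequence
      start <- tss - 1000 - 200
      el_rows[[chrom]] <- tibble::tibble(
        chrom = rep(chrom, ng), start = as.integer(start),
        end = as.integer(start + 200), strand = rep(".", ng),
        type = rep("other_fli", ng), max_consecutive = rep(NA_integer_, ng),
        total_repeats = rep(NA_integer_, ng), gene = lg$genes)
    }
    seqs[[chrom]] <- paste(chars, collapse = "")
  }

  empty_el <- tibble::tibble(chrom = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             type = character(0),
                             max_consecutive = integer(0),
                             total_repeats = integer(0),
                             gene = character(0))
  elements <- dplyr::bind_rows(c(list(empty_el), el_rows))
  seqs <- scrub_spurious_calls(seqs, elements, params)

  set.seed(derive_seed(config$seed, "enrichment"))
  elements$fli_enrichment <- rlnorm(nrow(elements), log(8), 0.5)
  elements$element <- if (nrow(elements)) {
    sprintf("el%05d", seq_len(nrow(elements)))
  } else character(0)
  elements <- elements[, c("element", "chrom", "start", "end", "strand",
                           "type", "max_consecutive", "total_repeats",
                           "fli_enrichment", "gene")]
  genes <- dplyr::bind_rows(genes_rows)
  genes <- genes[match(gt$gene, genes$gene), ]
  list(sequences = seqs, genes = genes, elements = elements)
}

# Mutate background bases until scanning finds exactly the planted
# elements: any microsatellite or ETS call not matching a planted record
# gets one base (outside planted footprints) flipped, iterating until the
# scan is clean.
scrub_spurious_calls <- function(seqs, elements, params) {
  for (chrom in names(seqs)) {
    pl <- elements[elements$chrom == chrom &
                     elements$type %in% c("ggaa_ms", "ets_motif"), ,
                   drop = FALSE]
    footprint <- rep(FALSE, nchar(seqs[[chrom]]))
    for (i in seq_len(nrow(pl))) footprint[(pl$start[i] + 1):pl$end[i]] <- TRUE
    key <- function(tab) paste(tab$start, tab$end, tab$type)
    planted_keys <- key(pl)
    chars <- NULL
    for (iter in 1:20) {
      found <- dplyr::bind_rows(
        find_ggaa_microsatellites(seqs[[chrom]], params, chrom),
        scan_ets_motif(seqs[[chrom]], params, chrom))
      spurious <- found[!(key(found) %in% planted_keys), , drop = FALSE]
      if (!nrow(spurious)) break
      if (iter == 20) stop("could not scrub spurious element calls on ", chrom)
      if (is.null(chars)) chars <- strsplit(seqs[[chrom]], "")[[1]]
      for (i in seq_len(nrow(spurious))) {
        pos <- (spurious$start[i] + 1):spurious$end[i]
        pos <- pos[!footprint[pos]]
        if (!length(pos)) next  # fully inside a planted footprint
        chars[pos] <- "C"  # C-blocks carry no GGAA/TTCC and break the motif
      }
      seqs[[chrom]] <- paste(chars, collapse = "")
    }
  }
  seqs
}
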