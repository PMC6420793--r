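#' Read a count matrix
#'
#' TSV (header row of sample ids, gene ids in the first column) or
#' MatrixMarket (`.mtx`, with sidecar `<stem>.genes.txt` and
#' `<stem>.samples.txt` id files).
#'
#' @param path file path.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".genes.txt"))
    colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     row.names = NULL, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#' @param counts matrix with dimnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample sheet (sample, condition, batch TSV)
#' @param path file path.
#' @return tibble with sample, condition, batch.
#' @export
read_samples <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition", "batch") %in% names(df)))
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in ", path)
  tibble::as_tibble(df)
}

#' Read a BED6 file (0-based half-open)
#' @param path file path.
#' @return tibble: chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("BED interval with start >= end at line ", bad[1], " of ", path)
  tibble::as_tibble(df)
}

#' Write BED6 (0-based half-open)
#' @param df tibble with chrom, start, end, name, score, strand.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Genes as BED6 (TSS as a 1-bp interval)
#' @param genes tibble with chrom, tss, strand, gene.
#' @param path output path.
#' @export
write_genes_bed <- function(genes, path) {
  write_bed(tibble::tibble(chrom = genes$chrom, start = genes$tss,
                           end = genes$tss + 1, name = genes$gene,
                           score = 0, strand = genes$strand), path)
}

#' Read gene TSS records from BED6
#' @param path file path.
#' @return tibble: chrom, tss, strand, gene.
#' @export
read_genes_bed <- function(path) {
  bed <- read_bed(path)
  tibble::tibble(chrom = bed$chrom, tss = bed$start, strand = bed$strand,
                 gene = bed$name)
}

#' Read FASTA into a named character vector
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (any(!nzchar(names(set))))
    stop("FASTA record with blank id (record ",
         which(!nzchar(names(set)))[1], ") in ", path)
  setNames(as.character(set), names(set))
}

#' Write sequences as FASTA (wrapped at 80 columns)
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80)
}

#' Write a tibble as deterministic TSV
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}
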