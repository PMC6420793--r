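# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use different algorithms (character
# loops, O(n^3) agglomeration, literal step-up definitions) from the code
# they verify.

# character-by-character GGAA/TTCC microsatellite scanner
oracle_ggaa_scan <- function(seq, min_repeats = 4, max_gap = 4,
                             unit = "GGAA") {
  seq <- toupper(seq)
  n <- nchar(seq)
  is_unit <- function(i) i + 3 <= n && substr(seq, i, i + 3) == unit
  runs <- list()
  i <- 1
  while (i <= n - 3) {
    if (is_unit(i)) {
      start <- i
      units <- 0
      while (is_unit(i)) { units <- units + 1; i <- i + 4 }
      runs[[length(runs) + 1]] <- c(start = start, end = i - 1, units = units)
    } else i <- i + 1
  }
  if (!length(runs)) {
    return(data.frame(start = integer(0), end = integer(0),
                      max_consecutive = integer(0),
                      total_repeats = integer(0)))
  }
  out <- list()
  cur <- runs[[1]]
  cur_max <- cur[["units"]]; cur_tot <- cur[["units"]]
  cur_start <- cur[["start"]]; cur_end <- cur[["end"]]
  if (length(runs) > 1) for (r in runs[-1]) {
    if (r[["start"]] - cur_end - 1 <= max_gap) {
      cur_end <- r[["end"]]
      cur_max <- max(cur_max, r[["units"]])
      cur_tot <- cur_tot + r[["units"]]
    } else {
      out[[length(out) + 1]] <- c(cur_start, cur_end, cur_max, cur_tot)
      cur_start <- r[["start"]]; cur_end <- r[["end"]]
      cur_max <- r[["units"]]; cur_tot <- r[["units"]]
    }
  }
  out[[length(out) + 1]] <- c(cur_start, cur_end, cur_max, cur_tot)
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1] - 1L, end = m[, 2], # to 0-based half-open
                   max_consecutive = m[, 3], total_repeats = m[, 4])
  df[df$total_repeats >= min_repeats, , drop = FALSE]
}

# ETS-motif oracle: expand the degenerate consensus into every concrete
# 9-mer and locate each with fixed-string matching
oracle_ets_scan <- function(seq) {
  seq <- toupper(seq)
  words_plus <- as.vector(outer(
    as.vector(outer(c("ACAGGAA", "ACCGGAA"), c("A", "G"), paste0)),
    c("C", "T"), paste0))
  rc <- function(w) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(w, "")[[1]]), collapse = ""))
  n <- nchar(seq)
  kmers <- substring(seq, seq_len(n - 8), seq(9, n))  # every 9-mer
  plus <- which(kmers %in% words_plus)
  minus <- which(kmers %in% vapply(words_plus, rc, ""))
  data.frame(start = c(plus, minus) - 1L,
             strand = rep(c("+", "-"), c(length(plus), length(minus))))
}

# literal BH step-up: padj_(i) = min_{j >= i} min(1, m * p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# direct median-of-ratios computation (per-sample loop)
oracle_size_factors <- function(counts) {
  ref <- apply(counts, 1, function(r) all(r > 0))
  lgm <- apply(counts[ref, , drop = FALSE], 1,
               function(r) mean(log(r)))
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    sf[j] <- exp(median(log(counts[ref, j]) - lgm))
  sf / exp(mean(log(sf)))
}

# O(n^3) complete-linkage agglomeration on a distance matrix
oracle_complete_linkage_heights <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(dm[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# closed-form 2x2 Pearson chi-square
oracle_chi2_2x2 <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  N * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# compact simulation config for fast tests
small_sim_config <- function(n_genes = 600, seed = 11, ...) {
  sim_config(
    n_genes = n_genes,
    constructs = list(
      WT = list(rescue_frac = 0.75, attenuation = 0.8, paradox_frac = 0.05),
      DEAD = list(rescue_frac = 0.02, attenuation = 0.1, paradox_frac = 0.1)),
    element_config = list(
      n_promoter_ms = 8, n_enhancer_ms = 8, n_ets = 8, n_other_fli = 2,
      repeat_length = c(min = 5, max = 20),
      promoter_distance = c(min = 500, max = 4500),
      enhancer_distance = c(min = 6000, max = 25000),
      ets_distance = c(min = 200, max = 4000),
      gene_spacing = 12000, enhancer_gene_spacing = 60000),
    seed = seed, ...)
}

# hand-built DE table
make_de <- function(gene, log2fc, padj, p = padj / 2) {
  tibble::tibble(gene = gene, baseMean = 100, log2fc = log2fc,
                 se = 0.1, stat = log2fc / 0.1, p = p, padj = padj)
}
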