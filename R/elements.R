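#' Scanning parameters for response-element discovery
#'
#' @param min_repeats minimum total GGAA units for a microsatellite call.
#' @param max_gap maximum bp of non-motif sequence between GGAA runs that
#'   are merged into one element.
#' @param ets_motif IUPAC consensus of the high-affinity ETS site.
#' @param distance_threshold bp; microsatellites nearer than this to the
#'   TSS are "promoter-like", others "enhancer-like" (strict `<`).
#' @param direct_window_up,direct_window_down bp of the strand-aware
#'   window around the TSS in which an ETS motif (or other FLI-bound
#'   locus) makes a gene a direct non-microsatellite target.
#' @param assoc_radius bp; microsatellites farther than this from a TSS are
#'   never associated with it.
#' @param scan_both_strands also report minus-strand elements (TTCC runs,
#'   reverse-complement motif matches).
#' @return a `scan_params` list.
#' @export
scan_params <- function(min_repeats = 4, max_gap = 4,
                        ets_motif = "ACMGGAARY",
                        distance_threshold = 5000,
                        direct_window_up = 5000, direct_window_down = 1000,
                        assoc_radius = 500000,
                        scan_both_strands = TRUE) {
  p <- list(min_repeats = min_repeats, max_gap = max_gap,
            ets_motif = toupper(ets_motif),
            distance_threshold = distance_threshold,
            direct_window_up = direct_window_up,
            direct_window_down = direct_window_down,
            assoc_radius = assoc_radius,
            scan_both_strands = scan_both_strands)
  num <- unlist(p[c("min_repeats", "max_gap", "distance_threshold",
                    "direct_window_up", "direct_window_down", "assoc_radius")])
  if (any(num < 0)) stop("scan parameters must be >= 0")
  if (!grepl("^[ACGTUMRWSYKVHDBN]+$", p$ets_motif))
    stop("ets_motif is not a valid IUPAC string: ", ets_motif)
  class(p) <- c("scan_params", "list")
  p
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
               M = "[AC]", R = "[AG]", W = "[AT]", S = "[CG]",
               Y = "[CT]", K = "[GT]", V = "[ACG]", H = "[ACT]",
               D = "[AGT]", B = "[CGT]", N = "[ACGT]")

iupac_to_regex <- function(motif) {
  paste(IUPAC_MAP[strsplit(motif, "")[[1]]], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_sequence <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0)
    stop("non-IUPAC character '", substr(seq, bad, bad),
         "' at position ", bad)
  invisible(TRUE)
}

# positions (1-based starts) of all occurrences of fixed `unit` in `seq`
fixed_starts <- function(seq, unit) {
  m <- gregexpr(unit, seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Find GGAA runs on one strand literal. Returns 0-based half-open
# coordinates plus repeat features.
scan_unit_runs <- function(seq, unit, params) {
  starts <- fixed_starts(seq, unit)
  if (!length(starts)) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          max_consecutive = integer(0),
                          total_repeats = integer(0)))
  }
  # group into maximal runs of consecutive (step-4) units
  new_run <- c(TRUE, diff(starts) != 4L)
  run_id <- cumsum(new_run)
  run_start <- tapply(starts, run_id, min)
  run_units <- tapply(starts, run_id, length)
  run_end <- run_start + 4L * run_units  # 1-based position after last unit
  # merge runs separated by <= max_gap non-motif bases
  n_runs <- length(run_start)
  gap <- if (n_runs > 1) run_start[-1] - run_end[-n_runs] else numeric(0)
  el_id <- cumsum(c(TRUE, gap > params$max_gap))
  tibble::tibble(
    start = as.integer(tapply(run_start, el_id, min)) - 1L,
    end = as.integer(tapply(run_end, el_id, max)) - 1L,
    max_consecutive = as.integer(tapply(run_units, el_id, max)),
    total_repeats = as.integer(tapply(run_units, el_id, sum))
  )
}

#' Find GGAA-microsatellite response elements
#'
#' Calls maximal runs of consecutive `GGAA` units (and `TTCC` runs,
#' reported as minus-strand elements, when `scan_both_strands`), merges
#' runs separated by at most `max_gap` non-motif bases into one element,
#' and drops elements with fewer than `min_repeats` total units.
#' Coordinates are 0-based half-open; scanning is case-insensitive.
#'
#' @param seq a nucleotide string over A/C/G/T/N.
#' @param params a [scan_params()].
#' @param chrom chromosome name recorded on the output rows.
#' @return tibble with chrom, start, end, strand, type = "ggaa_ms",
#'   max_consecutive, total_repeats.
#' @export
find_ggaa_microsatellites <- function(seq, params = scan_params(),
                                      chrom = "chr") {
  seq <- toupper(seq)
  check_sequence(seq)
  plus <- scan_unit_runs(seq, "GGAA", params)
  plus$strand <- rep("+", nrow(plus))
  out <- plus
  if (params$scan_both_strands) {
    minus <- scan_unit_runs(seq, "TTCC", params)
    minus$strand <- rep("-", nrow(minus))
    out <- dplyr::bind_rows(plus, minus)
  }
  out <- out[out$total_repeats >= params$min_repeats, , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  tibble::tibble(chrom = rep(chrom, nrow(out)), start = out$start,
                 end = out$end, strand = out$strand,
                 type = rep("ggaa_ms", nrow(out)),
                 max_consecutive = out$max_consecutive,
                 total_repeats = out$total_repeats)
}

#' Scan for high-affinity ETS motifs
#'
#' Reports every position (overlapping matches included) matching the
#' IUPAC consensus (default `ACMGGAARY`) on the plus strand and, when
#' `scan_both_strands`, its reverse complement on the minus strand.
#'
#' @inheritParams find_ggaa_microsatellites
#' @return tibble with chrom, start, end (0-based half-open), strand,
#'   type = "ets_motif".
#' @export
scan_ets_motif <- function(seq, params = scan_params(), chrom = "chr") {
  seq <- toupper(seq)
  check_sequence(seq)
  w <- nchar(params$ets_motif)
  find_all <- function(pattern) {
    m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  plus <- find_all(iupac_to_regex(params$ets_motif))
  starts <- plus
  strands <- rep("+", length(plus))
  if (params$scan_both_strands) {
    minus <- find_all(iupac_to_regex(revcomp(params$ets_motif)))
    starts <- c(starts, minus)
    strands <- c(strands, rep("-", length(minus)))
  }
  ord <- order(starts, strands)
  tibble::tibble(chrom = rep(chrom, length(starts)),
                 start = starts[ord] - 1L, end = starts[ord] - 1L + w,
                 strand = strands[ord],
                 type = rep("ets_motif", length(starts)))
}

#' Unsigned distance from an element to a TSS
#'
#' Distance in bp from the nearest element edge to the TSS; 0 when the TSS
#' lies inside the element; `NA` when on different chromosomes.
#'
#' @param el_chrom,el_start,el_end element coordinates (0-based half-open).
#' @param tss_chrom,tss TSS coordinates (0-based position).
#' @return numeric bp distance (vectorized).
#' @export
element_gene_distance <- function(el_chrom, el_start, el_end, tss_chrom, tss) {
  d <- pmax(el_start - tss, tss - el_end, 0)
  d[el_chrom != tss_chrom] <- NA_real_
  d
}

#' Classify genes by their nearest response element
#'
#' Implements the direct-target taxonomy: every gene that is significantly
#' regulated in the endogenous profile (BH-adjusted p < alpha) and has a
#' GGAA-microsatellite within `assoc_radius` is classed by the distance of
#' the nearest microsatellite (promoter-like `< distance_threshold`,
#' enhancer-like otherwise) crossed with the endogenous direction
#' (activated/repressed). Endo-significant genes without a microsatellite
#' but with an ETS motif (or other FLI-bound locus) inside the strand-aware
#' window `[TSS - direct_window_up, TSS + direct_window_down]` (gene
#' orientation) are `ets_direct` / `other_fli_direct`. Everything else,
#' including all endo-non-significant genes, is `none`. Precedence:
#' microsatellite > ETS motif > other FLI locus.
#'
#' @param genes tibble with chrom, tss (0-based), strand, gene.
#' @param elements tibble of elements (as from the scanners, plus optional
#'   `other_fli` rows); needs chrom, start, end, type and, if present, an
#'   `element` id column.
#' @param endo DETable of the endogenous (iLuc vs iEF) contrast.
#' @param params a [scan_params()].
#' @param alpha adjusted-p significance threshold.
#' @return tibble: gene, class, element (linked element id or NA),
#'   distance (bp or NA).
#' @export
assign_response_classes <- function(genes, elements, endo,
                                    params = scan_params(), alpha = 0.05) {
  if (!all(genes$gene %in% endo$gene))
    warning("genes absent from the endo table are classed 'none': ",
            paste(head(setdiff(genes$gene, endo$gene), 5), collapse = ", "))
  if (is.null(elements$element))
    elements$element <- sprintf("el%05d", seq_len(nrow(elements)))
  endo_idx <- match(genes$gene, endo$gene)
  sig <- !is.na(endo_idx) & !is.na(endo$padj[endo_idx]) &
    endo$padj[endo_idx] < alpha
  dir_act <- endo$log2fc[endo_idx] > 0

  cls <- rep("none", nrow(genes))
  link <- rep(NA_character_, nrow(genes))
  dist <- rep(NA_real_, nrow(genes))

  ms <- elements[elements$type == "ggaa_ms", , drop = FALSE]
  ets <- elements[elements$type == "ets_motif", , drop = FALSE]
  ofl <- elements[elements$type == "other_fli", , drop = FALSE]

  for (i in which(sig)) {
    tss <- genes$tss[i]; chrom <- genes$chrom[i]
    # nearest microsatellite within the association radius
    if (nrow(ms)) {
      d <- element_gene_distance(ms$chrom, ms$start, ms$end, chrom, tss)
      d[is.na(d) | d > params$assoc_radius] <- NA
      if (any(!is.na(d))) {
        k <- which.min(d)
        proximal <- d[k] < params$distance_threshold
        cls[i] <- paste0(if (proximal) "ms_prom_" else "ms_enh_",
                         if (dir_act[i]) "act" else "rep")
        link[i] <- ms$element[k]; dist[i] <- d[k]
        next
      }
    }
    # strand-aware direct window for non-microsatellite loci
    win <- if (genes$strand[i] == "-") {
      c(tss - params$direct_window_down, tss + params$direct_window_up)
    } else {
      c(tss - params$direct_window_up, tss + params$direct_window_down)
    }
    in_window <- function(tab) {
      which(tab$chrom == chrom & tab$start <= win[2] & tab$end - 1 >= win[1])
    }
    hit <- in_window(ets)
    if (length(hit)) {
      d <- element_gene_distance(ets$chrom[hit], ets$start[hit],
                                 ets$end[hit], chrom, tss)
      k <- hit[which.min(d)]
      cls[i] <- "ets_direct"; link[i] <- ets$element[k]; dist[i] <- min(d)
      next
    }
    hit <- in_window(ofl)
    if (length(hit)) {
      d <- element_gene_distance(ofl$chrom[hit], ofl$start[hit],
                                 ofl$end[hit], chrom, tss)
      k <- hit[which.min(d)]
      cls[i] <- "other_fli_direct"; link[i] <- ofl$element[k]; dist[i] <- min(d)
    }
  }
  tibble::tibble(gene = genes$gene, class = cls, element = link,
                 distance = dist)
}

#' Compare repeat/binding features between two element groups
#'
#' For each available feature (`max_consecutive`, `total_repeats`,
#' `fli_enrichment`) reports group medians and a Mann-Whitney rank-sum
#' test (normal approximation with tie correction, no continuity
#' correction). Features missing from either group are skipped with a note.
#'
#' @param groupA,groupB element tibbles.
#' @return tibble: feature, median_A, median_B, statistic (W), p.
#' @export
compare_element_features <- function(groupA, groupB) {
  if (!nrow(groupA) || !nrow(groupB)) stop("both element groups must be non-empty")
  feats <- c("max_consecutive", "total_repeats", "fli_enrichment")
  rows <- lapply(feats, function(f) {
    a <- groupA[[f]]; b <- groupB[[f]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) {
      message("feature '", f, "' absent in one group; skipped")
      return(NULL)
    }
    wt <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = FALSE))
    pv <- wt$p.value
    if (is.nan(pv)) pv <- 1  # zero rank variance: every observation tied
    tibble::tibble(feature = f, median_A = median(a), median_B = median(b),
                   statistic = unname(wt$statistic), p = pv)
  })
  dplyr::bind_rows(rows)
}
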