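#' Analysis thresholds for rescue classification
#'
#' @param alpha BH-adjusted p significance threshold (strict `<`).
#' @param fc_cutoff fold-change threshold for two-fold set/Venn analyses
#'   (strict `|FC| >`); the four-way rescue classification itself uses no
#'   fold-change cutoff.
#' @param control control condition name (the knockdown, "iEF").
#' @param endo endogenous-profile condition name ("iLuc").
#' @return an `analysis_params` list.
#' @export
analysis_params <- function(alpha = 0.05, fc_cutoff = 2.0,
                            control = "iEF", endo = "iLuc") {
  stopifnot(alpha > 0, alpha < 1, fc_cutoff >= 1)
  p <- list(alpha = alpha, fc_cutoff = fc_cutoff, control = control,
            endo = endo)
  class(p) <- c("analysis_params", "list")
  p
}

#' Four-way rescue status per gene
#'
#' Crosses significance in the endogenous (knockdown) profile with
#' significance in a construct's profile, both at BH-adjusted p < alpha
#' with no fold-change cutoff: `both_significant` (the scatterplot red),
#' `kd_only` (gray), `rescue_only` (yellow), `neither` (black).
#' Directions come from the log2FC signs; `concordant` is defined only
#' when both directions are. Genes testable in only one table count as
#' non-significant there and are flagged `partial`.
#'
#' @param endo,construct DETables sharing a gene universe.
#' @param params [analysis_params()].
#' @return tibble: gene, status, endo_dir, construct_dir, concordant,
#'   endo_lfc, construct_lfc, partial.
#' @export
classify_rescue_status <- function(endo, construct,
                                   params = analysis_params()) {
  shared <- intersect(endo$gene, construct$gene)
  if (!length(shared)) stop("endo and construct tables share no genes")
  e <- endo[match(shared, endo$gene), ]
  co <- construct[match(shared, construct$gene), ]
  e_sig <- !is.na(e$padj) & e$padj < params$alpha
  c_sig <- !is.na(co$padj) & co$padj < params$alpha
  status <- dplyr::case_when(
    e_sig & c_sig ~ "both_significant",
    e_sig ~ "kd_only",
    c_sig ~ "rescue_only",
    TRUE ~ "neither")
  endo_dir <- ifelse(e_sig, ifelse(e$log2fc > 0, "up", "down"), NA)
  construct_dir <- ifelse(c_sig, ifelse(co$log2fc > 0, "up", "down"), NA)
  tibble::tibble(
    gene = shared, status = status,
    endo_dir = endo_dir, construct_dir = construct_dir,
    concordant = ifelse(e_sig & c_sig, endo_dir == construct_dir, NA),
    endo_lfc = e$log2fc, construct_lfc = co$log2fc,
    partial = is.na(e$padj) | is.na(co$padj))
}

#' Directional fidelity per element class
#'
#' Restricted to endo-regulated genes (the red and gray scatterplot
#' points; `rescue_only` genes are excluded): per element class, the
#' fractions of genes the construct rescues concordantly, regulates
#' paradoxically (significant but in the wrong direction), and leaves
#' unchanged. The three fractions sum to 1. Classes with zero
#' endo-regulated genes are omitted.
#'
#' @param calls output of [classify_rescue_status()], optionally with a
#'   `construct` column when several constructs are stacked.
#' @param classes [assign_response_classes()] output (gene, class).
#' @param params [analysis_params()].
#' @return tibble: (construct,) class, n_endo_regulated,
#'   frac_rescued_concordant, frac_paradoxical, frac_unchanged.
#' @export
direction_fidelity <- function(calls, classes, params = analysis_params()) {
  if (!"construct" %in% names(calls)) calls$construct <- "construct"
  df <- dplyr::inner_join(calls, classes[, c("gene", "class")], by = "gene")
  df <- df[df$status %in% c("both_significant", "kd_only"), , drop = FALSE]
  out <- df |>
    dplyr::group_by(.data$construct, .data$class) |>
    dplyr::summarise(
      n_endo_regulated = dplyr::n(),
      frac_rescued_concordant =
        mean(.data$status == "both_significant" & .data$concordant),
      frac_paradoxical =
        mean(.data$status == "both_significant" & !.data$concordant),
      frac_unchanged = mean(.data$status == "kd_only"),
      .groups = "drop")
  out[out$n_endo_regulated > 0, , drop = FALSE]
}

#' Rescue strength: Pearson r and OLS slope over co-significant genes
#'
#' Over `both_significant` genes only: the Pearson correlation of
#' (endo log2FC, construct log2FC) with its two-sided t-based p-value,
#' and the slope of the ordinary least-squares fit of construct log2FC on
#' endo log2FC (with intercept; the intercept is reported, not
#' interpreted). With fewer than 3 such genes the result is an undefined
#' sentinel carrying n.
#'
#' @param calls output of [classify_rescue_status()] for one construct.
#' @return tibble row: n, pearson_r, r_pvalue, slope, intercept.
#' @export
rescue_strength <- function(calls) {
  sel <- calls[calls$status == "both_significant", , drop = FALSE]
  n <- nrow(sel)
  if (n < 3 || sd(sel$endo_lfc) == 0 || sd(sel$construct_lfc) == 0) {
    return(tibble::tibble(n = n, pearson_r = NA_real_, r_pvalue = NA_real_,
                          slope = NA_real_, intercept = NA_real_))
  }
  ct <- suppressWarnings(cor.test(sel$endo_lfc, sel$construct_lfc))
  fit <- lm(construct_lfc ~ endo_lfc, data = sel)
  tibble::tibble(n = n, pearson_r = unname(ct$estimate),
                 r_pvalue = ct$p.value,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]))
}

#' Two-fold significant gene sets
#'
#' Activated and repressed gene sets at the Venn-analysis cutoffs:
#' BH-adjusted p < alpha and fold change strictly above `fc_cutoff`
#' (log2FC > log2(fc_cutoff), or below its negative).
#'
#' @param de a DETable.
#' @param params [analysis_params()].
#' @return list with character vectors `activated` and `repressed`.
#' @export
twofold_gene_sets <- function(de, params = analysis_params()) {
  sig <- !is.na(de$padj) & de$padj < params$alpha
  lfc <- log2(params$fc_cutoff)
  list(activated = de$gene[sig & de$log2fc > lfc],
       repressed = de$gene[sig & de$log2fc < -lfc])
}

#' Chi-square test of gene-set overlap
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2
#' membership table of two gene sets over a stated universe, as used for
#' Venn-diagram overlaps. Degenerate margins (an empty set, or a set
#' equal to the universe) give p = NA with a reason.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return tibble row: nA, nB, overlap, universe, chi2, p, note.
#' @export
venn_overlap_test <- function(setA, setB, universe) {
  stopifnot(length(universe) >= 2)
  setA <- intersect(setA, universe); setB <- intersect(setB, universe)
  inA <- universe %in% setA; inB <- universe %in% setB
  a <- as.numeric(sum(inA & inB)); b <- as.numeric(sum(inA & !inB))
  c_ <- as.numeric(sum(!inA & inB)); d <- as.numeric(sum(!inA & !inB))
  N <- as.numeric(length(universe))
  res <- tibble::tibble(nA = sum(inA), nB = sum(inB), overlap = a,
                        universe = N, chi2 = NA_real_, p = NA_real_,
                        note = NA_character_)
  if (any(c(a + b, c_ + d, a + c_, b + d) == 0)) {
    res$note <- "degenerate margin (empty set or full universe)"
    return(res)
  }
  chi2 <- N * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  res$chi2 <- chi2
  res$p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  res
}

#' Stratified rescue summary
#'
#' One row per construct x element class x status/direction cell with
#' counts and within-stratum proportions (each construct x class stratum
#' sums to 1), with the stratum's rescue strength attached - the tidy
#' backbone of the per-class scatterplot/pie compilations.
#'
#' @param calls stacked [classify_rescue_status()] output with a
#'   `construct` column.
#' @param classes [assign_response_classes()] output.
#' @param params [analysis_params()].
#' @return tibble: construct, class, status, concordant, n, proportion,
#'   strength_n, pearson_r, r_pvalue, slope.
#' @export
strata_rescue_summary <- function(calls, classes,
                                  params = analysis_params()) {
  if (!"construct" %in% names(calls)) calls$construct <- "construct"
  df <- dplyr::inner_join(calls, classes[, c("gene", "class")], by = "gene")
  cells <- df |>
    dplyr::count(.data$construct, .data$class, .data$status,
                 .data$concordant) |>
    dplyr::group_by(.data$construct, .data$class) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  strengths <- df |>
    dplyr::group_by(.data$construct, .data$class) |>
    dplyr::group_modify(~rescue_strength(.x)) |>
    dplyr::ungroup() |>
    dplyr::rename(strength_n = "n")
  dplyr::left_join(cells, strengths, by = c("construct", "class"))
}
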