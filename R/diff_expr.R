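#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimate on size-factor-normalized counts with
#' condition-aware pooling of within-group variance, moderated by
#' shrinking 30% of the way (log scale) toward the trimmed-mean
#' dispersion of genes with similar baseline expression (20 bins).
#' Genes whose moment estimate is non-positive (at or below Poisson
#' variance) are floored at 1e-8 and flagged; all-zero genes likewise.
#'
#' @param counts count matrix, genes x samples.
#' @param size_factors per-sample positive factors.
#' @param condition factor/character of sample conditions (grouping for
#'   the within-group variance); a single group is allowed.
#' @return tibble: gene, baseMean, alpha, alpha_raw, floored (logical).
#' @export
estimate_dispersion <- function(counts, size_factors,
                                condition = rep("all", ncol(counts))) {
  stopifnot(all(size_factors > 0), ncol(counts) >= 2)
  norm <- sweep(counts, 2, size_factors, "/")
  condition <- factor(condition)
  base_mean <- rowMeans(norm)

  # pooled within-group moments
  ss <- matrix(0, nrow(counts), 1)
  df <- 0
  for (lev in levels(condition)) {
    idx <- which(condition == lev)
    if (length(idx) < 2) next
    mu <- rowMeans(norm[, idx, drop = FALSE])
    ss <- ss + rowSums((norm[, idx, drop = FALSE] - mu)^2)
    df <- df + length(idx) - 1
  }
  if (df == 0) stop("need at least one condition with >= 2 samples")
  v <- as.vector(ss) / df
  # inverse mean of size factors approximates the Poisson term on the
  # normalized scale
  pois <- base_mean * mean(1 / size_factors)
  mom <- (v - pois) / base_mean^2
  mom[base_mean == 0] <- NA

  ok <- !is.na(mom) & mom > 0
  alpha <- rep(1e-8, nrow(counts))
  if (sum(ok) >= 2) {
    n_bins <- min(20, max(1, floor(sum(ok) / 5)))
    bins <- cut(rank(base_mean[ok], ties.method = "first"),
                breaks = n_bins, labels = FALSE)
    target <- tapply(log(mom[ok]), bins, mean, trim = 0.1)
    alpha[ok] <- exp(0.7 * log(mom[ok]) + 0.3 * target[bins])
  } else if (any(ok)) {
    alpha[ok] <- mom[ok]
  }
  alpha <- pmax(alpha, 1e-8)
  tibble::tibble(gene = rownames(counts), baseMean = base_mean,
                 alpha = alpha, alpha_raw = mom,
                 floored = !ok)
}

#' Negative-binomial Wald test for one contrast
#'
#' Per gene, a negative-binomial GLM with log link, size factors as
#' multiplicative offsets and a single condition indicator
#' (test vs reference). Fitted by iteratively reweighted least squares
#' (at most 50 iterations, relative deviance tolerance 1e-8), vectorized
#' across genes. The reported log2 fold change is the coefficient over
#' ln 2, oriented test over reference; p is the two-sided normal tail of
#' coefficient/SE. Genes with zero counts in both groups are untestable
#' (p = NA).
#'
#' @param counts count matrix (genes x samples).
#' @param samples sample table.
#' @param contrast list/vector with `test` and `ref` condition names.
#' @param size_factors per-sample factors (for all columns of `counts`).
#' @param alphas per-gene dispersions (vector aligned with rows).
#' @return tibble: gene, baseMean, log2fc, se, stat, p, converged.
#' @export
wald_test <- function(counts, samples, contrast, size_factors, alphas) {
  test <- contrast[["test"]]; ref <- contrast[["ref"]]
  missing <- setdiff(c(test, ref), samples$condition)
  if (length(missing))
    stop("contrast condition(s) absent from sample table: ",
         paste(missing, collapse = ", "))
  idx <- which(samples$condition %in% c(test, ref))
  if (sum(samples$condition == test) < 2 || sum(samples$condition == ref) < 2)
    stop("each contrast condition needs >= 2 samples")
  y <- counts[, idx, drop = FALSE]
  sf <- size_factors[idx]
  tind <- as.numeric(samples$condition[idx] == test)
  off <- matrix(log(sf), nrow(y), length(idx), byrow = TRUE)
  alphas <- pmax(alphas, 1e-8)

  norm <- sweep(y, 2, sf, "/")
  mu_ref <- rowMeans(norm[, tind == 0, drop = FALSE])
  mu_test <- rowMeans(norm[, tind == 1, drop = FALSE])
  b0 <- log(pmax(mu_ref, 1e-3))
  b1 <- log(pmax(mu_test, 1e-3)) - b0
  clamp <- 15    # natural-log bound; complete-separation guard
  minmu <- 0.5   # floor on fitted means so separated genes keep finite SE

  nb_dev <- function(b0, b1) {
    mu <- pmax(exp(outer(b0, rep(1, length(idx))) + outer(b1, tind) + off),
               0.5)
    k <- 1 / alphas
    # 2*(loglik(saturated) - loglik(mu)), NB with fixed dispersion
    term <- ifelse(y > 0, y * log(y / mu), 0)
    2 * rowSums(term - (y + k) * log((y + k) / (mu + k)))
  }

  dev <- nb_dev(b0, b1)
  converged <- rep(FALSE, nrow(y))
  for (it in seq_len(50)) {
    eta <- outer(b0, rep(1, length(idx))) + outer(b1, tind) + off
    mu <- pmax(exp(eta), minmu)
    w <- mu / (1 + alphas * mu)
    z <- eta - off + (y - mu) / mu
    A <- rowSums(w); B <- rowSums(w * rep(tind, each = nrow(y)))
    r1 <- rowSums(w * z); r2 <- rowSums(w * z * rep(tind, each = nrow(y)))
    b0_new <- (r1 - r2) / pmax(A - B, 1e-12)
    b1_new <- pmin(pmax(r2 / pmax(B, 1e-12) - b0_new, -clamp), clamp)
    b0 <- b0_new; b1 <- b1_new
    dev_new <- nb_dev(b0, b1)
    done <- abs(dev_new - dev) < 1e-8 * (abs(dev) + 0.1)
    converged <- converged | done
    dev <- dev_new
    if (all(done)) break
  }
  eta <- outer(b0, rep(1, length(idx))) + outer(b1, tind) + off
  mu <- pmax(exp(eta), minmu)
  w <- mu / (1 + alphas * mu)
  A <- rowSums(w); B <- rowSums(w * rep(tind, each = nrow(y)))
  se_b1 <- sqrt(A / pmax(B * (A - B), 1e-24))
  stat <- b1 / se_b1
  p <- 2 * pnorm(-abs(stat))
  untestable <- rowSums(y) == 0
  p[untestable | !converged] <- NA
  tibble::tibble(gene = rownames(y), baseMean = rowMeans(norm),
                 log2fc = b1 / log(2), se = se_b1 / log(2),
                 stat = stat, p = p, converged = converged & !untestable)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; NA p-values are preserved and excluded from
#' the number of tests.
#'
#' @param p numeric vector of raw p-values in \[0,1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Differential expression for one contrast
#'
#' Composition of the stage: size factors (median-of-ratios, computed on
#' the supplied matrix unless given), condition-aware dispersion
#' estimation, the negative-binomial Wald test, and per-contrast BH
#' adjustment. The endogenous profile is the `iLuc` vs `iEF` contrast;
#' construct profiles are construct vs `iEF`.
#'
#' @inheritParams wald_test
#' @param test,ref condition names (ref defaults to "iEF").
#' @param size_factors,alphas optional precomputed values.
#' @return DETable tibble: gene, baseMean, log2fc, se, stat, p, padj.
#' @export
differential_expression <- function(counts, samples, test, ref = "iEF",
                                    size_factors = NULL, alphas = NULL) {
  stopifnot(identical(colnames(counts), samples$sample))
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(alphas)) {
    disp <- estimate_dispersion(counts, size_factors, samples$condition)
    alphas <- disp$alpha
  }
  de <- wald_test(counts, samples, list(test = test, ref = ref),
                  size_factors, alphas)
  de$padj <- bh_adjust(de$p)
  de
}
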