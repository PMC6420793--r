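#' Filter genes with low counts
#'
#' Removes genes averaging fewer than 1 count per sample (total count below
#' the number of samples), the standard pre-filter before differential
#' expression. Gene order is preserved.
#'
#' @param counts integer matrix, genes x samples, with rownames.
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts) {
  if (!nrow(counts) || !ncol(counts)) {
    warning("empty count matrix; nothing to filter")
    return(counts)
  }
  counts[rowSums(counts) >= ncol(counts), , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's median ratio of its
#' counts to the gene-wise geometric mean, over genes with nonzero counts
#' in every sample, rescaled to geometric mean 1.
#'
#' @param counts count matrix, genes x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has nonzero counts in all samples; relax the filter or ",
         "supply size factors computed on a larger reference set")
  lgm <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2, function(cnt)
    exp(median(log(cnt) - lgm)))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Empirical-Bayes batch adjustment of a log-expression matrix
#'
#' Parametric location/scale batch adjustment: per gene the matrix is
#' standardized against the design (batch means plus condition
#' covariates), per-batch location effects get a normal prior and
#' per-batch scale effects an inverse-gamma prior, both estimated from
#' the data; posterior means are found by fixed-point iteration
#' (tolerance 1e-6, at most 100 iterations), and the standardized values
#' are shifted/rescaled accordingly before condition effects and grand
#' means are restored. With a single batch the input is returned
#' unchanged.
#'
#' @param x numeric matrix, genes x samples (log2 scale).
#' @param samples tibble with `sample`, `condition`, `batch` matching the
#'   columns of `x`.
#' @param covariates character vector of `samples` columns to preserve as
#'   biological covariates (default `"condition"`).
#' @return the adjusted matrix, same dimensions.
#' @export
combat_adjust <- function(x, samples, covariates = "condition") {
  stopifnot(ncol(x) == nrow(samples))
  batch <- factor(samples$batch)
  if (nlevels(batch) < 2) return(x)
  n_per_batch <- table(batch)
  if (any(n_per_batch < 2))
    stop("every batch needs >= 2 samples for scale estimation")

  B <- model.matrix(~ 0 + batch)
  C <- NULL
  for (cv in covariates) {
    f <- factor(samples[[cv]])
    if (nlevels(f) > 1) {
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      C <- cbind(C, mm)
    }
  }
  X <- cbind(B, C)
  if (qr(X)$rank < ncol(X)) {
    conf <- find_confounded_pair(samples, covariates)
    stop("batch '", conf[1], "' is confounded with ", conf[2],
         " level '", conf[3], "'; cannot separate batch from condition")
  }

  n <- ncol(x)
  beta <- t(solve(crossprod(X), crossprod(X, t(x))))  # genes x coef
  I <- nlevels(batch)
  grand <- as.vector(beta[, seq_len(I), drop = FALSE] %*%
                       (as.numeric(n_per_batch) / n))
  stand_mean <- matrix(grand, nrow(x), n)
  if (!is.null(C))
    stand_mean <- stand_mean +
      beta[, -seq_len(I), drop = FALSE] %*% t(C)
  var_pooled <- rowMeans((x - t(X %*% t(beta)))^2)
  var_pooled <- pmax(var_pooled, 1e-12)
  z <- (x - stand_mean) / sqrt(var_pooled)

  z_adj <- z
  for (lev in levels(batch)) {
    idx <- which(batch == lev)
    n_i <- length(idx)
    zi <- z[, idx, drop = FALSE]
    g_hat <- rowMeans(zi)
    d_hat <- pmax(apply(zi, 1, var), 1e-12)
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    if (!is.finite(t2) || t2 < 1e-12) t2 <- 1e-12
    m <- mean(d_hat); s2 <- var(d_hat)
    if (is.finite(s2) && s2 > 1e-12) {
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      g_star <- g_hat; d_star <- d_hat
      for (it in seq_len(100)) {
        g_new <- (n_i * t2 * g_hat + d_star * g_bar) / (n_i * t2 + d_star)
        sum2 <- rowSums((zi - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (n_i / 2 + a_prior - 1)
        change <- max(abs(g_new - g_star) / pmax(abs(g_star), 1e-8),
                      abs(d_new - d_star) / d_star)
        g_star <- g_new; d_star <- d_new
        if (change < 1e-6) break
      }
    } else {
      # degenerate scale spread: shrink locations only
      g_star <- (n_i * t2 * g_hat + d_hat * g_bar) / (n_i * t2 + d_hat)
      d_star <- d_hat
    }
    z_adj[, idx] <- (zi - g_star) / sqrt(d_star)
  }
  z_adj * sqrt(var_pooled) + stand_mean
}

find_confounded_pair <- function(samples, covariates) {
  for (cv in covariates) {
    tab <- table(samples$batch, samples[[cv]])
    for (b in rownames(tab)) {
      lv <- colnames(tab)[tab[b, ] > 0]
      if (length(lv) == 1) return(c(b, cv, lv))
    }
    for (l in colnames(tab)) {
      bt <- rownames(tab)[tab[, l] > 0]
      if (length(bt) == 1) return(c(bt[1], cv, l))
    }
  }
  c("?", covariates[1], "?")
}

#' Filter, normalize and batch-adjust a count matrix
#'
#' The full preprocessing stage: low-count filter, median-of-ratios size
#' factors, log2(normalized + 1) transform, empirical-Bayes batch
#' adjustment, and back-transformation to non-negative integer
#' pseudo-counts (`round(2^x - 1)`, clipped at 0) for the count-based
#' differential-expression stage. The un-rounded adjusted log matrix is
#' kept for clustering and PCA.
#'
#' @param counts raw count matrix, genes x samples.
#' @param samples sample table (sample, condition, batch).
#' @return list: `counts` (filtered raw), `size_factors`, `log_adjusted`
#'   (genes x samples, log2 scale), `pseudo_counts` (integer matrix).
#' @export
preprocess_counts <- function(counts, samples) {
  stopifnot(identical(colnames(counts), samples$sample))
  filtered <- filter_low_counts(counts)
  sf <- estimate_size_factors(filtered)
  logn <- log2(sweep(filtered, 2, sf, "/") + 1)
  adj <- combat_adjust(logn, samples)
  pseudo <- round(pmax(2^adj - 1, 0))
  storage.mode(pseudo) <- "integer"
  list(counts = filtered, size_factors = sf, log_adjusted = adj,
       pseudo_counts = pseudo)
}
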