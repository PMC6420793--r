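#' Most variable genes
#'
#' Genes ranked by across-sample variance of (log-scale) expression;
#' ties broken lexicographically by gene id.
#'
#' @param x expression matrix, genes x samples, with rownames.
#' @param n number of genes to return (`n <= 0` gives an empty vector).
#' @return character vector of gene ids, most variable first.
#' @export
top_variable_genes <- function(x, n = 100) {
  if (n <= 0) return(character(0))
  stopifnot(n <= nrow(x))
  v <- apply(x, 1, var)
  rownames(x)[order(-v, rownames(x))][seq_len(n)]
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering of the rows of `x` with complete linkage
#' (inter-cluster distance = maximum pairwise distance). The default
#' metric is Euclidean distance on row-standardized values (z-scores),
#' the convention for expression heatmaps; `"correlation"` uses
#' 1 - Pearson correlation between rows; `"euclidean"` uses the raw
#' values.
#'
#' @param x numeric matrix (items in rows).
#' @param metric one of "euclidean_z", "euclidean", "correlation".
#' @return an [stats::hclust] object.
#' @export
hierarchical_cluster <- function(x, metric = c("euclidean_z", "euclidean",
                                               "correlation")) {
  metric <- match.arg(metric)
  stopifnot(nrow(x) >= 2)
  d <- switch(metric,
    euclidean_z = {
      z <- t(scale(t(x)))
      z[is.nan(z)] <- 0  # zero-variance rows
      dist(z)
    },
    euclidean = dist(x),
    correlation = as.dist(1 - cor(t(x))))
  if (any(is.na(d))) stop("NA distances; check input for missing values")
  hclust(d, method = "complete")
}

#' PCA of sample profiles
#'
#' Samples are observations; genes are centered (not scaled). Scores come
#' from the top right-singular directions, with a fixed sign convention:
#' the largest-magnitude gene loading of each component is positive.
#'
#' @param x expression matrix, genes x samples.
#' @param n_components number of components to return.
#' @return list: `scores` (samples x components), `var_frac`
#'   (per-component variance fractions, non-increasing).
#' @export
pca_scores <- function(x, n_components = 2) {
  stopifnot(ncol(x) >= 2)
  n_components <- min(n_components, ncol(x) - 1, nrow(x))
  if (all(apply(x, 1, var) == 0)) {
    scores <- matrix(0, ncol(x), n_components,
                     dimnames = list(colnames(x),
                                     paste0("PC", seq_len(n_components))))
    return(list(scores = scores, var_frac = rep(NA_real_, n_components)))
  }
  pr <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- pr$x[, k, drop = FALSE]
  for (j in k) {
    lead <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[lead, j] < 0) scores[, j] <- -scores[, j]
  }
  var_frac <- (pr$sdev^2 / sum(pr$sdev^2))[k]
  list(scores = scores, var_frac = var_frac)
}
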