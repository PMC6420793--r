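#' Simulate a knockdown/rescue RNA-seq experiment
#'
#' Draws a gene-by-sample integer count matrix under a negative-binomial
#' model with planted ground truth. Per gene `g` and sample `j` the mean is
#' `mu_gj = 2^(b_g + x_gc + beta_gb) * L_j` where `b_g` is the log2
#' baseline, `x_gc` the condition effect implied by the truth table (iEF,
#' the knockdown control, carries no effect; iLuc carries the endogenous
#' log2FC; each rescue construct carries its construct log2FC), `beta_gb`
#' an additive per-batch per-gene shift, and `L_j` a log-normal library-size
#' factor. Counts are `NB(mu, alpha_g * delta_b)` where `delta_b` is a
#' per-batch dispersion multiplier (mean 1), so batches differ in both
#' location and scale.
#'
#' Planted set sizes are deterministic: exactly
#' `round(frac_endo_activated * n_genes)` genes are activated, and per
#' construct exactly `round(rescue_frac * n)` of the endo-regulated genes
#' (per element class if `rescue_frac` is a named vector) are rescued, of
#' which `round(paradox_frac * n_rescued)` have the sign of their construct
#' effect flipped (paradoxical regulation). Rescued concordant genes get
#' `construct_lfc = s * endo_lfc`; paradoxical genes `-s * endo_lfc`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix, genes x samples), `samples`
#'   (tibble: sample, condition, batch) and `truth` (list of two tibbles:
#'   `genes` with endo_class/endo_lfc/element_class, `constructs` with
#'   per-construct rescued/direction/construct_lfc).
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  truth <- simulate_truth(config)

  set.seed(derive_seed(config$seed, "counts"))
  n <- config$n_genes
  genes <- truth$genes$gene
  conds <- config$conditions
  n_b <- config$n_batches

  baseline <- rnorm(n, config$baseline_mean_log2[["mean"]],
                    config$baseline_mean_log2[["sd"]])
  alpha <- rlnorm(n, config$dispersion[["meanlog"]], config$dispersion[["sdlog"]])

  samples <- tibble::tibble(
    sample = as.vector(outer(conds, seq_len(n_b), function(c, b) sprintf("%s_b%d", c, b))),
    condition = rep(conds, times = n_b),
    batch = sprintf("batch%d", rep(seq_len(n_b), each = length(conds)))
  )

  # condition effect matrix (genes x conditions), from truth
  cond_lfc <- matrix(0, n, length(conds), dimnames = list(genes, conds))
  cond_lfc[, "iLuc"] <- truth$genes$endo_lfc
  for (nm in names(config$constructs)) {
    tc <- truth$constructs[truth$constructs$construct == nm, ]
    cond_lfc[, nm] <- tc$construct_lfc[match(genes, tc$gene)]
  }

  batch_shift <- matrix(rnorm(n * n_b, 0, config$batch_shift_sd), n, n_b)
  delta_b <- rgamma(n_b, shape = config$batch_scale_shape,
                    rate = config$batch_scale_shape)
  libsize <- rlnorm(nrow(samples), 0, config$libsize_sdlog)

  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    b <- as.integer(sub("batch", "", samples$batch[j]))
    mu <- 2^(baseline + cond_lfc[, samples$condition[j]] + batch_shift[, b]) *
      libsize[j]
    counts[, j] <- rnbinom(n, mu = mu, size = 1 / (alpha * delta_b[b]))
  }
  storage.mode(counts) <- "integer"

  truth$params <- list(baseline_log2 = baseline, dispersion = alpha,
                       libsize = libsize, batch_dispersion_mult = delta_b)
  list(counts = counts, samples = samples, truth = truth)
}

# Planted ground truth: endo classes and effects, element-class membership,
# per-construct rescue flags and effects. Deterministic counts, random
# identities under the "truth" sub-seed.
simulate_truth <- function(config) {
  set.seed(derive_seed(config$seed, "truth"))
  n <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(n))

  n_act <- round(config$frac_endo_activated * n)
  n_rep <- round(config$frac_endo_repressed * n)
  ord <- sample.int(n)
  endo_class <- rep("null", n)
  endo_class[ord[seq_len(n_act)]] <- "activated"
  if (n_rep > 0) endo_class[ord[n_act + seq_len(n_rep)]] <- "repressed"

  mag <- abs(rnorm(n, config$endo_lfc[["mean"]], config$endo_lfc[["sd"]]))
  endo_lfc <- ifelse(endo_class == "activated", mag,
                     ifelse(endo_class == "repressed", -mag, 0))

  # element-class membership among endo-regulated genes; classes are
  # structural (which planted element, if any, is linked to the gene)
  ec <- config$element_config
  regulated <- which(endo_class != "null")
  want <- c(ms_prom = ec$n_promoter_ms, ms_enh = ec$n_enhancer_ms,
            ets = ec$n_ets, other = ec$n_other_fli)
  if (sum(want) > length(regulated))
    stop("element_config requests more element-linked genes (", sum(want),
         ") than endo-regulated genes (", length(regulated), ")")
  element_class <- rep("none", n)
  picked <- sample(regulated, sum(want))
  element_class[picked] <- rep(names(want), times = want)

  gene_tbl <- tibble::tibble(gene = genes, endo_class = endo_class,
                             endo_lfc = endo_lfc, element_class = element_class)

  construct_rows <- lapply(names(config$constructs), function(nm) {
    co <- config$constructs[[nm]]
    rescued <- rep(FALSE, n)
    if (length(co$rescue_frac) == 1 && is.null(names(co$rescue_frac))) {
      n_resc <- round(co$rescue_frac * length(regulated))
      rescued[sample(regulated, n_resc)] <- TRUE
    } else {
      for (cls in names(co$rescue_frac)) {
        pool <- which(endo_class != "null" & element_class == cls)
        n_resc <- round(co$rescue_frac[[cls]] * length(pool))
        if (n_resc > 0) rescued[sample(pool, n_resc)] <- TRUE
      }
    }
    direction <- rep(NA_character_, n)
    ridx <- which(rescued)
    n_para <- round(co$paradox_frac * length(ridx))
    para <- if (n_para > 0) sample(ridx, n_para) else integer(0)
    direction[ridx] <- "concordant"
    direction[para] <- "paradoxical"
    construct_lfc <- rep(0, n)
    construct_lfc[ridx] <- co$attenuation * endo_lfc[ridx]
    construct_lfc[para] <- -construct_lfc[para]
    tibble::tibble(gene = genes, construct = nm, rescued = rescued,
                   direction = direction, construct_lfc = construct_lfc)
  })

  list(genes = gene_tbl, constructs = dplyr::bind_rows(construct_rows))
}
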