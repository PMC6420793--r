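#' Configuration for the synthetic knockdown/rescue experiment
#'
#' Bundles all parameters of the generative model: per-gene baselines and
#' negative-binomial dispersions, the endogenous EWS/FLI signature (fractions
#' of activated/repressed genes and their log2 effect sizes), per-construct
#' rescue behaviour (fraction of the endogenous signature rescued, attenuation
#' of the rescued effect, fraction of rescued genes regulated in the wrong
#' direction), batch structure, and the planted response-element landscape.
#'
#' The defaults emulate the study design the pipeline targets: conditions
#' iLuc (no knockdown), iEF (EWS/FLI knockdown, the control for every
#' contrast) and three rescue constructs with qualitatively distinct
#' behaviour - a near-full rescue ("WT", rescue fraction 0.75, attenuation
#' 0.8), a partial rescue with substantial paradoxical activity ("DAF",
#' 0.40 / 0.5, paradox 0.30) and a functionally dead construct ("DEAD",
#' 0.02 / 0.1). Three replicate batches each contribute one sample per
#' condition.
#'
#' @param n_genes number of genes.
#' @param constructs named list; one entry per rescue construct with fields
#'   `rescue_frac` (scalar in \[0,1\], or a named vector over element classes
#'   `ms_prom`, `ms_enh`, `ets`, `other`, `none`), `attenuation` (slope `s`
#'   in \[0,1.5\] of construct log2FC per endogenous log2FC) and
#'   `paradox_frac` (fraction of rescued genes with flipped sign).
#' @param conditions condition names; must contain `"iLuc"`, `"iEF"` and
#'   every construct name.
#' @param n_batches replicate batches; each batch holds one sample per
#'   condition.
#' @param baseline_mean_log2 `c(mean, sd)` of the per-gene log2 baseline.
#' @param dispersion `c(meanlog, sdlog)` of the per-gene log-normal NB
#'   dispersion (Var = mu + alpha mu^2).
#' @param frac_endo_activated,frac_endo_repressed fractions of genes
#'   activated/repressed by endogenous EWS/FLI (iLuc over iEF).
#' @param endo_lfc `c(mean, sd)` of the magnitude of endogenous log2 effects.
#' @param batch_shift_sd sd of the additive per-batch, per-gene log2 shift.
#' @param batch_scale_shape gamma shape of the per-batch dispersion
#'   multiplier (mean 1; larger = milder batch-to-batch variance effects).
#' @param libsize_sdlog sdlog of the per-sample library-size factor.
#' @param element_config list controlling the planted response elements:
#'   counts `n_promoter_ms`, `n_enhancer_ms`, `n_ets`, `n_other_fli`;
#'   `repeat_length = c(min, max)` GGAA units per microsatellite;
#'   `promoter_distance`, `enhancer_distance`, `ets_distance` =
#'   `c(min, max)` bp from element edge to TSS; `gene_spacing` and
#'   `enhancer_gene_spacing` bp between TSSs on the element-bearing
#'   synthetic chromosomes.
#' @param seed integer seed; identical configs give byte-identical output.
#'
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 6000,
                       constructs = list(
                         WT   = list(rescue_frac = 0.75, attenuation = 0.8, paradox_frac = 0.05),
                         DAF  = list(rescue_frac = 0.40, attenuation = 0.5, paradox_frac = 0.30),
                         DEAD = list(rescue_frac = 0.02, attenuation = 0.1, paradox_frac = 0.10)
                       ),
                       conditions = c("iLuc", "iEF", names(constructs)),
                       n_batches = 3,
                       baseline_mean_log2 = c(mean = 6, sd = 2),
                       dispersion = c(meanlog = log(0.02), sdlog = 0.5),
                       frac_endo_activated = 0.2,
                       frac_endo_repressed = 0.2,
                       endo_lfc = c(mean = 2, sd = 0.5),
                       batch_shift_sd = 0.3,
                       batch_scale_shape = 20,
                       libsize_sdlog = 0.2,
                       element_config = list(
                         n_promoter_ms = 40, n_enhancer_ms = 40,
                         n_ets = 40, n_other_fli = 0,
                         repeat_length = c(min = 5, max = 25),
                         promoter_distance = c(min = 500, max = 4500),
                         enhancer_distance = c(min = 6000, max = 25000),
                         ets_distance = c(min = 200, max = 4000),
                         gene_spacing = 12000,
                         enhancer_gene_spacing = 60000
                       ),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), constructs = constructs,
    conditions = conditions, n_batches = as.integer(n_batches),
    baseline_mean_log2 = baseline_mean_log2, dispersion = dispersion,
    frac_endo_activated = frac_endo_activated,
    frac_endo_repressed = frac_endo_repressed,
    endo_lfc = endo_lfc, batch_shift_sd = batch_shift_sd,
    batch_scale_shape = batch_scale_shape, libsize_sdlog = libsize_sdlog,
    element_config = element_config, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- c("sim_config", "list")
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes <= 0) stop("n_genes must be positive: nothing to simulate")
  if (!all(c("iLuc", "iEF") %in% cfg$conditions))
    stop("conditions must include 'iLuc' and 'iEF'")
  unknown <- setdiff(names(cfg$constructs), cfg$conditions)
  if (length(unknown))
    stop("construct(s) not in conditions: ", paste(unknown, collapse = ", "))
  fr <- c(cfg$frac_endo_activated, cfg$frac_endo_repressed)
  if (any(fr < 0 | fr > 1)) stop("endo fractions must be in [0,1]")
  if (sum(fr) > 1) stop("frac_endo_activated + frac_endo_repressed must be <= 1")
  for (nm in names(cfg$constructs)) {
    co <- cfg$constructs[[nm]]
    if (any(co$rescue_frac < 0 | co$rescue_frac > 1))
      stop("rescue_frac out of [0,1] for ", nm)
    if (co$attenuation < 0 || co$attenuation > 1.5)
      stop("attenuation out of [0,1.5] for ", nm)
    if (co$paradox_frac < 0 || co$paradox_frac > 1)
      stop("paradox_frac out of [0,1] for ", nm)
  }
  if (cfg$batch_shift_sd > 0 && cfg$n_batches < 2)
    stop("n_batches must be >= 2 when batch effects are nonzero")
  ec <- cfg$element_config
  cnt <- unlist(ec[c("n_promoter_ms", "n_enhancer_ms", "n_ets", "n_other_fli")])
  if (any(cnt < 0)) stop("element counts must be >= 0")
  invisible(cfg)
}

# Sub-seeds are derived deterministically from the top-level seed, one per
# generator component, so that e.g. changing gene-level draws does not
# perturb element placement. Kept below 2^31 - 1.
derive_seed <- function(seed, component) {
  offsets <- c(truth = 11, counts = 29, annotation = 47, enrichment = 61)
  as.integer((as.numeric(seed) * 7919 + offsets[[component]]) %% 2147483647)
}
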