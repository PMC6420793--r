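# Run the knockdown/rescue study at the stated conditions and measure the
# pipeline's recovered rescue proportions and strengths for one seed.
run_recovery_study <- function(seed, constructs, n_genes = 6000,
                               n_batches = 3) {
  cfg <- sim_config(n_genes = n_genes, constructs = constructs,
                    n_batches = n_batches,
                    element_config = small_sim_config()$element_config,
                    seed = seed)
  sim <- simulate_experiment(cfg)
  pp <- preprocess_counts(sim$counts, sim$samples)
  sf <- estimate_size_factors(pp$pseudo_counts)
  disp <- estimate_dispersion(pp$pseudo_counts, sf, sim$samples$condition)
  endo <- differential_expression(pp$pseudo_counts, sim$samples, "iLuc",
                                  "iEF", sf, disp$alpha)
  out <- lapply(names(constructs), function(cn) {
    de <- differential_expression(pp$pseudo_counts, sim$samples, cn,
                                  "iEF", sf, disp$alpha)
    calls <- classify_rescue_status(endo, de)
    endo_reg <- calls$status %in% c("both_significant", "kd_only")
    st <- rescue_strength(calls)
    both <- calls[calls$status == "both_significant", ]
    tibble::tibble(
      construct = cn,
      frac_rescued = sum(calls$status == "both_significant") / sum(endo_reg),
      n_endo_regulated = sum(endo_reg),
      slope = st$slope, pearson_r = st$pearson_r,
      frac_paradoxical = mean(!both$concordant))
  })
  dplyr::bind_rows(out)
}

acceptance_constructs <- function(paradox = c(WT = 0, DAF = 0, DEAD = 0)) {
  list(
    WT   = list(rescue_frac = 0.75, attenuation = 0.8,
                paradox_frac = paradox[["WT"]]),
    DAF  = list(rescue_frac = 0.40, attenuation = 0.5,
                paradox_frac = paradox[["DAF"]]),
    DEAD = list(rescue_frac = 0.02, attenuation = 0.1,
                paradox_frac = paradox[["DEAD"]]))
}
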