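test_that("rescue status follows the significance 2x2", {
  endo <- make_de(c("a", "b", "c", "d"), log2fc = c(2, 1.5, 0.5, -1),
                  padj = c(0.01, 0.01, 0.40, 0.30))
  cons <- make_de(c("a", "b", "c", "d"), log2fc = c(1, -0.5, 2, 0.2),
                  padj = c(0.03, 0.50, 0.01, 0.40))
  calls <- classify_rescue_status(endo, cons)
  got <- setNames(calls$status, calls$gene)
  expect_equal(unname(got["a"]), "both_significant")
  expect_equal(unname(got["b"]), "kd_only")
  expect_equal(unname(got["c"]), "rescue_only")
  expect_equal(unname(got["d"]), "neither")
  expect_true(calls$concordant[calls$gene == "a"])  # both up
  expect_true(is.na(calls$concordant[calls$gene == "b"]))
})

test_that("statuses partition the shared universe and flag NA padj", {
  set.seed(301)
  genes <- sprintf("g%03d", 1:200)
  endo <- make_de(genes, log2fc = rnorm(200), padj = runif(200))
  cons <- make_de(genes, log2fc = rnorm(200), padj = runif(200))
  cons$padj[1:5] <- NA
  calls <- classify_rescue_status(endo, cons)
  expect_equal(nrow(calls), 200)
  expect_equal(sum(table(calls$status)), 200)
  expect_true(all(calls$partial[1:5]))
  # NA treated conservatively as non-significant
  expect_true(all(calls$status[1:5] %in% c("kd_only", "neither")))
  expect_error(classify_rescue_status(endo, make_de("zzz", 1, 0.5)),
               "share no genes")
})

test_that("fidelity fractions are restricted to endo-regulated genes", {
  genes <- sprintf("g%03d", 1:90)
  classes <- tibble::tibble(gene = genes,
                            class = rep(c("ms_prom_act", "ets_direct",
                                          "none"), each = 30))
  endo <- make_de(genes, log2fc = 2, padj = 0.01)

  dead <- make_de(genes, log2fc = 0.1, padj = 0.9)
  f_dead <- direction_fidelity(classify_rescue_status(endo, dead), classes)
  expect_true(all(f_dead$frac_unchanged == 1))

  f_perfect <- direction_fidelity(classify_rescue_status(endo, endo), classes)
  expect_true(all(f_perfect$frac_rescued_concordant == 1))
  expect_true(all(f_perfect$frac_paradoxical == 0))

  sums <- rowSums(f_perfect[, c("frac_rescued_concordant",
                                "frac_paradoxical", "frac_unchanged")])
  expect_equal(sums, rep(1, nrow(f_perfect)), tolerance = 1e-9)
})

test_that("rescue-only genes are excluded from fidelity denominators", {
  genes <- c("a", "b", "c")
  endo <- make_de(genes, log2fc = c(2, 2, 0.1), padj = c(0.01, 0.01, 0.9))
  cons <- make_de(genes, log2fc = c(2, 0.1, 2), padj = c(0.01, 0.9, 0.01))
  classes <- tibble::tibble(gene = genes, class = "ms_prom_act")
  f <- direction_fidelity(classify_rescue_status(endo, cons), classes)
  expect_equal(f$n_endo_regulated, 2)  # "c" is rescue_only: excluded
})

test_that("identity and scaled rescues give exact strength values", {
  set.seed(302)
  genes <- sprintf("g%03d", 1:50)
  lfc <- rnorm(50, 0, 2)
  endo <- make_de(genes, log2fc = lfc, padj = 0.01)
  st <- rescue_strength(classify_rescue_status(endo, endo))
  expect_equal(st$pearson_r, 1)
  expect_equal(st$slope, 1)
  half <- make_de(genes, log2fc = 0.5 * lfc, padj = 0.01)
  st2 <- rescue_strength(classify_rescue_status(endo, half))
  expect_equal(st2$pearson_r, 1)
  expect_equal(st2$slope, 0.5)
  # under 3 co-significant genes: sentinel
  endo3 <- make_de(genes, log2fc = lfc,
                   padj = c(0.01, 0.01, rep(0.9, 48)))
  st3 <- rescue_strength(classify_rescue_status(endo3, endo3))
  expect_equal(st3$n, 2)
  expect_true(is.na(st3$slope))
})

test_that("planted attenuation is recovered from noisy co-significant calls", {
  set.seed(303)
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  x <- rnorm(n, 0, 2)
  y <- 0.8 * x + rnorm(n, 0, 0.3)
  endo <- make_de(genes, log2fc = x, padj = 0.01)
  cons <- make_de(genes, log2fc = y, padj = 0.01)
  st <- rescue_strength(classify_rescue_status(endo, cons))
  expect_gt(st$slope, 0.7)
  expect_lt(st$slope, 0.9)
  expect_lt(st$r_pvalue, 1e-10)
})

test_that("two-fold gene sets use strict cutoffs", {
  de <- make_de(c("at_boundary", "up", "down", "weak_p"),
                log2fc = c(1.0, 1.1, -3, 3),
                padj = c(0.01, 0.01, 0.01, 0.2))
  sets <- twofold_gene_sets(de)
  expect_false("at_boundary" %in% sets$activated)  # |FC| = 2 exactly
  expect_true("up" %in% sets$activated)
  expect_true("down" %in% sets$repressed)
  expect_false("weak_p" %in% c(sets$activated, sets$repressed))
})

test_that("the overlap chi-square matches the closed form", {
  universe <- sprintf("g%04d", 1:100)
  A <- universe[1:50]
  res <- venn_overlap_test(A, A, universe)
  expect_equal(res$chi2, 100)
  expect_lt(res$p, 1e-20)
  # independence point: overlap = |A||B|/N exactly
  B <- c(universe[1:25], universe[51:75])  # |B| = 50, overlap 25
  res2 <- venn_overlap_test(A, B, universe)
  expect_equal(res2$chi2, 0)
  expect_equal(res2$p, 1)
})

test_that("the overlap test is symmetric and matches chisq.test", {
  skip_if_not_installed("stats")
  set.seed(304)
  universe <- sprintf("g%04d", 1:500)
  for (i in 1:20) {
    A <- sample(universe, 80)
    B <- sample(universe, 120)
    res <- venn_overlap_test(A, B, universe)
    swapped <- venn_overlap_test(B, A, universe)
    expect_equal(res$chi2, swapped$chi2)
    expect_equal(res$p, swapped$p)
    tab <- table(universe %in% A, universe %in% B)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate margins yield NA with a reason", {
  universe <- sprintf("g%04d", 1:50)
  res <- venn_overlap_test(character(0), universe[1:10], universe)
  expect_true(is.na(res$p))
  expect_match(res$note, "degenerate")
  res2 <- venn_overlap_test(universe, universe[1:10], universe)
  expect_true(is.na(res2$p))
})

test_that("independent random sets reject at the nominal rate", {
  set.seed(305)
  universe <- sprintf("g%05d", 1:10000)
  rej <- 0
  nsim <- 500
  for (i in seq_len(nsim)) {
    A <- sample(universe, 1000)
    B <- sample(universe, 1000)
    rej <- rej + (venn_overlap_test(A, B, universe)$p < 0.05)
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.07)
})

test_that("the stratified summary is a per-stratum partition with strength", {
  set.seed(399)
  genes <- sprintf("g%03d", 1:40)
  lfc <- rnorm(40, 2, 0.5)
  endo <- make_de(genes, log2fc = lfc, padj = 0.01)
  cons <- make_de(genes, log2fc = 0.8 * lfc, padj = 0.01)
  calls <- classify_rescue_status(endo, cons)
  calls$construct <- "WT"
  classes <- tibble::tibble(gene = genes, class = "ms_prom_act")
  strata <- strata_rescue_summary(calls, classes)
  expect_equal(nrow(strata), 1)
  expect_equal(strata$proportion, 1)
  expect_equal(strata$status, "both_significant")
  expect_equal(strata$slope, 0.8, tolerance = 1e-9)
  # proportions sum to 1 within each construct x class stratum
  set.seed(306)
  endo2 <- make_de(genes, log2fc = rnorm(40, 0, 2), padj = runif(40))
  cons2 <- make_de(genes, log2fc = rnorm(40, 0, 2), padj = runif(40))
  calls2 <- classify_rescue_status(endo2, cons2)
  calls2$construct <- "DAF"
  strata2 <- strata_rescue_summary(calls2, classes)
  expect_equal(sum(strata2$proportion), 1, tolerance = 1e-9)
})

test_that("paradoxical fractions planted in the simulation are recovered", {
  cfg <- sim_config(
    n_genes = 2500,
    constructs = list(DAF = list(rescue_frac = 0.60, attenuation = 0.6,
                                 paradox_frac = 0.30)),
    frac_endo_activated = 0.2, frac_endo_repressed = 0.2,
    element_config = small_sim_config()$element_config,
    seed = 307)
  sim <- simulate_experiment(cfg)
  pp <- preprocess_counts(sim$counts, sim$samples)
  sf <- estimate_size_factors(pp$pseudo_counts)
  disp <- estimate_dispersion(pp$pseudo_counts, sf, sim$samples$condition)
  endo <- differential_expression(pp$pseudo_counts, sim$samples, "iLuc",
                                  "iEF", sf, disp$alpha)
  daf <- differential_expression(pp$pseudo_counts, sim$samples, "DAF",
                                 "iEF", sf, disp$alpha)
  calls <- classify_rescue_status(endo, daf)
  both <- calls[calls$status == "both_significant", ]
  est_paradox <- mean(!both$concordant)
  expect_lt(abs(est_paradox - 0.30), 0.07)
})
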