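test_that("GGAA runs are called, merged and filtered as specified", {
  p <- scan_params()
  one <- find_ggaa_microsatellites("GGAAGGAAGGAAGGAA", p)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 0L)
  expect_equal(one$end, 16L)
  expect_equal(one$total_repeats, 4L)
  expect_equal(one$max_consecutive, 4L)

  merged <- find_ggaa_microsatellites(
    "GGAAGGAAGGAAGGAATTGGAAGGAAGGAAGGAA", p)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$total_repeats, 8L)
  expect_equal(merged$max_consecutive, 4L)

  # below min_repeats: dropped
  expect_equal(nrow(find_ggaa_microsatellites("GGAAGGAA", p)), 0)
  # gap above max_gap: two separate elements, each dropped (< 4 units)
  expect_equal(nrow(find_ggaa_microsatellites(
    "GGAAGGAACCCCCGGAAGGAA", p)), 0)
  # TTCC runs come out as minus-strand elements
  minus <- find_ggaa_microsatellites("TTCCTTCCTTCCTTCC", p)
  expect_equal(minus$strand, "-")
  expect_error(find_ggaa_microsatellites("GGAAXGGAA", p), "position 5")
})

test_that("microsatellite calls match the brute-force oracle", {
  set.seed(201)
  p <- scan_params()
  for (i in 1:200) {
    # GGAA-enriched alphabet so runs actually occur
    seq <- paste(sample(c("G", "G", "A", "A", "C", "T"), 2000,
                        replace = TRUE), collapse = "")
    got <- find_ggaa_microsatellites(seq, p)
    plus <- got[got$strand == "+", ]
    want <- oracle_ggaa_scan(seq, p$min_repeats, p$max_gap, "GGAA")
    expect_equal(plus$start, want$start)
    expect_equal(plus$end, want$end)
    expect_equal(plus$max_consecutive, want$max_consecutive)
    expect_equal(plus$total_repeats, want$total_repeats)
    minus <- got[got$strand == "-", ]
    want_m <- oracle_ggaa_scan(seq, p$min_repeats, p$max_gap, "TTCC")
    expect_equal(minus$start, want_m$start)
    expect_equal(minus$total_repeats, want_m$total_repeats)
  }
})

test_that("scanners are case-insensitive and mirror under revcomp", {
  p <- scan_params()
  seq <- "ggaaGGaaggAAGGAA"
  expect_equal(find_ggaa_microsatellites(seq, p)$total_repeats, 4L)
  set.seed(202)
  for (i in 1:20) {
    seq <- paste(sample(c("G", "A", "C", "T", "G", "A"), 500, TRUE),
                 collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    fwd <- find_ggaa_microsatellites(seq, p)
    rev <- find_ggaa_microsatellites(rc, p)
    n <- nchar(seq)
    # mirrored coordinates, swapped strands
    mirrored <- tibble::tibble(start = n - rev$end, end = n - rev$start,
                               strand = as.character(ifelse(rev$strand == "+", "-", "+")),
                               max_consecutive = rev$max_consecutive,
                               total_repeats = rev$total_repeats)
    o1 <- order(fwd$start, fwd$strand)
    o2 <- order(mirrored$start, mirrored$strand)
    expect_equal(fwd$start[o1], mirrored$start[o2])
    expect_equal(fwd$end[o1], mirrored$end[o2])
    expect_equal(fwd$strand[o1], mirrored$strand[o2])
    expect_equal(fwd$total_repeats[o1], mirrored$total_repeats[o2])
  }
})

test_that("raising min_repeats never increases the number of calls", {
  set.seed(203)
  for (i in 1:30) {
    seq <- paste(sample(c("G", "G", "A", "A", "T"), 1500, TRUE),
                 collapse = "")
    n_calls <- vapply(2:8, function(mr)
      nrow(find_ggaa_microsatellites(seq, scan_params(min_repeats = mr))),
      integer(1))
    expect_true(all(diff(n_calls) <= 0))
  }
})

test_that("ETS motif scanning expands the IUPAC consensus on both strands", {
  p <- scan_params()
  plus <- scan_ets_motif("ACAGGAAGC", p)
  expect_equal(nrow(plus), 1)
  expect_equal(plus$strand, "+")
  expect_equal(plus$start, 0L)
  minus <- scan_ets_motif("GCTTCCTGT", p)
  expect_equal(nrow(minus), 1)
  expect_equal(minus$strand, "-")
  expect_equal(nrow(scan_ets_motif("ACTGGAAGC", p)), 0)  # T at M position
  # overlapping matches are all reported
  two <- scan_ets_motif("ACAGGAAGCACCGGAAAT", p)
  expect_equal(nrow(two), 2)
})

test_that("ETS calls match the enumeration oracle on random sequence", {
  set.seed(204)
  p <- scan_params()
  for (i in 1:200) {
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    got <- scan_ets_motif(seq, p)
    want <- oracle_ets_scan(seq)
    o1 <- order(got$start, got$strand)
    o2 <- order(want$start, want$strand)
    expect_equal(got$start[o1], want$start[o2])
    expect_equal(got$strand[o1], want$strand[o2])
  }
})

test_that("element-TSS distance follows the edge convention", {
  expect_equal(element_gene_distance("c", 1000, 1100, "c", 1050), 0)
  expect_equal(element_gene_distance("c", 1000, 1100, "c", 1600), 500)
  expect_equal(element_gene_distance("c", 1000, 1100, "c", 400), 600)
  expect_true(is.na(element_gene_distance("c1", 0, 10, "c2", 5)))
})

test_that("response classes follow distance, window and precedence rules", {
  genes <- tibble::tibble(
    chrom = "c", tss = c(10000, 100000, 300000, 400000, 450000),
    strand = c("+", "+", "-", "+", "+"),
    gene = c("prom_act", "enh_rep", "ets_minus", "nonsig", "noelement"))
  elements <- tibble::tibble(
    element = c("ms1", "ms2", "ets1"),
    chrom = "c",
    start = c(10000 - 4999 - 40, 100000 + 50000, 300000 + 800),
    end = c(10000 - 4999, 100000 + 50000 + 40, 300000 + 809),
    strand = c("+", "+", "+"),
    type = c("ggaa_ms", "ggaa_ms", "ets_motif"),
    max_consecutive = c(10L, 10L, NA), total_repeats = c(10L, 10L, NA),
    fli_enrichment = NA_real_)
  endo <- make_de(genes$gene, log2fc = c(2, -2, 1.5, 3, 1),
                  padj = c(0.01, 0.01, 0.01, 0.5, 0.01))
  cls <- assign_response_classes(genes, elements, endo,
                                 scan_params(assoc_radius = 60000))
  got <- setNames(cls$class, cls$gene)
  expect_equal(unname(got["prom_act"]), "ms_prom_act")   # 4999 < 5 kb
  expect_equal(unname(got["enh_rep"]), "ms_enh_rep")     # 50 kb away
  # minus-strand gene: motif 800 bp right of TSS is upstream in gene
  # orientation, inside the direct window
  expect_equal(unname(got["ets_minus"]), "ets_direct")
  expect_equal(unname(got["nonsig"]), "none")            # endo padj 0.5
  expect_equal(unname(got["noelement"]), "none")
  # partition: exactly one class per gene
  expect_equal(nrow(cls), length(unique(cls$gene)))
})

test_that("microsatellites outrank ETS motifs and the radius is enforced", {
  genes <- tibble::tibble(chrom = "c", tss = c(5000, 600000 + 5000),
                          strand = "+", gene = c("both", "far_ms"))
  elements <- tibble::tibble(
    element = c("ms1", "ets1", "ms2"),
    chrom = "c",
    start = c(5000 + 1000, 5000 - 2000, 0),
    end = c(5000 + 1040, 5000 - 1991, 40),
    strand = "+", type = c("ggaa_ms", "ets_motif", "ggaa_ms"),
    max_consecutive = c(10L, NA, 10L), total_repeats = c(10L, NA, 10L),
    fli_enrichment = NA_real_)
  endo <- make_de(genes$gene, log2fc = c(2, 2), padj = c(0.01, 0.01))
  cls <- assign_response_classes(genes, elements, endo, scan_params())
  expect_equal(cls$class[cls$gene == "both"], "ms_prom_act")
  # ms2 is 600 kb from far_ms: outside the 500 kb association radius
  expect_equal(cls$class[cls$gene == "far_ms"], "none")
  expect_warning(
    assign_response_classes(genes, elements, make_de("both", 2, 0.01),
                            scan_params()),
    "absent")
})

test_that("exactly-5kb microsatellites are enhancer-like (strict < 5 kb)", {
  genes <- tibble::tibble(chrom = "c", tss = 20000, strand = "+",
                          gene = "edge")
  elements <- tibble::tibble(
    element = "ms1", chrom = "c", start = 20000 + 5000,
    end = 20000 + 5040, strand = "+", type = "ggaa_ms",
    max_consecutive = 10L, total_repeats = 10L, fli_enrichment = NA_real_)
  endo <- make_de("edge", 2, 0.01)
  cls <- assign_response_classes(genes, elements, endo, scan_params())
  expect_equal(cls$class, "ms_enh_act")
})

test_that("feature comparison reports rank-sum tests per feature", {
  el <- function(mc, tr, fe = NA_real_) {
    tibble::tibble(max_consecutive = mc, total_repeats = tr,
                   fli_enrichment = fe)
  }
  a <- el(rep(20L, 20), rep(25L, 20), runif(20, 5, 10))
  same <- compare_element_features(a, a)
  expect_equal(same$p, rep(1, 3))
  expect_equal(same$median_A, same$median_B)

  b <- el(rep(5L, 20), rep(6L, 20), runif(20, 5, 10))
  diff <- compare_element_features(a, b)
  expect_lt(diff$p[diff$feature == "max_consecutive"], 0.01)

  # missing feature is skipped with a note
  expect_message(
    res <- compare_element_features(a[, 1:2], b),
    "skipped")
  expect_equal(nrow(res), 2)
  expect_error(compare_element_features(a[0, ], b), "non-empty")
})

test_that("the rank-sum test holds its nominal type-I level", {
  set.seed(205)
  rej <- 0
  nsim <- 1000
  for (i in seq_len(nsim)) {
    x <- rnorm(20); y <- rnorm(20)
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.07)
})
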