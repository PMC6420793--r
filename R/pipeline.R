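#' Assemble a pipeline configuration
#'
#' @param counts,samples,fasta,genes paths to the count TSV/MatrixMarket,
#'   sample sheet, genome FASTA and gene BED6 (TSS records).
#' @param elements optional BED of user-supplied loci of type `other_fli`
#'   (ChIP-derived); never computed from sequence.
#' @param out_dir output directory (created if needed).
#' @param constructs character vector of rescue construct condition names;
#'   default: every condition other than the control and endo labels.
#' @param analysis [analysis_params()].
#' @param scan [scan_params()].
#' @param seed integer recorded in the manifest (the analysis stages are
#'   deterministic; the seed governs upstream simulation only).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, fasta, genes,
                            elements = NULL, out_dir,
                            constructs = NULL,
                            analysis = analysis_params(),
                            scan = scan_params(), seed = 1L) {
  for (p in c(counts, samples, fasta, genes, elements)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  cfg <- list(counts = counts, samples = samples, fasta = fasta,
              genes = genes, elements = elements, out_dir = out_dir,
              constructs = constructs, analysis = analysis, scan = scan,
              seed = as.integer(seed))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full knockdown/rescue pipeline
#'
#' Executes preprocess (filter, size factors, batch adjustment),
#' differential expression (endogenous iLuc-vs-iEF profile plus one
#' profile per rescue construct, all against the iEF control),
#' response-element discovery and gene classification, rescue
#' classification / fidelity / strength / Venn overlap, and profile
#' summaries (variable genes, complete-linkage clustering, PCA), writing
#' deterministic TSV/JSON outputs and a manifest to `out_dir`. Re-running
#' with an identical config reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of in-memory results.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(inputs = config[c("counts", "samples", "fasta", "genes",
                                     "elements")],
                   parameters = list(analysis = unclass(config$analysis),
                                     scan = unclass(config$scan)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("rescuemap")),
                   stages = list())
  results <- list()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, out, complete = FALSE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "complete"),
                                  attr(res, "manifest_info"))
    res
  }
  info <- function(x, ...) { attr(x, "manifest_info") <- list(...); x }

  inputs <- stage("read_inputs", function() {
    counts <- read_counts(config$counts)
    samples <- read_samples(config$samples)
    if (!"iEF" %in% samples$condition)
      stop("control condition 'iEF' absent from the sample table")
    seqs <- read_fasta(config$fasta)
    genes <- read_genes_bed(config$genes)
    other <- NULL
    if (!is.null(config$elements)) {
      bed <- read_bed(config$elements)
      other <- tibble::tibble(element = bed$name, chrom = bed$chrom,
                              start = bed$start, end = bed$end,
                              strand = bed$strand, type = "other_fli",
                              max_consecutive = NA_integer_,
                              total_repeats = NA_integer_,
                              fli_enrichment = NA_real_)
    }
    info(list(counts = counts, samples = samples, seqs = seqs,
              genes = genes, other = other),
         n_genes = nrow(counts), n_samples = ncol(counts))
  })

  prep <- stage("preprocess", function() {
    pp <- preprocess_counts(inputs$counts, inputs$samples)
    write_counts(pp$pseudo_counts, file.path(out, "adjusted_counts.tsv"))
    write_tsv_file(tibble::tibble(sample = names(pp$size_factors),
                                  size_factor = pp$size_factors),
                   file.path(out, "size_factors.tsv"))
    write_counts_real(pp$log_adjusted, file.path(out, "log_adjusted.tsv"))
    info(pp, n_genes_kept = nrow(pp$counts))
  })

  constructs <- config$constructs
  if (is.null(constructs))
    constructs <- setdiff(unique(inputs$samples$condition),
                          c(config$analysis$control, config$analysis$endo))

  de <- stage("diff_expr", function() {
    sf <- estimate_size_factors(prep$pseudo_counts)
    disp <- estimate_dispersion(prep$pseudo_counts, sf,
                                inputs$samples$condition)
    conds <- c(endo = config$analysis$endo,
               setNames(constructs, constructs))
    tabs <- lapply(names(conds), function(nm) {
      tab <- differential_expression(prep$pseudo_counts, inputs$samples,
                                     test = conds[[nm]],
                                     ref = config$analysis$control,
                                     size_factors = sf,
                                     alphas = disp$alpha)
      write_tsv_file(tab, file.path(out, paste0("de_", nm, ".tsv")))
      tab
    })
    names(tabs) <- names(conds)
    info(tabs, contrasts = length(tabs))
  })

  elements <- stage("response_elements", function() {
    found <- dplyr::bind_rows(lapply(names(inputs$seqs), function(chrom) {
      dplyr::bind_rows(
        find_ggaa_microsatellites(inputs$seqs[[chrom]], config$scan, chrom),
        scan_ets_motif(inputs$seqs[[chrom]], config$scan, chrom))
    }))
    found$max_consecutive <- found$max_consecutive %||% NA_integer_
    found$total_repeats <- found$total_repeats %||% NA_integer_
    found$fli_enrichment <- NA_real_
    found$element <- sprintf("el%05d", seq_len(nrow(found)))
    all_el <- dplyr::bind_rows(found, inputs$other)
    write_tsv_file(all_el, file.path(out, "elements.tsv"))
    classes <- assign_response_classes(inputs$genes, all_el, de$endo,
                                       config$scan, config$analysis$alpha)
    write_tsv_file(classes, file.path(out, "gene_classes.tsv"))
    info(list(elements = all_el, classes = classes),
         n_elements = nrow(all_el))
  })

  rescue <- stage("rescue_analysis", function() {
    calls <- dplyr::bind_rows(lapply(constructs, function(cn) {
      cl <- classify_rescue_status(de$endo, de[[cn]], config$analysis)
      cl$construct <- cn
      write_tsv_file(cl, file.path(out, paste0("rescue_calls_", cn, ".tsv")))
      cl
    }))
    fidelity <- direction_fidelity(calls, elements$classes, config$analysis)
    write_tsv_file(fidelity, file.path(out, "fidelity.tsv"))
    strengths <- dplyr::bind_rows(lapply(constructs, function(cn) {
      st <- rescue_strength(calls[calls$construct == cn, ])
      st$construct <- cn
      st
    }))
    write_tsv_file(strengths, file.path(out, "strength.tsv"))
    strata <- strata_rescue_summary(calls, elements$classes, config$analysis)
    write_tsv_file(strata, file.path(out, "strata.tsv"))
    endo_sets <- twofold_gene_sets(de$endo, config$analysis)
    universe <- intersect(de$endo$gene[!is.na(de$endo$padj)],
                          unlist(lapply(de[constructs], function(t)
                            t$gene[!is.na(t$padj)])))
    venn <- dplyr::bind_rows(lapply(constructs, function(cn) {
      sets <- twofold_gene_sets(de[[cn]], config$analysis)
      dplyr::bind_rows(
        dplyr::mutate(venn_overlap_test(endo_sets$activated,
                                        sets$activated, universe),
                      construct = cn, direction = "activated"),
        dplyr::mutate(venn_overlap_test(endo_sets$repressed,
                                        sets$repressed, universe),
                      construct = cn, direction = "repressed"))
    }))
    jsonlite::write_json(venn, file.path(out, "venn.json"),
                         dataframe = "rows", na = "null", digits = NA,
                         pretty = TRUE)
    info(list(calls = calls, fidelity = fidelity, strengths = strengths,
              strata = strata, venn = venn), n_calls = nrow(calls))
  })

  profiles <- stage("profile_summaries", function() {
    expr <- prep$log_adjusted
    top <- top_variable_genes(expr, min(100, nrow(expr)))
    writeLines(top, file.path(out, "top_variable_genes.txt"))
    hc <- hierarchical_cluster(expr[top, , drop = FALSE])
    writeLines(hclust_to_newick(hc), file.path(out, "gene_clusters.nwk"))
    pca <- pca_scores(expr)
    write_tsv_file(tibble::tibble(sample = rownames(pca$scores),
                                  PC1 = pca$scores[, 1],
                                  PC2 = pca$scores[, 2]),
                   file.path(out, "pca_scores.tsv"))
    write_tsv_file(tibble::tibble(component = paste0("PC", seq_along(pca$var_frac)),
                                  var_frac = pca$var_frac),
                   file.path(out, "pca_variance.tsv"))
    info(list(top = top, hclust = hc, pca = pca), n_top = length(top))
  })

  write_manifest(manifest, out, complete = TRUE)
  invisible(list(preprocess = prep, de = de, elements = elements,
                 rescue = rescue, profiles = profiles))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_counts_real <- function(x, path) {
  df <- data.frame(gene = rownames(x),
                   apply(x, 2, formatC, digits = 10, format = "g"),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_manifest <- function(manifest, out, complete) {
  manifest$complete <- complete
  files <- setdiff(list.files(out), "manifest.json")
  manifest$outputs <- lapply(setNames(files, files), function(f)
    unname(tools::md5sum(file.path(out, f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)
}

# serialize an hclust merge tree as Newick with merge heights as branch
# lengths (leaf labels from hc$labels)
hclust_to_newick <- function(hc) {
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  node <- function(i, parent_h) {
    if (i < 0) return(paste0(lab[-i], ":", format(parent_h, digits = 8)))
    h <- hc$height[i]
    paste0("(", node(hc$merge[i, 1], h), ",", node(hc$merge[i, 2], h),
           "):", format(parent_h - h, digits = 8))
  }
  n <- nrow(hc$merge)
  paste0("(", node(hc$merge[n, 1], hc$height[n]), ",",
         node(hc$merge[n, 2], hc$height[n]), ");")
}
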