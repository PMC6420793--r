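# rescuemap

Structure–function mapping of fusion transcription factors by
knockdown/rescue RNA-seq.

In Ewing sarcoma, the EWS/FLI fusion oncoprotein drives a large
transcriptional program from GGAA-microsatellites and high-affinity ETS
sites. The standard way to ask *which part of the protein does what* is a
knockdown/rescue experiment: deplete endogenous EWS/FLI with shRNA (iEF),
keep a luciferase-shRNA control (iLuc), then re-express wildtype or mutant
constructs in the depleted cells. Each construct's transcriptional profile
is its differential expression against the depleted iEF control; the
endogenous signature is iLuc vs iEF. A gene is **rescued** by a construct
when it is significantly regulated (BH-adjusted p < 0.05) in both
profiles, **paradoxically regulated** when the directions disagree, and
the **rescue strength** is the Pearson r and OLS slope of construct
log2FC on endogenous log2FC over co-significant genes — slope < 1 means
attenuated rescue. Stratifying these calls by response-element class
(promoter-like GGAA-microsatellite < 5 kb from the TSS, enhancer-like
> 5 kb, ETS-direct via the ACMGGAARY consensus within 5 kb upstream /
1 kb downstream) yields the structure–function map.

The package implements the full pipeline:

1. **Preprocess** — low-count filter (mean < 1 count/sample),
   median-of-ratios size factors, parametric empirical-Bayes batch
   adjustment (location and scale), back-transformed to pseudo-counts.
2. **Differential expression** — negative-binomial Wald test per
   contrast (moment dispersion estimates moderated toward a
   mean-expression trend; size factors as offsets; per-contrast BH).
3. **Response elements** — GGAA-microsatellite scanner (merged runs,
   repeat features), IUPAC ETS-motif scanner on both strands, distance
   rules, and per-gene element classification.
4. **Rescue analysis** — four-way rescue status, directional fidelity,
   rescue strength, two-fold gene sets and chi-square Venn overlaps,
   element-stratified summaries.
5. **Profile summaries** — most-variable genes, complete-linkage
   clustering, PCA with fixed sign conventions.
6. **Synthetic data** — a negative-binomial generator with planted
   ground truth (endogenous signature, per-construct rescue fractions,
   attenuation, paradox fractions, planted genomic elements), used by all
   recovery tests.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (written to `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_response_elements.R
Rscript analysis/05_rescue_analysis.R
Rscript analysis/06_profile_summaries.R
```

`01` simulates 6,000 genes x 15 samples (iLuc, iEF and constructs WT,
DAF, DEAD in 3 replicate batches; 1,200 genes activated and 1,200
repressed by endogenous EWS/FLI) plus a synthetic genome carrying 40
promoter-like and 40 enhancer-like GGAA-microsatellites and 40 ETS
motifs. `03` then prints the headline DE table:

```
iLuc  vs iEF:  2538 genes at padj < 0.05 (1263 up, 1275 down)
WT    vs iEF:  1916 genes at padj < 0.05 (959 up, 957 down)
DAF   vs iEF:   946 genes at padj < 0.05 (481 up, 465 down)
DEAD  vs iEF:    30 genes at padj < 0.05 (17 up, 13 down)
```

— the graded activity WT > DAF > DEAD expected of a full, partial and
dead rescue. `04` recovers the planted elements and classes
(23 + 17 promoter-ms, 23 + 16 enhancer-ms, 40 ETS-direct among
endo-detected genes), and `06` reproduces the familiar PCA geometry:
rescued WT samples sit between iLuc and iEF (centroid distances 64.7 and
69.0), while the dead construct lands on top of the knockdown control
(distance 0.5 to iEF):

```
PC1 65.3% / PC2 13.0% of variance
WT   centroid: distance to iLuc   64.7, to iEF   69.0
DAF  centroid: distance to iLuc   93.8, to iEF    8.2
DEAD centroid: distance to iLuc   98.5, to iEF    0.5
```

In-memory, the same analysis is a few calls:

```r
library(rescuemap)
cfg  <- sim_config(seed = 1)
sim  <- simulate_experiment(cfg)
pp   <- preprocess_counts(sim$counts, sim$samples)
endo <- differential_expression(pp$pseudo_counts, sim$samples, "iLuc")
wt   <- differential_expression(pp$pseudo_counts, sim$samples, "WT")
calls <- classify_rescue_status(endo, wt)
rescue_strength(calls)
#>       n pearson_r   r_pvalue  slope intercept
#>    1773     0.978  ~0         0.785   ...
```

`run_pipeline()` executes every stage from on-disk inputs (counts TSV,
sample sheet, FASTA, gene BED) and writes deterministic TSV/JSON outputs
plus a manifest; reruns are byte-identical.

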