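---
title: "Knockdown/rescue structure-function mapping: models and methods"
author: "rescuemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockdown/rescue structure-function mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescuemap)
```

# The experimental design this package analyzes

EWS/FLI is the fusion transcription factor that drives Ewing sarcoma: the
low-complexity EWS domain fused to the FLI ETS DNA-binding domain. A
standard way to map which parts of the protein do what is the
knockdown/rescue design: endogenous EWS/FLI is depleted by shRNA (the
**iEF** condition), a control knockdown targets luciferase (**iLuc**), and
depleted cells are "rescued" with wildtype or mutant constructs. Every
construct's transcriptional profile is the differential expression of its
samples against the depleted **iEF control**; the endogenous signature
(the *endo* profile) is the iLuc vs iEF contrast. A construct rescues a
gene when the gene is significantly regulated in both the endo profile and
the construct's profile; it acts *paradoxically* when the two directions
disagree.

EWS/FLI binds two kinds of response elements: GGAA-microsatellites
(tandem GGAA repeats; "promoter-like" when < 5 kb from a TSS,
"enhancer-like" beyond) and high-affinity ETS consensus sites
(IUPAC `ACMGGAARY`). Stratifying rescue behavior by element class is the
structure-function readout: a construct may work at promoter-proximal
repeats but fail at distal enhancers.

# The generative model behind the synthetic study

Deposited RNA-seq from such studies is not redistributable at desk scale,
so the package ships a generator whose output has the statistical
structure the analysis assumes, plus the ground truth needed for
parameter-recovery testing.

Counts are negative binomial with mean-dispersion parameterization
(`Var = mu + alpha * mu^2`), matching the model fitted downstream:

$$\mu_{gj} = 2^{\,b_g + x_{g,c(j)} + \beta_{g,b(j)}}\; L_j, \qquad
  y_{gj} \sim \mathrm{NB}(\mu_{gj},\; \alpha_g \delta_{b(j)})$$

* `b_g`: log2 baseline, Normal(6, 2) — a typical bulk RNA-seq expression
  spread where the median gene has ~64 counts.
* `alpha_g`: log-normal(log 0.02, 0.5) — cell-line-grade dispersions.
* `x_gc`: condition effect. iEF carries none (it is the reference state);
  iLuc carries the endogenous log2 effect; each rescue construct carries
  its construct effect.
* `beta_gb`: additive per-batch per-gene log2 shift, Normal(0, 0.3) — the
  batch structure that motivates empirical-Bayes adjustment; `delta_b` is
  a per-batch dispersion multiplier, Gamma(20, 20), so batches also differ
  in scale.
* `L_j`: library-size factor, log-normal(0, 0.2), so size-factor
  estimation is non-trivial.

Endogenous effects are planted deterministically: exactly
`round(frac * n_genes)` genes are activated (default 20%) or repressed
(20%), with magnitudes |Normal(2, 0.5)| log2 units — strong, as expected
of a master regulator's signature. Per construct, exactly
`round(rescue_frac * n_regulated)` endo-regulated genes are rescued with
`construct_lfc = s * endo_lfc` (attenuation `s`), and a `paradox_frac` of
the rescued genes get the sign flipped with the same attenuation — the
simplest model that produces the observed discordance. The default
constructs emulate the study conditions: a near-full rescue (WT: 0.75
rescued, s = 0.8, 5% paradox), a partial rescue with substantial
paradoxical activity (DAF: 0.40, s = 0.5, 30% paradox), and a
functionally dead construct (DEAD: 0.02, s = 0.1, 10% paradox). Three
replicate batches each contribute one sample per condition; replicate
counts per condition in the original experiments are not stated
publicly, so three is a choice, not a claim.

## The synthetic genome

`simulate_annotation()` writes one chromosome per element class
(promoter-microsatellite, enhancer-microsatellite, ETS, background). This
is a deliberate identifiability choice: gene classification associates
each endo-significant gene with its *nearest* microsatellite within a
500 kb radius, so on a single dense chromosome nearly every gene would
have *some* microsatellite within radius and the microsatellite classes
would swallow the ETS and background classes. Separating classes by
chromosome makes the planted class the recoverable truth while exercising
exactly the same assignment code paths as real data.

Planted elements are literal sequence: `GGAA` repeated `r` times
(uniform 5-25 units) at a uniform distance from the gene's TSS (500-4,500
bp for promoter-like, 6,000-25,000 bp for enhancer-like), and concrete
`ACMGGAARY` instances in the strand-aware upstream window. Background
sequence is then *scrubbed*: any scanner call that is not a planted
element has its non-planted bases rewritten (iterating until the scan is
clean), so the round-trip invariant — scanning the emitted FASTA recovers
the planted elements exactly — holds with no tolerance. What this genome
does **not** emulate: GC structure, repeat families other than GGAA/TTCC,
gene density variation, and microsatellites near non-regulated genes;
passing recovery tests therefore demonstrates correctness of the
machinery, not robustness to every genomic confounder.

# Preprocessing

* **Low-count filter** — genes averaging under 1 count per sample are
  removed. "Per sample" is read as a rate (total < n_samples), not as
  "every sample ≥ 1", which would discard most genes in sparse designs.
* **Size factors** — median-of-ratios over genes with nonzero counts in
  all samples, rescaled to geometric mean 1.
* **Batch adjustment** — parametric empirical-Bayes location/scale
  adjustment of `log2(normalized + 1)` values: per-gene standardization
  against batch means plus condition covariates, a Normal prior on batch
  locations and an inverse-gamma prior on batch scales (both estimated
  from the data by moments), posterior means by fixed-point iteration
  (tolerance 1e-6, max 100 iterations). The test suite verifies the
  implementation against `sva::ComBat` to 1e-6. Whether the original
  analysis adjusted raw counts, log counts or variance-stabilized values
  is unstated; this package adjusts log2 normalized counts and
  back-transforms to integer pseudo-counts (`round(max(2^x - 1, 0))`)
  because the downstream DE stage is a count model. The un-rounded
  adjusted matrix is kept for clustering and PCA.

A batch perfectly confounded with a condition is refused by name; with a
single batch the adjustment is the identity.

# Differential expression

The DE stage is a self-contained negative-binomial Wald test:

* **Dispersion** — method-of-moments on normalized counts with
  within-condition pooling, moderated by shrinking 30% of the way (log
  scale) toward the trimmed-mean dispersion of genes in the same
  baseline-expression bin (20 bins, 10% trim). Non-positive moment
  estimates are floored at 1e-8 (sub-Poisson genes genuinely belong
  there; the constant-counts case is the canonical example).
* **Wald test** — per gene, an NB GLM with log link, size factors as
  offsets, and a single test-vs-reference indicator, fitted by IRLS
  (vectorized across genes; deviance tolerance 1e-8, max 50 iterations;
  fitted means floored at 0.5 so completely separated genes keep a finite
  standard error). log2FC is the coefficient over ln 2, oriented test
  over iEF; p is the two-sided normal tail.
* **BH** — per-contrast Benjamini-Hochberg step-up; NA p-values are kept
  out of the test count.

Numerical calibration has a known limit that users should understand:
with per-gene *estimated* dispersions, the extreme p-tail (p ~ 1e-5 and
below, the region that decides BH rejections among thousands of null
genes) is slightly anticonservative for any estimator in this family —
we verified that DESeq2 on identical all-null matrices also produces
occasional BH discoveries. The package's calibration study therefore
reports the fraction of null genes falsely discovered (which is
controlled far below 5%) and the KS distance of the raw p-distribution
from uniform (< 0.03 at 10 samples/group), and the calibration design
uses 10 samples per group, where the moment estimator is stable; at 3
samples per group individual near-zero dispersion estimates make single-
gene tail p-values unreliable, which is a property of the estimator, not
a bug in the implementation.

# Response elements

`find_ggaa_microsatellites()` calls maximal runs of consecutive GGAA
units, merges runs separated by at most 4 non-motif bases, and drops
calls with fewer than 4 total units; `TTCC` runs are the minus-strand
equivalent. The source study inherits its microsatellite loci from cited
localization data whose exact definition is not restated, so
`min_repeats = 4` and `max_gap = 4` are documented stand-ins, exposed in
`scan_params()`. Distances are unsigned, element edge to TSS, with ties
at exactly 5,000 bp resolved to enhancer-like (strict "< 5 kb").
Coordinates are 0-based half-open internally and in BED output.

Gene classification precedence is microsatellite > ETS motif > other
FLI-bound locus; "other FLI" intervals are consumed from a user-supplied
BED (ChIP-derived) and never computed from sequence. Feature comparisons
between element groups (max consecutive units, total units, FLI binding
enrichment) use the Mann-Whitney rank-sum test with normal approximation
and tie correction; when every observation is tied the p-value is defined
as 1 (no evidence of difference).

# Rescue classification and strength

Per construct, genes are crossed by significance (BH-adjusted p < 0.05,
strict, no fold-change cutoff) in the endo and construct profiles:
`both_significant`, `kd_only`, `rescue_only`, `neither` — the red, gray,
yellow and black of the rescue scatterplots. Directional fidelity is
computed over endo-regulated genes only (red + gray; `rescue_only` genes
are excluded, matching the restriction to the knockdown-defined
signature), as fractions concordant-significant, paradoxical, and
unchanged, which sum to 1 per construct and class.

Rescue strength is the Pearson correlation (two-sided t-based p) and the
OLS slope, with intercept, of construct log2FC on endo log2FC over
`both_significant` genes; the intercept is reported but not interpreted.
With fewer than 3 such genes, or a degenerate spread, the result is an
explicit NA sentinel carrying n. One caveat discovered during validation
and worth knowing: both contrasts share the iEF control samples, so their
fold-change errors are positively correlated; for a construct with almost
no true activity the co-significant set is small and false-positive
dominated, and this coupling can inflate the apparent slope in individual
simulations. Cross-replicate medians are the stable summary for slopes of
near-dead constructs.

Two-fold gene sets use strict cutoffs (|FC| > 2 and padj < 0.05); the
overlap test is the Pearson chi-square without continuity correction on
the 2x2 membership table. The universe is an explicit argument — the
package defaults to genes surviving the count filter and testable in both
contrasts — because overlap significance depends on it and the original
choice is unstated.

# Profile summaries

The most-variable-gene ranking uses across-sample variance with
lexicographic tie-breaks. Hierarchical clustering is complete-linkage on
Euclidean distances of row-standardized (z-scored) values — conventional
expression-heatmap practice; correlation distance is available. PCA
centers genes, takes sample scores from the top right-singular
directions, and fixes signs so each component's largest-magnitude loading
is positive, making outputs reproducible across platforms.

# Problem sizes and test design

The recovery studies in the test-suite and the acceptance script run at
6,000 genes, 5 conditions, 3 batches (10 replicate simulations for
fraction/slope recovery, 3 for paradox recovery), the null-calibration
study at 5,000 genes x 20 samples x 20 simulations (5 in the acceptance
script), and the oracle-equivalence checks at 1,000 random 2-kb
sequences and 1,000 random p-vectors. Rescued proportions are averaged
across replicate simulations; slopes use the cross-replicate median (see
the shared-control caveat above). These sizes give stable estimates of
every recovered quantity while keeping a full run in minutes on one CPU.

# Known limitations

* The DE stage recreates the *kind* of analysis the cited tools perform
  (median-of-ratios, NB Wald, BH) but not their exact numerical output;
  gene-list-level equality with any specific DESeq2 version is not a
  goal.
* The non-parametric batch-adjustment variant is not implemented.
* Far-tail p-values at 2-3 replicates per condition are unreliable for
  individual genes (see above); aggregate quantities (rescue fractions,
  slopes over hundreds of genes) are the intended readout.
* The synthetic genome's one-chromosome-per-class layout makes class
  recovery exact but does not test behavior under overlapping element
  neighborhoods; `assign_response_classes()` precedence rules are
  separately unit-tested on hand-built geometries for those cases.
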