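---
title: "Nominating direct transcription-factor targets from three evidence layers"
author: "DirectTargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating direct transcription-factor targets from three evidence layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DirectTargets)
```

## Scope and model

`DirectTargets` nominates genes directly sustained by an amplified
transcription factor by requiring three independent observations to
coincide on the same gene: a transcriptional response to knocking the
factor down, a nearby binding site for the factor, and overexpression in
primary tumors that carry extra copies of the factor's locus. Each layer
is a self-contained module; `integrate_candidates()` takes their exact
intersection. The package starts from quantified data — RPKM-like
expression tables, called peak lists, a gene model, a cohort expression
matrix with per-sample copy-number ratios at one index locus. Alignment,
quantification and peak calling are upstream of its scope.

### Knockdown response

For one cell line, the response of gene $g$ is the ratio
$r_g = x_g^{kd} / x_g^{ctrl}$ of its abundance under factor-targeting
siRNA to its abundance under non-targeting control. Two conventions
matter and both are applied inclusively:

* **Measurability.** Ratios are only trusted for genes with abundance
  $\ge$ `min_abundance` (default 1 RPKM) in *both* conditions; below
  that, sampling noise dominates and the gene is called `not_measured`.
  A gene absent from a line's table is likewise `not_measured` in that
  line, never silently `unchanged`.
* **Substantial change.** A change of "at least 25%" is read literally:
  $r \le 0.75$ is `down`, $r \ge 1.25$ is `up`, the boundary values
  included.

Cross-line structure is summarized two ways: `consistent_genes()` (genes
carrying the same call in at least *k* of the supplied lines, with the
full membership matrix) and `cross_line_correlation()`, which correlates
per-line $\log_2 r$ profiles over the union of each line's top-*n* down-
and up-regulated genes. Ratios are formed on the raw abundance scale;
correlations use $\log_2 r$ so that down- and up-regulation contribute
symmetrically (the standard heatmap scale). P-values come from the
ordinary Pearson test and are Bonferroni-adjusted over the number of line
pairs — the most conservative standard choice, configurable through
`adjust`. A pair sharing fewer than 3 measured genes is reported `NA`
rather than failing.

### Binding (cistrome)

Peaks are BED intervals (0-based, half-open; GTF gene models are shifted
to this convention on load). `annotate_peaks()` assigns each peak to the
gene with the nearest transcription start site on the same chromosome
within `window` bp (default 100,000 — the conventional distance within
which promoter and enhancer binding is credited to a gene). Distances are
signed and strand-oriented: positive means downstream of the TSS in the
gene's reading direction. Two genuinely open conventions are settled as
explicit defaults rather than guesses:

* the peak's reference point is its **midpoint** (`reference = "summit"`
  uses a summit column when present);
* proximity is measured to the **TSS**, not the gene body
  (`distance_to = "body"` is available), because the distance histogram
  this module feeds is TSS-anchored.

`extract_peak_windows()` takes the `top` strongest gene-associated peaks
(default 500) and returns `width`-bp windows (default 100) centered on the
reference point, clipped at contig ends — the classic input for motif
analysis of a cistrome. `scan_motif()` matches a degenerate IUPAC
consensus (default `CACTY`, the Nkx2 homeodomain core; the extended
`CHCTY` form is equally valid input) on both strands, reporting
minus-strand hits at plus-strand offsets; `motif_enrichment()` compares
the observed hit total against per-sequence mononucleotide shuffles,
which hold each window's length and base composition fixed. With $B$
shuffles the add-one empirical p-value cannot fall below $1/(B+1)$, so
`n_shuffles` bounds the attainable resolution. De novo motif discovery is
deliberately out of scope: the consensus is known, and the question the
module answers is whether it is present and enriched.

### Tumor cohort (two-class SAM)

Samples are stratified by the copy-number tumor/normal ratio at the index
locus — amplified strictly above 1.5, non-amplified strictly below 1.1,
the zone between excluded as indeterminate — and both groups are gated to
the top quartile of index-gene expression (type-7 linear-interpolation
quantile, inclusive at the cut; the convention is stated because "top 25
percentile" is convention-sensitive). Group sizes are whatever the data
yield; the test refuses to run below 2 samples per group.

`sam_two_class()` implements the significance-analysis-of-microarrays
statistic in its original form:

$$ d_i = \frac{\bar{x}_{A,i} - \bar{x}_{B,i}}{s_i + s_0}, \qquad
   s_i = \sqrt{\left(\tfrac{1}{n_A}+\tfrac{1}{n_B}\right)
   \frac{\sum_A (x-\bar x_A)^2 + \sum_B (x-\bar x_B)^2}{n_A+n_B-2}} $$

* $s_0$ is chosen from the percentiles $\{0, 0.05, \dots, 1\}$ of the
  $s_i$ distribution to minimize the coefficient of variation of
  $\mathrm{mad}(d)$ across quantile windows of $s$ — the standard
  fudge-factor rule that stops low-variance genes from dominating.
  `s0 = 0` recovers the unmoderated statistic; the selection is scale
  equivariant, so $d$ is invariant to rescaling the data.
* The null is built from `n_perm` (default 200) seeded whole-label
  permutations. Sorted observed statistics $d_{(i)}$ are compared with
  the permutation-mean order statistics $\bar d_{(i)}$; for a threshold
  $\Delta$, the smallest positive $d_{(i)}$ with
  $d_{(i)} - \bar d_{(i)} > \Delta$ and the largest negative one with
  $\bar d_{(i)} - d_{(i)} > \Delta$ define cut points in $d$, and every
  gene beyond a cut point is called. Working with cut points (rather than
  per-gene exceedance alone) keeps the called sets nested in $\Delta$,
  which makes the per-gene $q$ — the minimum estimated FDR over all
  $\Delta$ at which the gene is called — well defined as a prefix
  minimum over the $\Delta$ grid.
* The FDR at $\Delta$ is $\hat\pi_0 \cdot \mathrm{median}_b
  \#\{\text{permuted } d \text{ beyond the cuts}\} / \max(1, \#called)$,
  with $\hat\pi_0$ estimated from the fraction of observed $d$ inside the
  central 50% of the pooled permuted statistics, clipped at 1.

Expression declared linear is $\log_2(x+1)$-transformed on construction
of the `cohort_study`, since the statistic assumes a roughly additive
scale. Two FDR bounds are deliberately both surfaced: 0.10 (the default,
matching candidate-table use) and 0.05 (the stricter conventional
choice); the package resolves the tension by making the bound a
parameter rather than picking silently.

### Gene-set enrichment

`gsea_two_class()` is the weighted Kolmogorov–Smirnov form: genes are
ranked by signal-to-noise $(\mu_A-\mu_B)/(\sigma_A+\sigma_B)$ with each
$\sigma$ floored at $\max(0.2\,|\mu|, 10^{-8})$ (the reference
implementation's guard against near-constant genes), and the enrichment
score is the signed maximum deviation of a running sum that adds
$|metric|^p$ (normalized over set members, $p$ = 1 by default) at hits
and subtracts $1/(N-N_{hit})$ at misses; $p = 0$ reduces to the classic
KS statistic, a property the tests exploit. Significance uses phenotype
permutation when both classes have at least 7 samples; below that the
permutation space is too coarse and the module falls back to gene
permutation with a warning (`perm_type` overrides). NES divides ES by the
mean same-sign permuted ES; the FDR estimator compares the pooled
permuted-NES tail with the observed-NES tail at each score, clipped to
[0, 1]. Set-size filters (default 15–500 members present in the data)
apply to measured genes, not nominal set sizes. How several cell lines
are combined into two classes is left to the caller — the module is
deliberately generic two-class.

### Integration

`integrate_candidates()` forms, per cell line, the set
{called `down`} ∩ {has an annotated peak} ∩ {cohort $d>0$, $q \le$
threshold} and carries all three evidence values through unchanged;
rendering (e.g. FDR as a percentage) is presentation-layer only.
"Upregulated by the factor" is operationalized as *down upon knockdown*.
The default requires the response and the peak in the *same* line,
matching a per-line candidate table; `mode = "cross_line"` accepts peak
evidence from any line. Removing any evidence layer, or relaxing any
threshold, can only grow the candidate set — a monotonicity the tests
assert. `hypergeometric_overlap()` provides the exact one-sided tail for
set-overlap questions; `overlap_summary()` reports the
regulated-vs-peak-associated intersection in both directions.

## The synthetic-data generator

`simulate_bundle()` writes a complete, seeded input bundle with planted
ground truth. What it emulates, and what it does not, bounds what passing
tests prove.

Emulated:

* multiplicative log-normal noise on RPKM-like abundances
  (`expression_noise_sigma`, default 0.15 on the natural-log scale, i.e.
  roughly ±15% per condition — typical technical spread for well-expressed
  genes);
* planted direct targets (default 50 of 2,000) with per-line knockdown
  ratios drawn from 0.2–0.7 and indirect targets (default 100) from
  0.4–0.9, the latter deliberately straddling the 0.75 call boundary so
  classification is exercised near its threshold;
* a fraction of null genes (default 5%) forced below the RPKM filter in
  one condition to exercise the `not_measured` path; planted responsive
  genes are given baselines of at least 8 RPKM, because the regime being
  emulated concerns adequately expressed targets whose knockdown response
  is observable above the filter;
* a small genome (3 contigs × 4 Mb) on which 100-kb windows are
  meaningful, with true peaks placed 0.2–2 kb from their target's TSS
  (promoter-proximal, so nearest-TSS assignment is unambiguous at the
  simulated gene density) among uniformly placed decoys; true peaks score
  higher than decoys on average (50–100 vs 0–90), with overlap, as in
  ranked peak calls;
* consensus-motif instances inserted into true-peak windows at rate 0.8;
* a cohort (30 amplified / 60 non-amplified / 30 indeterminate samples)
  with log2 expression noise of 0.8 per gene, a 1.5-log2 shift at planted
  direct targets in amplified samples, and a 1.0-log2 shift of the index
  gene itself (so the top-quartile gate enriches for, but is not
  identical to, the amplified group);
* one planted gene set among decoys in the GMT.

Not emulated: read-level data, fragment-level ChIP coverage, gene-length
and GC biases, correlated gene–gene noise, subclonal copy-number
structure, or the marginal distributions of any real tumor cohort.
Passing the end-to-end recovery tests therefore demonstrates that the
pipeline's logic and statistics behave as designed under the stated noise
model — not that real data of any particular study would yield any
particular gene list.

All draws descend from the single `seed` in a fixed order (gene roles,
planted ratios, per-line expression noise, genome, per-line peaks and
motif insertions, cohort, gene sets), so identical seeds give
byte-identical files.

## Numerical and degenerate-input choices

* Tie-breaks are everywhere deterministic — ascending lexicographic gene
  identifier (rankings, annotation ties, top-gene cuts), chromosome then
  start for equal peak scores — so outputs are byte-reproducible.
* Inclusive comparisons at every stated boundary: RPKM filter, 25%
  thresholds, expression-gate percentile, FDR bounds.
* `compute_response()` with a zero filter floor treats a zero control
  abundance as `not_measured` (a ratio would be undefined).
* A constant gene row is allowed in SAM: $d = 0$ when the group means
  agree; an all-constant matrix with `s0 = 0` is an error.
* `enrichment_score()` falls back to equal hit increments when every
  in-set metric is exactly zero; a set covering all ranked genes is an
  error (the miss denominator would vanish).
* Empirical p-values use add-one smoothing throughout, so they are never
  exactly zero.
* Peak windows are clipped at contig ends rather than padded.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` size their simulations for
seconds-scale runs while keeping the statistics honest: oracle
comparisons on ≤ 50-element inputs; SAM calibration on 20 replicates of
200 genes × (30 vs 60) samples with 100–200 permutations; GSEA planted
recovery on 300 genes × 12 samples against 10 decoy sets; end-to-end
recovery on the full default bundle (2,000 genes, 3 lines, 50 planted
direct targets). These sizes are the package's own choices for its
reference checks; all of them scale up by changing the corresponding
arguments.

## Known limitations

* Nearest-TSS annotation assigns at most one gene per peak; peaks in
  dense loci between two close TSSs are credited to one gene only.
* The SAM FDR is an estimate whose resolution is limited by `n_perm`;
  with small groups the permutation space itself may be the binding
  constraint.
* GSEA's gene-permutation fallback tests a weaker null than phenotype
  permutation and is flagged accordingly.
* The integration is a hard triple intersection: a gene missing any one
  evidence layer (e.g. measured in only some lines) cannot be nominated,
  which is faithful to the design but unforgiving of missingness.
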