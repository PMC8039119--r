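---
title: "Models and methods behind the microglia pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the microglia pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
rules each stage implements, the defaults and why, what the synthetic data
do and do not emulate, and the numerical choices a maintainer would
otherwise have to reverse-engineer from the code.

## The problem

Microglia — the brain's resident immune cells — are not one homogeneous
population. Along the nigrostriatal pathway (the dopaminergic projection
that degenerates in Parkinson's disease), midbrain microglia sit in a more
immune-alerted state than their striatal neighbors. Detecting that kind of
regional sub-structure from droplet single-cell RNA-seq requires a chain
of decisions — which barcodes are cells, which cells are usable, how to
normalize, cluster and annotate, how to test expression differences
without confounding by sequencing depth — and a second, independent line
of evidence from cell morphology, since activated microglia retract and
simplify their processes. This package implements that chain as separate,
contract-tested functions.

## Cell and gene quality control

**Barcode selection.** Barcodes are ranked by total counts; on the
cumulative count curve over log10 rank (both axes rescaled to the unit
square) the knee is the rank with the maximal *signed* perpendicular
distance above the chord joining the endpoints. The signed form matters:
the ambient-barcode plateau lies below the chord, and taking absolute
distances can select a spurious early rank. When all totals are equal
there is no knee; everything is returned with a warning.

**The 2-of-3 MAD rule.** Three per-cell criteria, evaluated separately
within each region dataset (so a deeply sequenced region does not flag an
entire shallow one):

* genes: expressed genes `< 200` **or** `> median + 2 MAD` — the absolute
  floor catches near-empty droplets, the upper tail catches
  multiplet-like cells. The underlying phrasing of this rule is
  grammatically ambiguous ("higher than 200 with 2 MADs above the
  median"); this directionality is our resolution of it, and both the
  floor and the multiplier are parameters of `qc_params()`.
* depth: `|total counts − median| > 2 MAD` (two-sided);
* mitochondrial: `% mito counts > median + 1.5 MAD` (upper-sided; a cell
  with zero total counts has `pct_mito` defined as 0 and is caught by the
  depth/genes criteria instead).

MAD is the unscaled median absolute deviation from the median; the 1.4826
normal-consistency factor is **not** applied by default but is exposed as
`mad_constant`. A cell failing at least `min_fail = 2` criteria is
removed. Note the statistical consequence: on any noisy cohort a fixed
MAD multiplier flags a scale-invariant fraction of healthy cells per
criterion (for roughly Gaussian metrics, ~18% beyond 2 MADs two-sided);
only the *joint* 2-of-3 requirement keeps healthy-cell losses low, and
only a literally homogeneous cohort has zero losses. Datasets with fewer
than 3 cells skip filtering with a warning.

**Gene filter.** Genes kept iff expressed (count > 0) in ≥ 5 cells and
the symbol does not match the mitochondrial (`mt-`) or ribosomal
(`Rps`/`Rpl`) prefixes, case-insensitively. The filter is idempotent.

**Integration.** Matrices filtered per region are concatenated over the
intersection of their gene universes (lexicographic gene order, duplicate
barcodes suffixed by region). No anchor-based batch correction is
performed: the synthetic data carry no batch effect, and cell-level QC is
complete before integration, so concatenation is sufficient for every
quantity this package computes.

## Normalization, variable genes, embedding

Normalized expression is `log1p(count / total × 10,000)`; consequently
`sum(expm1(value))` is exactly the scale factor in every cell, which the
tests assert to 1e-6 relative error. Within-cell rank order of counts is
preserved.

Variable genes are ranked by standardized variance: a degree-2 polynomial
of log10 variance on log10 mean is fitted across genes with positive
variance of the raw counts, each gene's counts are standardized by the
trend-predicted standard deviation, clipped at `sqrt(n_cells)`, and the
variance of the clipped values is the statistic. Ties break by gene
order. If the trend is degenerate (fewer than three distinct means, or a
rank-deficient fit) the expected variance is taken as flat, which reduces
the ranking to a plain variance sort.

PCA: the selected genes' normalized values are per-gene centered and
scaled to unit variance (zero-variance genes contribute zeros), scaled
values are clipped at ±10 (a guard against single extreme cells dominating
a component), and the embedding is the exact SVD. Component signs are
canonicalized so each component's largest-magnitude loading is positive,
making the embedding reproducible to the bit for identical input. The
default of 20 components is a convention, not an estimate; it is a
parameter.

## Clustering and resolution selection

The cell graph is a shared-nearest-neighbor graph: each cell's neighbor
set is itself plus its k = 20 Euclidean nearest neighbors in PC space;
cells are connected if either contains the other, weighted by the Jaccard
overlap of their neighbor sets; zero-weight edges are dropped. Louvain
modularity maximization (with resolution parameter) runs on this graph at
every grid point (default 0.1–1.5 in steps of 0.1) under a fixed seed.

Each partition is scored by the mean silhouette over cells in PC space
(Euclidean); cells in singleton clusters score 0, and single-cluster
partitions take a −1 sentinel so they can never win unless nothing else
exists (that case returns with a warning). The chosen resolution is the
argmax, ties broken toward the smaller resolution. Above 5,000 cells the
silhouette uses a fixed-seed subsample of that size; the default test and
analysis scales never trigger it. The silhouette implementation is
vectorized but is held, in the tests, to within 1e-10 of a literal
quadratic-time oracle and of `cluster::silhouette`.

## Annotation and purification

For every marker gene of the bundled panel, cluster means of normalized
expression are z-scored across clusters; a cluster's score for a type is
the mean z-score over that type's present markers (absent markers are
logged and skipped). Assignment is argmax, flagged ambiguous when the top
two scores differ by less than 0.1. Scoring is invariant to cluster
relabeling and cell order.

Purification of a target population removes cells detecting at least 2 of
the contaminant trio *Mbp*/*Mag*/*Plp1* (raw count > 0). The 2-marker
requirement exists because a single ambient transcript is common in
droplet data; it is configurable. The purified subset is then re-embedded
and re-clustered by the same machinery — an orchestration (script 04), not
a new algorithm.

## Differential expression

**Hurdle test** (one-vs-rest marker screen): per gene, a logistic
regression of detection (count > 0) on group + log(total transcripts),
and a Gaussian linear model of normalized expression among detected cells
on the same design. Each part contributes a likelihood-ratio statistic
against its covariate-only reduction; the p-value is the chi-square tail
of the sum at the summed degrees of freedom. Two calibration details:

* the continuous part's contribution is the chi-square deviate of the
  exact F test rather than `n·log(RSS0/RSS1)` — the latter is
  anticonservative for genes detected in fewer than ~20 cells (measured
  rejection 0.13 at the 0.05 level in that stratum under a null), the
  F-calibrated version is level across strata;
* genes detected in fewer than 3 cells report p = 1 with a
  `low_detection` flag, and complete separation in the logistic part
  falls back to Fisher's exact test on the detection table, flagged.

Log fold change is the natural-log difference of group means of
normalized values; pct_1/pct_2 are percent-expressing. The marker screen
runs every cluster against the rest with *no* fold-change or detection
pre-filtering and Bonferroni correction within each comparison.

**NB GLM** (sub-state comparison): per gene, a log-link negative-binomial
GLM of raw counts on the subset factor + log(total transcripts), tested
against the covariate-only model by likelihood ratio. The NB size is a
method-of-moments estimate on the residuals of a full-model Poisson fit
— moments taken on the marginal counts would mistake covariate- and
group-driven variance for overdispersion and lose level (measured null
rejection 0.044 vs 0.049 at nominal 0.05). Dispersion is floored at 1e-8
(near-Poisson for underdispersed genes); failed fits fall back to a
flagged Poisson GLM. BH q-values are computed across genes.

`adjust_pvalues()` implements both corrections directly (Bonferroni
`min(1, m·p)`; BH step-up with enforced monotonicity) and is held to
`stats::p.adjust` within 1e-12 on random vectors.

## Signature comparison and qPCR

Signature overlap is a case-sensitive symbol intersection (an optional
case-folding flag exists because public gene lists mix cases), reported as
counts and as a percentage of the first signature. Direction concordance
is the fraction of shared genes whose sign of change (+1/−1) agrees,
relative to the shared count. Relative qPCR expression is `2^−ΔCT` with
ΔCT the threshold-cycle difference between target and reference gene.

## Morphometrics

A skeleton is a rooted tree of 3D nodes in micrometres (SWC format; parent
−1 marks the soma). Total process length sums Euclidean parent–child edge
lengths. A branch point is a non-root node with ≥ 2 children — the root
counts only with ≥ 3, because a bipolar soma is not a bifurcation of a
process. Segments are maximal unbranched paths between critical points
(root, branch points, tips); equivalently, one segment per non-root
critical node. The proprietary tracing software the field uses does not
publish its exact segment definition; this contract is normative for the
package. A single-node skeleton counts as one zero-length segment.
Trifurcations count as one branch point.

Group statistics mirror the field's split: ANOVA + Tukey HSD for the
continuous metrics (density, process length), Kruskal–Wallis + Dunn for
the count-valued ones (branch points, segments). Dunn's pairwise z uses
the standard tie correction and Bonferroni adjustment over all pairs (no
adjustment is prescribed by convention, so the most conservative standard
one is used). If every observation is identical the omnibus p is reported
as 1 with a `zero_variance` flag rather than NaN.

## What the synthetic data emulate — and what they don't

`simulate_dataset()` draws gene counts as negative binomial
(gamma–Poisson), the standard droplet noise model, with mean
`profile × depth` (depth lognormal per cell) and a shared inverse-
dispersion (default size 2, i.e. strongly overdispersed). The study-like
default `brain_sim_spec()` plants: four brain cell types, each with its
marker genes plus a ~50-gene dedicated program at 6-fold enrichment over a
shared baseline (`Exp(rate = 2)` means, ~0.5 counts/gene at unit depth);
two microglia sub-states (30% immune-alerted, a 10-gene inflammatory
program at 4-fold with homeostatic markers expressed by all microglia);
`mt-`-prefixed genes at ~5% of counts; and three artifact classes — empty
droplets (multinomial ambient profile, totals ≤ 5% of the median cell),
high-mito cells (low depth, mito fraction resampled above the clean
median + 4 MADs, so they violate two QC criteria), and contaminated
microglia (microglia profile + 0.15× oligodendrocyte profile with the
*Mbp*/*Mag*/*Plp1* analogs floored at mean 5, so they stay inside the
microglia cluster but are reliably detected by the 2-of-3 marker rule).
Marker genes alone (3–4 per type) carry too little signal to separate
types at realistic depth; the planted programs are what make the
clustering benchmark meaningful.

Not emulated: batch effects between regions (integration is plain
concatenation), ambient-RNA soup in real cells, UMI collisions, doublets
as a mixture of two specific types, gene–gene correlation beyond the
planted programs, and any empirical depth/dispersion values from real
libraries (none are published for the study's libraries; defaults were
chosen for testability). Passing the pipeline's tests therefore shows the
*rules* are implemented correctly and recover planted structure under
droplet-like noise — not that the defaults are optimal on any particular
real dataset.

`simulate_skeleton()` grows a rooted binary tree (one trunk, then k
bifurcations at randomly chosen tips, straight segments of fixed length in
random 3D directions), so length `(2k+1)·L`, k branch points and `2k+1`
segments are known exactly by construction.

## Problem sizes and reproducibility

The test suite and the acceptance script run the clustering benchmark at 3
planted types × 300 cells × 1,000 genes over 20 seeds, DE calibration on
nulls of 400 cells × 500 genes (hurdle, three replicates) and 30 × 50-gene
chunks at 200 cells with independent label permutations (NB GLM), the
group-statistics calibration at 1,000 replicates of 3 × 12 observations,
and the full study-like workflow at ~1,200 barcodes × 1,500 genes — sizes
chosen so the whole suite completes in a couple of minutes while leaving
the Monte-Carlo error well inside each criterion's band. Every stochastic
step takes an explicit seed, and fixed seed implies bit-identical output:
simulation, Louvain, and subsampling all derive from function arguments,
never from global state left behind by other code.

## Known limitations

* The hurdle test's Gaussian part assumes approximate normality of
  log-normalized expression among detected cells; it is calibrated at the
  tested sizes but has no exact small-sample guarantee below ~20 detected
  cells (where the F calibration, not asymptotics, carries it).
* Method-of-moments NB dispersion is per-gene and unshrunk; with very few
  cells per subset a shrinkage estimator would be more stable (explicitly
  out of scope here).
* Silhouette-based resolution selection can over-fragment continuous
  sub-structure (visible in the purified-microglia re-clustering, where
  sub-states form a gradient rather than islands); the scan table is
  always returned so the granularity choice is auditable.
* The knee heuristic assumes a single dominant plateau of ambient
  barcodes; exotic multi-knee rank curves should be inspected via the
  selection report.
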