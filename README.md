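# miglia

Tools for studying regional heterogeneity of brain microglia with droplet
single-cell RNA-seq and 3D cell-skeleton morphometry. The package
re-implements, as tested and reusable functions, a complete analysis of
dissociated midbrain and striatum tissue: barcode selection, quality
control, normalization, clustering with data-driven resolution selection,
marker-based cell-type annotation, purification of the microglia
population, covariate-adjusted differential expression across microglia
sub-states (homeostatic vs immune-alerted), gene-signature comparison, and
skeleton-based morphometrics of microglial cells. A synthetic droplet-data
generator with planted ground truth makes every stage testable without any
download.

It is written for computational biologists who want each step of such a
pipeline as an auditable function with a contract, rather than a monolithic
framework call.

## Methods at a glance

- **Cell QC (2-of-3 MAD rule).** Per region dataset, a cell is flagged on
  the gene criterion if it expresses fewer than 200 genes or more than
  median + 2·MAD; on the depth criterion if |total counts − median| >
  2·MAD; on the mitochondrial criterion if %mito > median + 1.5·MAD (MAD
  unscaled). Cells failing ≥ 2 criteria are removed. Cell-containing
  barcodes are first selected at the knee of the cumulative count curve
  over log rank. Genes expressed in < 5 cells and all `mt-`/`Rps`/`Rpl`
  symbols are dropped.
- **Normalization and embedding.** Per cell,
  `log1p(count / total × 10,000)`; the 5,000 most variable genes by
  standardized variance under a quadratic mean–variance trend; exact PCA of
  the centered, unit-scaled (clipped at ±10) submatrix.
- **Clustering.** Shared-nearest-neighbor graph (Jaccard weights, k = 20)
  in PC space; Louvain modularity optimization over a resolution grid
  (0.1–1.5); the resolution with the best mean silhouette wins, with the
  per-cell silhouette `s = (b − a) / max(a, b)`.
- **Annotation and purification.** Cluster scores are means of z-scored
  (across clusters) marker expression from a bundled mouse brain panel
  (microglia: *P2ry12*, *Hexb*, *Cx3cr1*, *Siglech*; …). Microglia cells
  detecting ≥ 2 of *Mbp*/*Mag*/*Plp1* are purged as oligodendrocyte
  contamination.
- **Differential expression.** One-vs-rest hurdle tests (logistic detection
  part + Gaussian expression part among detected cells, both with
  log(total transcripts) as covariate; summed likelihood-ratio chi-square;
  Bonferroni), and negative-binomial GLM likelihood-ratio tests across
  subsets (same covariate; BH q-values).
- **Signatures and qPCR.** Gene-set overlap with direction concordance
  (shared genes, % shared, % with equal sign of change), and relative
  expression 2^−ΔCT against a reference gene.
- **Morphometrics.** From SWC skeletons: total process length (sum of
  parent–child edge lengths), branch points (non-root nodes with ≥ 2
  children; root only with ≥ 3), segments (maximal unbranched paths
  between root, branch points and tips). Group comparisons use one-way
  ANOVA + Tukey HSD (density, process length) and Kruskal–Wallis + Dunn
  with Bonferroni (branch points, segments).

## Worked example

The `analysis/` directory holds the full workflow as numbered scripts
(`Rscript analysis/01_simulate_data.R`, then `02` … `06`), each writing its
tables under `results/`. Running them end to end prints, among other
things:

```
simulated 1200 barcodes x 1500 genes
knee selection: 1053 of 1200 barcodes kept
cells after QC: 927 (889 clean of 960); genes kept: 1467
planted empty removed: 144 of 144 (100.0%)
planted high_mito removed: 48 of 48 (100.0%)
chosen resolution 0.1 -> 4 clusters (best silhouette 0.346)
adjusted Rand index vs planted types (clean cells): 1.000
cluster identities: 0=microglia, 1=oligodendrocytes, 2=astrocytes, 3=endothelial
36 of 265 target cells removed as contaminated
NB GLM across sub-states: 9 genes at q < 0.05
shared: 9 of 9 derived genes (100%); concordant: 9 of 9 (100%)
```

Reading: all 144 planted empty droplets fall below the barcode-rank knee
and all 48 planted high-mitochondrial cells fail the 2-of-3 rule; the
silhouette scan picks 4 clusters that reproduce the 4 planted cell types
exactly (ARI 1.0); purification removes the oligodendrocyte-contaminated
microglia; the covariate-adjusted GLM recovers the planted immune-alerted
program (9 genes at q < 0.05, all in the planted signature with the
planted direction of change). The morphometric arm (script 06) computes
process length, branch points and segments for 12 skeletons per region and
runs the matching ANOVA/Tukey and Kruskal–Wallis/Dunn statistics.

A minimal interactive session:

```r
library(miglia)
sim <- simulate_dataset(brain_sim_spec(seed = 1))
x   <- gene_filter(qc_filter(knee_select(sim$matrix))$matrix)
x   <- lognormalize(x)
emb <- pca_embed(x, select_hvg(x, 5000), n_components = 20)
rs  <- select_resolution(emb, build_knn_graph(emb, k = 20), seed = 1)
score_marker_panels(x, rs$labels)$assignments
```

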