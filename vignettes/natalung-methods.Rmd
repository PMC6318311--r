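---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natalung)
```

This vignette is the package's own account of its science: the models
behind each stage, the tunable parameters with their defaults and the
reasoning for them, what the synthetic generator does and does not
emulate, the numerical choices, and the known limitations.

## The analysis problem

Droplet scRNA-seq of whole newborn lung yields a sparse genes × cells
matrix of UMI counts in which four major cell populations (epithelial,
endothelial, mesenchymal, immune) and many subtypes are mixed, two
library preparations (batches) introduce technical differences, and a
small percentage of "cells" are two-cell droplets. The workflow turns
this matrix into a two-level cell-type atlas with per-type signature
genes, using detection frequency (count > 0) as the central statistic:
at the depth of droplet data, whether a gene is detected at all is more
robust than its magnitude.

## Quality control

Cells with fewer than `min_genes = 500` detected genes or more than
`max_mito = 0.10` mitochondrial transcript fraction are removed, then
genes detected in fewer than `min_cells = 2` cells. Removal rules are
strict inequalities ("< 500", "> 10%"), so keeps are inclusive: a cell
with exactly 500 genes or exactly 10% mitochondrial content survives.
Mitochondrial genes are recognized by the `mt-` symbol prefix
(case-insensitive), overridable by an explicit list. Cells are filtered
before genes; gene detection counts therefore refer to kept cells. QC
medians are computed on the fully filtered matrix and the summary
records the stage. For plate-based (microfluidic) data,
`filter_cells_plate()` additionally removes cells that detect more than
half the genes of two distinct major-type marker panels — cross-well
contaminants; the 50% panel threshold is a configurable convention, as
no numeric rule is standard.

## Normalization and batch scaling

Counts are divided by the cell total and multiplied by the median total,
then log2(x+1) transformed (`library_normalize()`, `log_transform()`;
the stage tag prevents double transformation; zeros stay exact zeros on
the sparse path).

Between the two steps, `control_gene_scaling()` estimates one
multiplicative factor per batch from negative-control genes — genes
whose biology is assumed constant across cell types, so any batch
difference in their means is technical. The factor for batch *b* is the
mean over control genes of (mean in reference batch / mean in *b*);
ratio-of-means is this package's explicit choice of estimator, logged in
the output, since no single formula is canonical.

One identifiability point matters and is easy to miss: a capture
efficiency factor that multiplies *every* gene of a batch is removed
exactly by library-size normalization (both numerator and denominator
scale). On data normalized by observed totals the estimated factors are
therefore expected to be ≈ 1 whenever the batch effect is globally
multiplicative — the generator's case. The recovery analyses instead
normalize by the *true* library sizes from the ground truth, where the
factor is identifiable; `analysis/03_normalize.R` shows both numbers
side by side. On real data, batch effects are never exactly global, and
the residual, gene-shared component is what this scaling removes.

## Iterative clustering

1. **Highly variable genes.** Per gene, the dispersion (variance/mean) of
   the de-logged expression is z-scored within 20 equal-frequency bins of
   the log2 mean; genes with mean in `[0.0125, 8]` (log2 scale) and z ≥ 1
   are kept. The binning removes the mean–dispersion trend; cutoffs are
   conventional and configurable.
2. **PCA.** Selected genes are z-scored across cells with values capped
   at ±10 to bound outlier leverage, and decomposed exactly
   (`prcomp`). Components with sd > 3 are kept for the major pass,
   sd > 2 for subtype passes; when fewer than 2 pass, the first 2 are
   forced (with a warning) so graph construction stays defined.
3. **Graph clustering.** A kNN graph in PC space, edges re-weighted by
   the Jaccard overlap of neighbour sets (zero-weight edges dropped), is
   partitioned by Louvain modularity maximization at resolution 1 with a
   fixed seed; labels are ordered by decreasing cluster size. The
   default `k = max(10, 0.25·√n)` is kept deliberately small: a
   community can only survive modularity optimization if k is below its
   size, and the smallest populations this workflow must resolve —
   doublet clusters — hold a percent or two of cells.
4. **Doublet clusters.** A cluster whose mean within-cluster expression
   frequency exceeds 0.5 for two or more distinct major-type panels is
   flagged and excluded from subtyping and signatures.
5. **Type assignment.** Each cluster gets the panel maximizing the mean
   sensitivity-based enrichment score of the panel's genes; the margin to
   the runner-up is reported and exact ties yield `"ambiguous"`. Several
   modularity clusters typically map to one type: Louvain refines
   homogeneous populations into sub-communities, and the reconciliation
   through marker panels — not a forced cluster count — recovers the
   types. This is why agreement with truth is evaluated on assigned type
   labels.
6. **Subtypes.** Within each assigned major type (pooled across its
   clusters): ComBat empirical-Bayes batch correction when more than one
   batch is present, fresh variable-gene selection, PCA with the sd > 2
   rule, and Jaccard–Louvain again. Batch correction is applied only at
   this level; at the major level the types separate without it.
   ComBat's shrinkage has no exact fixed point, so re-correction moves
   per-gene means by the shrunk estimation noise (order 10⁻³ at these
   sizes) — approximate, not exact, idempotence.
7. **Dendrogram.** Cell types are summarized by mean expression over
   signature genes; distance is 1 − Pearson correlation with Ward
   linkage (`ward.D2`; `average` linkage reproduces the plate-data
   hierarchical-clustering contract). Serializable to Newick.

t-SNE embeddings (`tsne_embed()`) are produced for visualization only
and are never consumed by clustering or statistics.

## Marker statistics

"Expression" is detection, count > 0, throughout. For a gene in a
cluster, with in/out expressing counts *m*ᵢₙ/*m*ₒᵤₜ of *n*ᵢₙ/*n*ₒᵤₜ
cells:

- **Binomial test** (one-tailed, enrichment): P(X ≥ *m*ᵢₙ) for
  X ~ Binomial(*n*ᵢₙ, *p*₀), *p*₀ the out-of-cluster frequency, by exact
  tail summation. A zero out-frequency uses the pseudo-frequency
  1/(*n*ₒᵤₜ+1), for the test and for the effective size. The
  out-frequency excludes the cluster's own cells. Because *p*₀ is
  plugged in as known, the test is calibrated only in its intended
  cluster-versus-rest regime (*n*ₒᵤₜ ≫ *n*ᵢₙ): at a 1:9 split the null
  rejection at 0.05 sits near 0.04, while at a 50/50 split the size
  inflates to ≈ 0.11 — a caveat the tests document explicitly. FDR is
  Benjamini–Hochberg within cluster across genes.
- **Signatures**: the four criteria (FDR < 0.05, effective size ≥ 2,
  in-frequency ≥ 0.2, overall frequency < 0.4), ranked by sensitivity
  descending, FDR ascending, gene id as the final tiebreak for
  reproducibility, capped at 100. In the pipeline, signatures are
  computed per assigned cell type with doublet-cluster cells excluded.
- **Enrichment score** (a/b)/(c/d): undefined scores (b = 0 or c = 0)
  are missing, never 0.
- **Fisher association**: one-tailed hypergeometric tail, no mid-p
  correction; pass means p < 0.05 and enrichment ≥ 1.5, unadjusted (a BH
  column is provided for reference). The exact test is conservative at
  moderate sample sizes: on a 400-cell null its empirical size is
  ≈ 0.032, not 0.05 — a property of exact conditional tests, documented
  rather than "fixed" with mid-p.
- **Welch t** (one-tailed, Welch–Satterthwaite df) for plate data;
  **chi-square with Yates** for comparing two detection frequencies;
  **candidate TF selection** by the differential-expression clause
  (FDR < 0.1, effective size ≥ 2, in-frequency ≥ 0.2, overall < 0.4,
  sensitivity ≥ 0.2) or expression in > 60% of the type's cells;
  **pseudo-bulk** as per-group raw-count sums with optional per-million
  scaling.

Null-calibration experiments evaluate rejection rates on genes with
detection frequency in [0.1, 0.9]: outside that range the discrete tests
cannot reject at all (they are conservative, which is asserted
separately), so including such genes would only dilute the measurement.

## The synthetic generator

`simulate_counts()` draws gamma–Poisson (negative-binomial) counts with
expected value `library_size × batch_factor × profile(gene, type)`. What
it emulates, with defaults and reasons:

- **Cell types and subtypes**: 3 types × 2 subtypes × 2 batches × 200
  cells ≈ 1,200 cells; each type over-expresses 20 disjoint markers
  8-fold, each subtype 10 further markers 8-fold.
- **Skewed gene abundance**: filler-gene weights are log-normal
  (sd 2.4 on the log scale), reproducing droplet data's sparse detection
  regime where most genes are rarely detected; marker and control genes
  sit at a fixed weight (0.8 relative to the filler median). The total
  filler mass is pinned to its expectation so that the structured genes'
  share of the transcriptome is a design quantity rather than a
  heavy-tailed random draw — otherwise marker detectability would swing
  ±40% between seeds.
- **Counts**: negative-binomial with size 5, in the range estimated for
  UMI data (inverse overdispersion roughly 3–10); library sizes
  log-normal (median ≈ 5,500, sd 0.3 logs).
- **Mitochondrial genes**: 13 genes (the mitochondrial protein-coding
  complement) named `mt-*`, carrying 5% of expected transcripts in every
  type, so the QC prefix rule works unchanged.
- **Negative controls**: 200 genes with identical expected expression in
  all types.
- **Batch effect**: a single multiplicative capture factor (1.5 on batch
  2) on all genes — see the identifiability note above.
- **Doublets**: 7.5% of cells are equal-weight mixtures of two distinct
  *type-level* (subtype-averaged) profiles with 1.5× library size. The
  rate preserves the absolute size of doublet clusters (~30 cells per
  type pair) observed in real atlases of ~8,000 cells at this fixture's
  6.7× smaller scale; preserving the detected-cluster *rate* (~2%)
  instead would leave groups too small to resolve at 1,200 cells.

What it does **not** emulate: ambient RNA and empty droplets, UMI
collisions, gene–gene correlation beyond type structure, gene-specific
batch effects, cell-cycle or continuous (trajectory) variation.
Passing tests on this generator therefore show the workflow recovers
planted discrete structure under realistic sparsity and noise — not that
it is robust to every artefact of real droplet data.

## Stochasticity and determinism

Every stochastic stage takes a seed; the pipeline fans a single master
seed out by fixed offsets (simulation = seed, major Louvain = seed+101,
subtype passes = seed+1000+index), so full runs are bit-identical under
one seed, and the RNG state of the calling session is never disturbed.
Louvain itself is seed-dependent: cluster *boundaries* at the community
scale can differ between seeds even when type-level results agree.

## Problem sizes

Tests and the acceptance analyses run at desk scale, chosen so the whole
suite completes in well under two minutes of compute per component: the
reference fixture ~1,200 cells × 2,000 genes, the null calibration 2,000
genes × 400 cells with 10 random labelings, statistic oracles at 100
random tables each. Brute-force kNN (dense distances) is quadratic in
cells and entirely adequate at these sizes; a tree- or index-based
neighbour search would be the first change needed for 10⁵-cell data.

## Known limitations

- The binomial test's plug-in out-frequency makes it anticonservative
  outside the cluster-versus-rest regime (see above).
- The exact Fisher association is conservative (empirical size ≈ 0.032
  at 400 cells); power comparisons against mid-p variants are out of
  scope.
- Doublet-cluster flagging requires doublets to form clusters; mixtures
  diluted below ~50% panel co-expression, or doublet groups split by the
  clustering, escape the flag. In the reference conditions, strong
  doublet communities (≥ 75% doublets) are always flagged, but total
  doublet capture is partial — consistent with real atlases, where
  flagged doublet clusters hold fewer cells than the physical doublet
  rate implies.
- Ratio-of-means control scaling assumes the residual batch effect is
  shared across control genes; gene-specific batch effects are only
  addressed at the subtype level by ComBat.
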