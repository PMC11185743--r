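---
title: "Methods: building and interrogating a dopamine-neuron subtype taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and interrogating a dopamine-neuron subtype taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`dopatax` implements a complete desk-scale workflow for organizing midbrain
dopamine (DA) neuron subtypes into a hierarchical molecular taxonomy from
single-nucleus RNA-seq counts, projecting spatial-panel (MERFISH-style)
measurements onto that taxonomy, contrasting genotypes, and scoring cells
for polygenic disease relevance. Every stage can be validated against a
synthetic-data generator that plants a known taxonomy, spatial layout, and
genotype effects, so that recovery is measurable rather than assumed.

This vignette explains the models and procedures, the parameters that
matter, the numerical choices, and what the synthetic validation does and
does not establish about real data.

# The synthetic-data generator

`make_truth()` plants a rooted binary taxonomy: families are joined under
the root (family 1 versus the rest, then family 2 versus family 3), and
leaves within a family split recursively. Defaults give three families of
two leaves — six subtypes — over a 600-gene universe, matching the
three-family organization typical of DA-neuron taxonomies at a size where
every stage runs in seconds.

**Branch markers are near-binary.** Each internal node carries eight marker
genes per arm, expressed at `effect_size` (default 4) times their baseline
along that arm and at `off_leak` (default 0.05) times baseline elsewhere.
The realized on/off mean ratio is therefore `effect_size / off_leak` = 80,
i.e. log2 fold changes around 6 — the regime in which curated DA branch
markers (Sox6, Calb1, Gad2, Prkcd-class genes) actually operate, and the
regime a detection-difference marker filter is designed for. A graded 4-fold
marker on an otherwise well-expressed gene cannot be a useful intersectional
gate: with negative-binomial counts its off-branch detection never falls
below roughly half, and stepwise codes built from such genes stop isolating
their target populations. Marker baselines are drawn lognormal
(meanlog −1, sd 0.4) so that on-branch detection is ~90% and off-branch
detection ~10% at the default depth.

**Counts.** Cells draw a leaf from the leaf proportions (uniform by
default); per-gene rates are baseline times the node multipliers along the
cell's root-to-leaf path, times genotype effects; counts are negative
binomial with shared dispersion `r` (default 2; variance `mu + mu^2/r`) and
a lognormal per-cell depth factor (sigma 0.35 around 5,000 counts). The
literature rarely characterizes count noise beyond medians, so the
dispersion default is a free, documented choice; a moment check in the test
suite verifies the generator's variance follows the closed form, including
the Poisson limit.

**Sex structure.** Two male-specific and two female-specific genes (the
Uty/Eif2s3y versus Xist/Tsix convention) are expressed at high level in the
matching sex; 5% of cells drop both sets, creating the indeterminate middle
peak seen in real sex-ratio histograms.

**Doublets.** A fraction (default 3%) of cells are 50/50 mixtures of one DA
leaf profile and a glial profile (four glial marker genes); they carry their
own truth label and are expected to be flagged at cluster level, not
per cell.

**Spatial data.** The panel holds 120 genes: most planted markers (the last
two of each node arm stay off-panel, as real reduced panels omit some
informative genes — these off-panel markers are what imputation is tested
on) plus random background genes. Two panel genes are forced to zero
detection, emulating failed probes. Cells are placed uniformly inside the
rectangular region polygon assigned to their family (SNc, VTA, RR;
micrometre coordinates, origin bottom-left, one pseudo-section per
dataset); volumes are lognormal around 1,500 µm³. Spatial depth defaults to
400 transcripts per cell over the panel; this keeps per-gene mean counts
within a factor ~2 of the reference on the shared genes, the regime in
which a ratio-based shared-feature filter retains most of the panel, as a
real cross-platform selection does.

What the generator does **not** emulate: transcriptome-wide co-expression,
batch and ambient-RNA structure, segmentation errors beyond the volume
filter, and spatial gradients within regions. Passing the recovery tests
therefore demonstrates the correctness of the algorithms under a known
model, not their performance on any particular real dataset.

# Quality control and sex inference

`compute_qc()` reports per-cell totals, detected genes, and mitochondrial /
ribosomal count fractions on the [0, 1] scale. `filter_cells()` applies
per-sample windows with strict open bounds, matching the conventional
`>` / `<` subset filters; a Seurat-style `percent.mt < 0.5` is 0.5 percent,
i.e. 0.005 as a fraction, and configurations should state which scale they
use. `filter_spatial_cells()` keeps cells with segmentation volume inside
[500, 4000] µm³ and at least 40 transcripts; the volume window is stated
as keep-within, the intent behind the usual "too large or too small"
exclusion.

`infer_sex()` scores `log2((male + 1) / (female + 1))` and calls at ±1
(2-fold) by default — the published histograms show three peaks but no
cutoff, so the threshold is a documented choice. Gene lists are
configuration, not constants, because "Eif" alone is not a unique symbol
(Eif2s3y is the likely intent).

`flag_doublet_clusters()` flags any cluster in which more than half the
cells detect a glial marker — cluster-level flagging as practiced, not a
per-cell doublet simulation.

# Normalization, embedding, clustering

Normalization is counts-per-10,000 followed by `log1p`; the embedding input
is per-gene z-scored with values clipped at ±10. SCTransform and CCA-based
multi-sample integration are deliberately not reimplemented; users mapping
real multi-sample data should expect differences from pipelines that
integrate. One consequence is handled explicitly: pooled male and female
animals leave strong sex-gene structure that integration would have
absorbed, so `reduce_dims()` accepts `exclude_genes` and the standard
practice is to exclude the known sex-linked genes from the embedding (they
remain available for marker statistics). The PCA fixes each component's
sign so the largest-magnitude loading is positive, making runs reproducible
across BLAS implementations.

Clustering builds the exact Euclidean k-nearest-neighbour graph in
component space (self included, k = 40 by default), converts it to
shared-nearest-neighbour Jaccard weights pruned below 1/15, and runs seeded
Louvain modularity at the requested resolution; singletons merge into the
nearest centroid. Resolution is a per-dataset operating point in this
field (published DA work uses 0.8 for snRNA-seq, 0.7 for MERFISH, 0.65 for
subclustering); for the default six-leaf simulation the package's workflow
uses resolution 1.0 with 32 components, which separates sibling leaves
without fragmenting them. `cluster_stability()` re-runs the whole
normalize/reduce/cluster path on random 80% subsamples and scores each
original cluster by the fraction of retained within-cluster pairs still
co-clustered — a declared stand-in for unpublished stability scripts, with
box-plot summaries (1.5×IQR outliers) per cluster.

# The taxonomy: node markers, stepwise codes, names

`build_tree()` joins cluster centroids by average-linkage hierarchical
clustering on Euclidean distances (the reference implementation leaves its
linkage unstated; average linkage is the documented choice).
`annotate_nodes()` runs Wilcoxon marker statistics between the two arms of
every node using only cells descending from that node, with the
binary-marker thresholds `min_pct = 0.2`, `min_diff_pct = 0.25`,
`logfc_threshold = 1`. Fold changes use the
`log2((mean(expm1 x) + 1) / (mean(expm1 y) + 1))` convention with its
pseudocount of 1; p-values use the normal approximation with tie and
continuity correction, BH-adjusted across tested genes; ordering is fully
deterministic (|log2fc| desc, then p, then gene name). Both positively and
negatively enriched sides are retained at every node.

`derive_codes()` walks root-to-leaf and records one gate gene per branch
point. Published codes involved manual curation of the gene that "best
distinguished" each branch; the deterministic stand-in picks the side's
marker with the largest detection gap (pct1 − pct2), which is precisely the
property that makes a gene usable as a literal expression gate. The
fold-change-ranked top marker is available via `gate_by = "rank"`. Codes
are unique by construction (distinct root-to-leaf paths); the test suite
additionally evaluates each code as an intersectional detection gate and
requires it to isolate its target leaf.

`name_clusters()` assigns families from the top-level divisions of the tree
and names each cluster `Family^TopGene` from a one-vs-rest-of-family
comparison, resolving collisions with the next-ranked gene and falling back
to `Family^cN` where one-vs-rest is undefined (single-cluster families).

# Spatial mapping

`select_shared_features()` keeps genes detected in both datasets whose
per-cell mean counts agree within `max_ratio` (default 4 — how the
published 281-of-500 selection was thresholded is unquantified, so this is
a declared choice); zero-detection panel genes (failed probes) are always
excluded.

`find_anchors()` projects the query onto the reference PCA of the shared,
per-dataset-scaled genes (a documented simplification of CCA-based anchor
machinery: project-then-match). Mutual nearest neighbours across datasets
become anchors. Each anchor is scored by shared-neighbour overlap: the
fraction of the reference member's nearest query cells that also neighbour
the query member, averaged with the mirror-image fraction on the reference
side. Anchors that join cells embedded in different neighbourhoods — as
happens when a query population has no reference counterpart — score low.

`transfer_labels()` weights each query cell's nearest anchors with a
Gaussian kernel (bandwidth = distance to the k_weight-th anchor),
normalizes the kernel to sum 1, multiplies by the anchor scores, and sums
by reference label. The similarity score (the argmax label's weight) is
therefore ≤ 1, reaching 1 only when all contributing anchors are perfect;
it is gated at 0.5 by default. "Cell similarity score" and
"prediction.max.score" are treated as the same quantity. Two degenerate
rules keep the geometry exact: anchors at numerically zero distance take
all the weight, and among them identity anchors (both ends coinciding with
the query cell) take precedence — this is what makes the
reference-as-query round trip reproduce each cell's own profile exactly.

`impute_expression()` uses the same weights renormalized to a convex
combination, so imputed values are bounded by the contributing reference
profiles. `imputation_fidelity()` correlates imputed with measured
expression per gene over cells non-zero in both, reporting NA below 10
such cells — failed probes surface here as NA/low fidelity.
`assign_regions()` implements even-odd ray casting with boundary points
counting as inside and first-polygon-wins priority; GeoJSON winding is
ignored. Composition tables are emitted in both normalizations (within
region and within cluster).

# Genotype contrasts

`condition_de()` applies the Wilcoxon machinery with only a 10% detection
filter and no fold-change filter, BH across tested genes, and summary
counts of FDR-significant genes and |log2fc| > 0.5 subsets. The per-cell
test treats cells as independent — with few libraries per condition this
inflates significance, so every result carries an explicit
pseudoreplication warning field; pseudobulk is out of scope at two
libraries per group. `proportion_shift()` adds a permutation test for
composition changes (published comparisons were descriptive; the test is
added rigor). `cluster_similarity()` is neighbour voting: pooled Spearman
correlations over jointly variable genes (binned by expression, top decile
excluded, bin-median dispersion rule — the exact within-bin cutoff of the
reference pipeline is not restated anywhere, so the bin median is a
declared stand-in), mean correlation to each cluster as the vote, and
AUROC per cluster pair. ALRA dropout correction is not reimplemented;
similarity runs on normalized counts, with any imputed matrix accepted as
an optional input.

# Enrichment

`preranked_gsea()` computes the weighted Kolmogorov-Smirnov running sum
(hit steps proportional to |score|, exponent 1), builds the null from
random same-size gene sets, reports the two-sided tail frequency with +1
smoothing, and normalizes ES by the mean |null ES| of matching sign
(whether published p-values were one- or two-tailed per sign is unstated;
two-sided with sign-matched NES is adopted). Defaults follow the
conventional 25/500 size window and 1,000 permutations.
`overrepresentation()` is the upper-tail hypergeometric against a
caller-supplied expression background — the ≥10%-detection universe of the
contrast that produced the hits — so results are not driven by cell-type
specific expression. `synaptic_fractions()` reports compartment and
function fractions with raw counts alongside ("20/77"-style); gene matching
throughout is case-insensitive with an optional ortholog map.

# Disease-relevance scoring

`score_cells()` weights each risk gene by `z / (sd + 0.05)` ("vs"
inverse-variance weighting; the reference tool's exact formula is not
restated in print, so epsilon and the `sum(|w|)` normalization are
documented choices validated by the null-calibration tests) and averages
normalized expression. Control sets replace every risk gene with a uniform
draw from the same (mean, variance) expression bin. Every score vector —
risk and each control — is standardized across cells before the per-cell
normalization; this removes the gene-set-level offset that would otherwise
move all cells of a replicate together and is what makes group-level
inference calibrated. Binning defaults to the conventional 20×20, which
presumes a transcriptome-scale gene universe; at desk scale the bins should
be scaled to keep control pools of ~20 genes (the synthetic workflow uses
10×3 on 600 genes — 20×20 would leave one or two genes per pool and make
controls degenerate). Scoring uses the full normalized matrix by default
(whether the published highly-variable-gene step restricted scoring or only
embedding preparation is ambiguous; an HVG restriction can be applied by
subsetting the matrix).

`group_bootstrap()` resamples cells with replacement within each group
(default 10,000 resamples), takes percentile CIs, and calls a group
significant when the 95% CI excludes 0. Note what this does and does not
test: it propagates cell-sampling uncertainty only. A random gene set that
genuinely overlaps a subtype's marker program produces a real association
that this test will (correctly) flag; the null-calibration property is
therefore stated for gene sets with no constructed relation to the cell
grouping, where the false-positive rate is controlled. Monte-Carlo per-cell
p-values against the control distribution are also emitted.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → qc → taxonomy → spatial → contrast →
risk from a single config (YAML or JSON), writing CSV/MatrixMarket/GeoJSON/
Newick outputs with md5s in a manifest. All randomness derives from one
global seed fanned out per stage by a stable string hash, so stage
insertion does not shift other stages' streams and two runs of one config
are byte-identical. Problem sizes in the bundled tests and in
`scripts/acceptance.R` — 3,000 dissociated cells, 1,500 spatial cells, 600
genes, six leaves — are the package's chosen desk-scale study conditions:
large enough for every statistic to stabilize, small enough to iterate on.

# Known limitations

- No SCTransform/CCA integration and no batch simulation: real multi-sample
  datasets will cluster differently than under the published pipeline.
- The stability score is a pair-counting stand-in for unpublished scripts.
- Per-cell DE p-values are anti-conservative under pseudoreplication (the
  warning field says so); group-level risk inference propagates
  cell-sampling uncertainty only.
- The anchor machinery is project-then-match; datasets with strong
  platform-specific expression shifts would benefit from the full CCA
  treatment it simplifies.
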