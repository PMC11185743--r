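# dopatax

Hierarchical molecular taxonomy of midbrain dopamine (DA) neuron subtypes:
clustering, dendrogram node markers and stepwise codes, spatial-panel label
transfer, genotype contrasts, and polygenic disease-relevance scoring — with
a synthetic-data generator that plants known ground truth so every stage is
verifiable.

## The scientific problem

Midbrain DA neurons are not one population: single-nucleus RNA-seq resolves
them into families (Sox6-like, Calb1-like, Gad2-like) that subdivide into
many subtypes with distinct anatomy and disease vulnerability. Working with
such a taxonomy raises a chain of computational problems that this package
solves as one pipeline:

1. **QC and sex inference** — per-sample filter windows on UMIs, detected
   genes, and mitochondrial/ribosomal fractions; per-cell sex calls from
   the log2 ratio of male-specific (Uty/Eif2s3y-type) to female-specific
   (Xist/Tsix-type) counts; cluster-level flagging of neuron–glia doublets
   by glial marker detection (Mbp/Atp1a2-type).
2. **Taxonomy** — shared-nearest-neighbour Louvain clustering of a PCA
   embedding; average-linkage dendrogram over cluster centroids; Wilcoxon
   marker statistics at every branch point using only the descendant cells
   (`pct1`/`pct2` detection fractions, Seurat-convention
   `log2((mean(expm1 x)+1)/(mean(expm1 y)+1))` fold changes, BH
   correction); a unique **stepwise expression code** per subtype — the
   ordered branch-gate genes from root to leaf, e.g.
   `MK016+ & MK044+ & MK079+` — and `Family^TopGene` shorthand names;
   downsample–recluster stability scores.
3. **Spatial mapping** — shared-feature selection between a reduced gene
   panel (MERFISH-style) and the reference; mutual-nearest-neighbour
   anchors in a projected joint space with shared-neighbourhood scores;
   label transfer with a similarity score gated at 0.5;
   whole-transcriptome imputation with per-gene fidelity correlations;
   region polygon assignment (even-odd point-in-polygon, GeoJSON) and
   composition tables.
4. **Genotype contrasts** — scoped Wilcoxon differential expression with a
   10% detection background, permutation tests for subtype proportion
   shifts, and neighbour-voting cluster-similarity AUROCs across
   conditions.
5. **Enrichment and risk** — preranked GSEA (weighted Kolmogorov–Smirnov
   running sum, random-set null, sign-matched NES), hypergeometric
   over-representation against a custom expression background, synaptic
   compartment/function fractions, and scDRS-style cell scores for GWAS
   gene sets against mean–variance-matched control genes with bootstrap
   group-level confidence intervals.

The synthetic module (`make_truth()`, `simulate_counts()`,
`simulate_spatial()`) plants a three-family, six-leaf binary taxonomy with
near-binary branch markers (on/off ratio ≈ 80, the log2FC ≈ 6 regime of
curated DA markers), negative-binomial counts with lognormal depth,
sex-gene structure, glial doublets, a 120-gene spatial panel with failed
probes, rectangular SNc/VTA/RR region layouts, and a genotype that shifts
expression without shifting composition.

## Worked example

```r
library(dopatax)

truth  <- make_truth(seed = 1)
counts <- simulate_counts(truth, n_cells = 3000, seed = 2)
truth
#> truth_spec: 600 genes, 6 leaves in 3 families, 5 nodes
#> topology: ((L1_1,L1_2),((L2_1,L2_2),(L3_1,L3_2)));

nr  <- normalize_counts(counts)
emb <- reduce_dims(nr, 32, exclude_genes = unlist(truth$sex_genes))
cl  <- cluster_cells(emb, k_neighbors = 40, resolution = 1, seed = 3)
cl
#> clustering: 3000 cells, 7 clusters (k=40, resolution=1)
#>   0   1   2   3   4   5   6
#> 503 496 489 482 478 457  95

adjusted_rand_index(cl$labels, counts$cell_meta$truth_leaf)
#> [1] 0.9985363

# cluster 6 is the planted neuron-glia doublet cluster; flag and drop it
flag_doublet_clusters(counts, cl$labels, truth$doublet_spec$markers)
#> [1] "6"
```

After removing the flagged cluster and re-clustering, the dendrogram,
node markers, stepwise codes and names:

```r
tree <- derive_codes(annotate_nodes(build_tree(emb2, cl2), nr2, cl2))
tree$recipes
#>                          0                          1
#> "MK016+ & MK044+ & MK079+"          "MK001+ & MK029+"
#>                          2                          3
#>          "MK001+ & MK019+" "MK016+ & MK044+ & MK066+"
#>                          4                          5
#> "MK016+ & MK037+ & MK057+" "MK016+ & MK037+ & MK050+"

name_clusters(tree, nr2, cl2)
#>   cluster family     name         top_genes
#> 1       0     F2 F2^MK079 MK079,MK075,MK073
#> 2       1     F1 F1^MK030 MK030,MK027,MK025
#> ...
```

Each recipe reads as an intersectional detection gate: a cell of subtype 0
is a cell detecting MK016, MK044 and MK079 — the branch genes on its
root-to-leaf path. Here the codes recover the planted node markers
(MK001/MK016 are root-arm markers, the final gene is the leaf's own
marker), and evaluating the gates on raw counts isolates each target leaf
with median precision ≈ 0.9 (`evaluate_code()`).

The whole chain — including spatial transfer, contrasts, and risk — runs
from one config:

```r
manifest <- run_pipeline(list(seed = 11, out_dir = "run1"))
# identical seeds give byte-identical outputs
```

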