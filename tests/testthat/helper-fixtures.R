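# shared fixtures, computed once per test session

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, builder(), envir = .fx)
  .fx[[name]]
}

fx_truth <- function() fx("truth", function() make_truth(seed = 101))

fx_counts <- function() fx("counts", function()
  simulate_counts(fx_truth(), n_cells = 3000, seed = 102))

fx_norm <- function() fx("norm", function() normalize_counts(fx_counts()))

fx_embedding <- function() fx("embedding", function()
  reduce_dims(fx_norm(), 32, exclude_genes = unlist(fx_truth()$sex_genes)))

fx_clustering <- function() fx("clustering", function()
  suppressWarnings(cluster_cells(fx_embedding(), 40, 1.0, seed = 103)))

# doublet-flagged clusters removed, re-normalized and re-clustered: the
# state on which the dendrogram is built
fx_clean <- function() fx("clean", function() {
  tr <- fx_truth()
  cl <- fx_clustering()
  flagged <- flag_doublet_clusters(fx_counts(), cl$labels,
                                   tr$doublet_spec$markers)
  keep <- !(as.character(cl$labels) %in% flagged)
  counts <- fx_counts()[, keep]
  nr <- normalize_counts(counts)
  emb <- reduce_dims(nr, 32, exclude_genes = unlist(tr$sex_genes))
  cl2 <- suppressWarnings(cluster_cells(emb, 40, 1.0, seed = 103))
  list(counts = counts, norm = nr, embedding = emb, clustering = cl2,
       flagged = flagged)
})

fx_tree <- function() fx("tree", function() {
  cln <- fx_clean()
  tree <- build_tree(cln$embedding, cln$clustering)
  tree <- annotate_nodes(tree, cln$norm, cln$clustering)
  derive_codes(tree)
})

fx_spatial <- function() fx("spatial", function()
  simulate_spatial(fx_truth(), fx_counts(), n_cells = 1500, seed = 104))

fx_anchors <- function() fx("anchors", function() {
  shared <- select_shared_features(fx_counts(), fx_spatial())
  find_anchors(fx_counts(), fx_spatial(), shared, seed = 105)
})

# majority truth leaf per cluster of a clustering
majority_leaf <- function(labels, truth_leaf) {
  vapply(split(truth_leaf, as.character(labels)),
         function(v) names(which.max(table(v))), "")
}

# independent AUROC used as an oracle in tests
oracle_auroc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small deterministic count_matrix for unit tests
toy_counts <- function(n_genes = 50, n_cells = 20, seed = 7, lambda = 3) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  count_matrix(m)
}
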