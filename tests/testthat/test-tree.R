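fake_clustering <- function(labels) {
  structure(list(labels = labels, k_neighbors = 10, resolution = 1,
                 seed = 1), class = "clustering")
}

test_that("tree topology follows average-linkage centroid distances", {
  # three tight blobs: A and B close, C far; first merge must be {A, B}
  set.seed(30)
  scores <- rbind(cbind(rnorm(10, 0, .01), rnorm(10, 0, .01)),
                  cbind(rnorm(10, 1, .01), rnorm(10, 0, .01)),
                  cbind(rnorm(10, 10, .01), rnorm(10, 0, .01)))
  labels <- rep(0:2, each = 10)
  tree <- build_tree(structure(list(scores = scores), class = "embedding"),
                     fake_clustering(labels))
  first <- tree$nodes[[1]]
  expect_setequal(c(first$left_leaves, first$right_leaves), c("0", "1"))
  expect_setequal(tree$leaves, c("0", "1", "2"))
  expect_error(build_tree(structure(list(scores = scores),
                                    class = "embedding"),
                          fake_clustering(rep(0, 30))), ">= 2 clusters")
})

test_that("the inferred dendrogram reproduces the planted families", {
  tr <- fx_truth()
  cln <- fx_clean()
  tree <- fx_tree()
  expect_setequal(tree$leaves, as.character(sort(unique(cln$clustering$labels))))

  maj <- majority_leaf(cln$clustering$labels,
                       cln$counts$cell_meta$truth_leaf)
  fam <- tree_families(tree, 3)
  planted <- tr$families[maj[names(fam)]]
  # family partition congruent with the planted families
  expect_equal(length(unique(paste(fam, planted))), 3)

  # planted topology recovered exactly (Robinson-Foulds distance 0)
  inferred <- ape::read.tree(text = tree_newick(
    tree, leaf_names = maj[tree$leaves]))
  planted_phy <- ape::read.tree(text = tr$tree_newick)
  rf <- phangorn::RF.dist(ape::unroot(inferred), ape::unroot(planted_phy))
  expect_equal(rf, 0)
})

test_that("node markers are local to their branch point", {
  cln <- fx_clean()
  tree <- fx_tree()
  # a non-root node: recomputing its markers from only its descendant
  # cells reproduces the stored tables
  nid <- tree$nodes[[1]]$id
  nd <- tree$nodes[[nid]]
  labels <- as.character(cln$clustering$labels)
  a <- which(labels %in% nd$left_leaves)
  b <- which(labels %in% nd$right_leaves)
  mk <- rank_markers(cln$norm$norm, a, b)
  left <- mk[mk$log2fc > 0, , drop = FALSE]
  rownames(left) <- NULL; rownames(nd$markers_left) <- NULL
  expect_equal(nd$markers_left, left)
})

test_that("identical arms yield empty markers and a named code error", {
  set.seed(31)
  counts <- matrix(rpois(40 * 60, 4), 40,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("c%03d", 1:60)))
  x <- count_matrix(counts)
  nr <- normalize_counts(x)
  labels <- rep(0:1, each = 30)
  scores <- cbind(rnorm(60), rnorm(60))
  tree <- build_tree(structure(list(scores = scores), class = "embedding"),
                     fake_clustering(labels))
  tree <- annotate_nodes(tree, nr, fake_clustering(labels))
  expect_equal(nrow(tree$nodes[[1]]$markers_left), 0)
  expect_error(derive_codes(tree), "N1")
})

test_that("stepwise codes are unique and follow the root-to-leaf path", {
  tree <- fx_tree()
  expect_false(anyDuplicated(tree$recipes) > 0)
  for (leaf in tree$leaves) {
    code <- tree$codes[[leaf]]
    expect_identical(code$node[1], tree$nodes[[length(tree$nodes)]]$id)
    expect_true(all(code$sign == "+"))
    # each code gene appears in the corresponding node marker list
    for (i in seq_len(nrow(code))) {
      nd <- tree$nodes[[code$node[i]]]
      expect_true(code$gene[i] %in% c(nd$markers_left$gene,
                                      nd$markers_right$gene))
    }
  }
})

test_that("two-leaf trees give single-gate codes", {
  set.seed(33)
  counts <- matrix(rpois(30 * 80, 2), 30,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("c%03d", 1:80)))
  counts["g01", ] <- c(rpois(40, 15), rpois(40, 0.1))  # gX marks cluster 0
  counts["g02", ] <- c(rpois(40, 0.1), rpois(40, 15))  # gY marks cluster 1
  x <- count_matrix(counts)
  nr <- normalize_counts(x)
  labels <- rep(0:1, each = 40)
  scores <- cbind(c(rnorm(40, 0, .1), rnorm(40, 5, .1)), rnorm(80, 0, .1))
  tree <- build_tree(structure(list(scores = scores), class = "embedding"),
                     fake_clustering(labels))
  tree <- annotate_nodes(tree, nr, fake_clustering(labels))
  tree <- derive_codes(tree)
  expect_identical(unname(tree$recipes), c("g01+", "g02+"))
})

test_that("shorthand names use family and planted top markers", {
  tr <- fx_truth()
  cln <- fx_clean()
  tree <- fx_tree()
  nm <- name_clusters(tree, cln$norm, cln$clustering, n_families = 3)
  expect_false(anyDuplicated(nm$name) > 0)
  maj <- majority_leaf(cln$clustering$labels,
                       cln$counts$cell_meta$truth_leaf)
  # the name's gene is one of the leaf's own planted markers for >= 5/6
  leaf_markers <- function(leaf) {
    hits <- vapply(tr$nodes, function(nd)
      identical(nd$left_leaves, leaf) || identical(nd$right_leaves, leaf),
      TRUE)
    nd <- tr$nodes[[which(hits)[1]]]
    if (identical(nd$left_leaves, leaf)) nd$markers_left else nd$markers_right
  }
  gene <- sub("^F\\d+\\^", "", nm$name)
  ok <- vapply(seq_len(nrow(nm)), function(i)
    gene[i] %in% leaf_markers(maj[[nm$cluster[i]]]), TRUE)
  expect_gte(sum(ok), 5)

  # single-cluster family falls back to a positional name
  sub_labels <- fake_clustering(rep(0:2, each = 10))
  scores <- cbind(c(rnorm(10, 0, .01), rnorm(10, 1, .01), rnorm(10, 20, .01)),
                  rnorm(30, 0, .01))
  counts <- matrix(rpois(20 * 30, 3), 20,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("c%03d", 1:30)))
  t2 <- build_tree(structure(list(scores = scores), class = "embedding"),
                   sub_labels)
  t2 <- annotate_nodes(t2, normalize_counts(count_matrix(counts)), sub_labels)
  n2 <- name_clusters(t2, normalize_counts(count_matrix(counts)), sub_labels,
                      n_families = 2)
  expect_true(any(grepl("\\^c", n2$name)))  # the singleton family
})
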