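make_blob_counts <- function(n_per, seed = 1, n_genes = 60, strength = 30) {
  set.seed(seed)
  mu <- matrix(1, n_genes, 2)
  mu[1:20, 1] <- strength
  mu[21:40, 2] <- strength
  counts <- cbind(matrix(rpois(n_genes * n_per, mu[, 1]), n_genes),
                  matrix(rpois(n_genes * n_per, mu[, 2]), n_genes))
  dimnames(counts) <- list(sprintf("g%02d", seq_len(n_genes)),
                           sprintf("c%03d", seq_len(2 * n_per)))
  list(x = count_matrix(counts), truth = rep(c("A", "B"), each = n_per))
}

test_that("well-separated blobs are recovered exactly; resolution 0 merges all", {
  blob <- make_blob_counts(60, seed = 21)
  nr <- normalize_counts(blob$x)
  emb <- reduce_dims(nr, 5)
  # k on the order of the cluster size, as with any k-NN graph method
  cl <- suppressWarnings(cluster_cells(emb, 30, 0.8, seed = 1))
  expect_equal(adjusted_rand_index(cl$labels, blob$truth), 1)
  expect_identical(sort(unique(cl$labels)), 0:1)

  # resolution -> 0 merges every community of a connected graph
  one <- make_blob_counts(60, seed = 25, strength = 1)  # homogeneous
  emb1 <- reduce_dims(normalize_counts(one$x), 5)
  cl0 <- suppressWarnings(cluster_cells(emb1, 30, 0, seed = 1))
  expect_equal(length(unique(cl0$labels)), 1L)
})

test_that("clustering recovers the planted taxonomy at study scale", {
  cl <- fx_clustering()
  truth <- fx_counts()$cell_meta$truth_leaf
  expect_gte(adjusted_rand_index(cl$labels, truth), 0.9)
  # labels contiguous from 0, every cell labeled
  expect_identical(sort(unique(cl$labels)),
                   seq_len(length(unique(cl$labels))) - 1L)
  expect_length(cl$labels, ncol(fx_counts()$counts))
})

test_that("stability scores separate real clusters from forced splits", {
  blob <- make_blob_counts(90, seed = 22)
  nr <- normalize_counts(blob$x)
  emb <- reduce_dims(nr, 5)
  cl <- suppressWarnings(cluster_cells(emb, 15, 0.8, seed = 2))
  st <- cluster_stability(blob$x, cl, 0.8, n_reps = 4, n_components = 5,
                          seed = 3)
  expect_true(all(st$scores >= 0 & st$scores <= 1, na.rm = TRUE))
  expect_true(all(st$summary$median >= 0.95))

  # one homogeneous blob, arbitrarily split in two, reclustered at a
  # resolution that shatters it
  set.seed(4)
  counts <- matrix(rpois(60 * 200, 5), 60,
                   dimnames = list(sprintf("g%02d", 1:60),
                                   sprintf("c%03d", 1:200)))
  fake <- structure(list(labels = stats::setNames(rep(0:1, each = 100),
                                                  colnames(counts)),
                         k_neighbors = 15, resolution = 2, seed = 1),
                    class = "clustering")
  st2 <- cluster_stability(count_matrix(counts), fake, 0.8, n_reps = 4,
                           n_components = 5, seed = 5)
  expect_true(all(st2$summary$median <= 0.6))
})

test_that("stability equals brute-force pair counting", {
  blob <- make_blob_counts(15, seed = 23, strength = 20)
  nr <- normalize_counts(blob$x)
  emb <- reduce_dims(nr, 4)
  cl <- suppressWarnings(cluster_cells(emb, 8, 0.8, seed = 6))
  st <- cluster_stability(blob$x, cl, 0.8, n_reps = 2, n_components = 4,
                          keep_replicates = TRUE, seed = 7)
  for (r in seq_len(2)) {
    rep_info <- st$replicates[[r]]
    orig <- cl$labels[rep_info$cells]
    for (ci in sort(unique(cl$labels))) {
      idx <- which(orig == ci)
      if (length(idx) < 2) next
      co <- 0; tot <- 0
      for (i in seq_along(idx)[-length(idx)])
        for (j in (i + 1):length(idx)) {
          tot <- tot + 1
          co <- co + (rep_info$labels[idx[i]] == rep_info$labels[idx[j]])
        }
      expect_equal(unname(st$scores[as.character(ci), r]), co / tot)
    }
  }
})

test_that("resolution sweep yields a conserved cluster-flow edge table", {
  blob <- make_blob_counts(40, seed = 24, strength = 1)  # one blob really
  nr <- normalize_counts(blob$x)
  emb <- reduce_dims(nr, 4)
  sw <- suppressWarnings(resolution_sweep(emb, c(0.01, 0.05, 0.1), 40, seed = 8))
  expect_true(all(sw$n_clusters == 1))
  expect_equal(nrow(sw$edges), 2)          # a chain

  emb2 <- fx_embedding()
  # subsample cells for speed; hierarchy still present
  sub <- structure(list(scores = emb2$scores[1:1200, ]), class = "embedding")
  sw2 <- suppressWarnings(
    resolution_sweep(sub, seq(0.1, 1.1, by = 0.1), 30, seed = 9))
  for (i in seq_along(sw2$resolutions)[-1]) {
    e <- sw2$edges[sw2$edges$res_to == sw2$resolutions[i], ]
    out <- tapply(e$n_cells, e$cluster_from, sum)
    sizes <- table(sw2$clusterings[[i - 1]])
    expect_equal(as.numeric(out[names(sizes)]), as.numeric(sizes))
  }
  expect_gte(sum(diff(sw2$n_clusters) >= 0), 9)
})
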