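# exact k-nearest neighbours (Euclidean), self included in the k
.knn_index <- function(scores, k, block = 1024L) {
  n <- nrow(scores)
  stopifnot(k <= n)
  sq <- rowSums(scores^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(scores[rows, , drop = FALSE], scores)
    for (r in seq_along(rows))
      idx[rows[r], ] <- order(d2[r, ])[seq_len(k)]
  }
  idx
}

# shared-nearest-neighbour graph: Jaccard overlap of k-NN sets, pruned
.snn_graph <- function(scores, k_neighbors, prune = 1 / 15) {
  n <- nrow(scores)
  k <- min(k_neighbors, n)
  nn <- .knn_index(scores, k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  snn <- shared
  snn@x <- snn@x / (2 * k - snn@x)   # Jaccard: |a&b| / |a|b|
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  Matrix::drop0(snn)
}

#' Graph-based clustering of an embedding
#'
#' Builds the exact k-nearest-neighbour graph in component space, converts
#' it to shared-nearest-neighbour weights (Jaccard overlap of neighbour
#' sets, pruned below 1/15), and runs seeded Louvain modularity community
#' detection at the given resolution.  Singleton communities are merged
#' into the cluster with the nearest centroid.  Labels are contiguous
#' integers from 0, ordered by decreasing cluster size.
#'
#' @param embedding an \code{\link{reduce_dims}} result (or a bare score
#'   matrix, cells x components).
#' @param k_neighbors neighbours per cell (self counts as one).
#' @param resolution Louvain resolution; higher gives more clusters.
#' @param seed integer seed for the community detection.
#' @return list of class \code{clustering}: integer \code{labels} (0-based,
#'   named by cell when the scores carry rownames), \code{k_neighbors},
#'   \code{resolution}, \code{seed}, \code{modularity}.
#' @export
cluster_cells <- function(embedding, k_neighbors = 40, resolution = 0.8,
                          seed = 1L) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else as.matrix(embedding)
  n <- nrow(scores)
  stopifnot(k_neighbors < n)
  snn <- .snn_graph(scores, k_neighbors)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::components(g)$no > 1)
    warning("SNN graph is disconnected; communities found per component")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  com <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(com)
  # merge singletons into the nearest cluster by centroid distance
  sizes <- table(labels)
  if (any(sizes == 1) && length(sizes) > 1) {
    singles <- names(sizes)[sizes == 1]
    keepers <- names(sizes)[sizes > 1]
    if (length(keepers)) {
      cents <- t(vapply(keepers, function(cl)
        colMeans(scores[labels == as.integer(cl), , drop = FALSE]),
        numeric(ncol(scores))))
      for (cl in singles) {
        i <- which(labels == as.integer(cl))
        d2 <- rowSums((cents - matrix(scores[i, ], nrow(cents),
                                      ncol(scores), byrow = TRUE))^2)
        labels[i] <- as.integer(keepers[which.min(d2)])
      }
    }
  }
  # relabel to 0-based contiguous ids by decreasing size
  ord <- names(sort(table(labels), decreasing = TRUE))
  relab <- stats::setNames(seq_along(ord) - 1L, ord)
  labels <- unname(relab[as.character(labels)])
  names(labels) <- rownames(scores)
  structure(list(labels = labels, k_neighbors = k_neighbors,
                 resolution = resolution, seed = seed,
                 modularity = igraph::modularity(g, labels + 1L,
                                                 weights = igraph::E(g)$weight)),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("clustering: %d cells, %d clusters (k=%d, resolution=%g)\n",
              length(x$labels), length(unique(x$labels)),
              x$k_neighbors, x$resolution))
  print(table(x$labels))
  invisible(x)
}

#' Cluster stability under random downsampling and reclustering
#'
#' Repeatedly downsamples cells without replacement, re-runs the
#' normalize / reduce / cluster pipeline with the original parameters, and
#' scores each original cluster by the fraction of its retained
#' within-cluster cell pairs that are still co-clustered in the replicate.
#' Low scores mark clusters whose cells collapse into others when data is
#' removed.
#'
#' @param x the raw \code{\link{count_matrix}} the clustering was built on.
#' @param clustering a \code{\link{cluster_cells}} result on those cells.
#' @param downsample_frac fraction of cells kept per replicate (0 < f < 1).
#' @param n_reps number of replicates (>= 2).
#' @param n_components,target_sum,scale_cap pipeline parameters to re-use.
#' @param exclude_genes genes excluded from the replicate embeddings (same
#'   convention as \code{\link{reduce_dims}}).
#' @param keep_replicates store each replicate's retained cells and labels
#'   (for auditing the pair-counting).
#' @param seed integer seed.
#' @return list of class \code{stability_report}: \code{scores} (clusters x
#'   replicates, NA where a cluster retained < 2 cells) and \code{summary}
#'   (median, quartiles and 1.5 x IQR outlier counts per cluster).
#' @export
cluster_stability <- function(x, clustering, downsample_frac = 0.8,
                              n_reps = 10, n_components = 32,
                              target_sum = 1e4, scale_cap = 10,
                              exclude_genes = NULL, keep_replicates = FALSE,
                              seed = 1L) {
  stopifnot(downsample_frac > 0, downsample_frac < 1, n_reps >= 2)
  labels <- clustering$labels
  n <- ncol(x$counts)
  stopifnot(length(labels) == n)
  clusters <- sort(unique(labels))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scores <- matrix(NA_real_, length(clusters), n_reps,
                   dimnames = list(as.character(clusters), NULL))
  replicates <- if (keep_replicates) vector("list", n_reps) else NULL
  for (rep_i in seq_len(n_reps)) {
    keep <- sort(sample.int(n, floor(downsample_frac * n)))
    sub <- x[, keep]
    nr <- normalize_counts(sub, target_sum, scale_cap)
    emb <- reduce_dims(nr, min(n_components, length(keep) - 1),
                       exclude_genes = exclude_genes)
    k <- min(clustering$k_neighbors, length(keep) - 1)
    cl2 <- suppressWarnings(cluster_cells(emb, k, clustering$resolution,
                                          seed = seed + rep_i))
    new_lab <- cl2$labels
    if (keep_replicates)
      replicates[[rep_i]] <- list(cells = keep, labels = unname(new_lab))
    orig <- labels[keep]
    for (ci in seq_along(clusters)) {
      idx <- which(orig == clusters[ci])
      m <- length(idx)
      if (m < 2) next
      tt <- table(new_lab[idx])
      scores[ci, rep_i] <- sum(choose(tt, 2)) / choose(m, 2)
    }
  }
  summ <- t(apply(scores, 1, function(s) {
    s <- s[!is.na(s)]
    q <- stats::quantile(s, c(.25, .5, .75), names = FALSE)
    iqr <- q[3] - q[1]
    c(q1 = q[1], median = q[2], q3 = q[3],
      n_outliers = sum(s < q[1] - 1.5 * iqr | s > q[3] + 1.5 * iqr))
  }))
  structure(list(scores = scores,
                 summary = data.frame(cluster = as.character(clusters), summ,
                                      row.names = NULL),
                 replicates = replicates,
                 downsample_frac = downsample_frac, n_reps = n_reps,
                 seed = seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: %d clusters x %d replicates (frac=%g)\n",
              nrow(x$scores), x$n_reps, x$downsample_frac))
  print(x$summary)
  invisible(x)
}

#' Cluster evolution across a ladder of resolutions
#'
#' Clusters the same SNN graph at each resolution and records, for each
#' consecutive pair of resolutions, how cells flow from the coarser
#' clusters into the finer ones — the edge table of a cluster tree.
#'
#' @param embedding \code{\link{reduce_dims}} result.
#' @param resolutions ascending numeric vector (e.g. seq(0.1, 1.1, 0.1)).
#' @param k_neighbors,seed as in \code{\link{cluster_cells}}.
#' @return list of class \code{resolution_sweep}: \code{clusterings} (list
#'   of label vectors, one per resolution), \code{n_clusters}, and
#'   \code{edges} (data.frame: res_from, cluster_from, res_to, cluster_to,
#'   n_cells).
#' @export
resolution_sweep <- function(embedding, resolutions = seq(0.1, 1.1, by = 0.1),
                             k_neighbors = 40, seed = 1L) {
  stopifnot(!is.unsorted(resolutions))
  labs <- lapply(resolutions, function(r)
    cluster_cells(embedding, k_neighbors, r, seed)$labels)
  names(labs) <- as.character(resolutions)
  edges <- NULL
  for (i in seq_along(resolutions)[-1]) {
    tt <- table(labs[[i - 1]], labs[[i]])
    df <- as.data.frame(tt, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    edges <- rbind(edges, data.frame(
      res_from = resolutions[i - 1], cluster_from = df$Var1,
      res_to = resolutions[i], cluster_to = df$Var2,
      n_cells = df$Freq, row.names = NULL))
  }
  structure(list(clusterings = labs,
                 n_clusters = vapply(labs, function(l) length(unique(l)), 0L),
                 edges = edges, resolutions = resolutions),
            class = "resolution_sweep")
}

#' Adjusted Rand index between two labelings
#' @param a,b label vectors over the same cells.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tt <- table(a, b)
  n <- length(a)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(tt)
  si <- sum_comb(rowSums(tt))
  sj <- sum_comb(colSums(tt))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
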