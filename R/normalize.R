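#' Depth-normalize, log-transform and z-scale a count matrix
#'
#' Per-cell counts are scaled to \code{target_sum} total (the conventional
#' counts-per-10k), log1p-transformed, and additionally returned as a dense
#' per-gene z-scored matrix with values clipped at \code{± scale_cap} for
#' embedding.  Constant genes get z-scores of exactly 0.  Cells with zero
#' depth are excluded with a warning.
#'
#' @param x a \code{\link{count_matrix}}.
#' @param target_sum per-cell total after depth scaling.
#' @param scale_cap clip value for the z-scored matrix.
#' @return list of class \code{norm_result}: \code{norm} (sparse genes x
#'   cells log-normalized), \code{scaled} (dense genes x cells, clipped
#'   z-scores), \code{target_sum}, \code{scale_cap}, \code{dropped_cells}.
#' @export
normalize_counts <- function(x, target_sum = 1e4, scale_cap = 10) {
  stopifnot(inherits(x, "count_matrix"))
  depth <- Matrix::colSums(x$counts)
  drop <- depth == 0
  if (any(drop)) {
    warning(sprintf("excluding %d zero-depth cell(s)", sum(drop)))
    x <- x[, !drop]
    depth <- depth[!drop]
  }
  norm <- x$counts %*% Matrix::Diagonal(ncol(x$counts), target_sum / depth)
  dimnames(norm) <- dimnames(x$counts)
  norm@x <- log1p(norm@x)
  mu <- Matrix::rowMeans(norm)
  # var over cells, sparse-friendly: E[x^2] - mu^2 with n/(n-1) correction
  n <- ncol(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  sd <- sqrt(pmax(v, 0))
  scaled <- as.matrix(norm - mu %o% rep(1, n))
  nz <- sd > 0
  scaled[nz, ] <- scaled[nz, , drop = FALSE] / sd[nz]
  scaled[!nz, ] <- 0
  scaled[scaled > scale_cap] <- scale_cap
  scaled[scaled < -scale_cap] <- -scale_cap
  structure(list(norm = methods::as(norm, "CsparseMatrix"), scaled = scaled,
                 target_sum = target_sum, scale_cap = scale_cap,
                 dropped_cells = colnames(x$counts)[drop]),
            class = "norm_result")
}

#' Principal-component embedding of a scaled matrix
#'
#' PCA of the z-scaled gene-by-cell matrix (cells as observations).  The
#' component sign is fixed so that each component's largest-magnitude gene
#' loading is positive, making runs reproducible across platforms.
#'
#' @param x a \code{norm_result} (its \code{scaled} slot is used) or a dense
#'   genes x cells matrix.
#' @param n_components number of components (>= 2).
#' @param exclude_genes genes dropped before the decomposition.  Datasets
#'   pooling male and female animals without cross-sample integration
#'   should list the sex-linked genes (Xist, Tsix, Uty, Eif2s3y, ...) here
#'   so that cells embed by subtype rather than by sex; the genes stay in
#'   the normalized matrix for marker statistics.
#' @param seed kept for interface symmetry; the decomposition is exact and
#'   deterministic.
#' @return list of class \code{embedding}: \code{scores} (cells x K),
#'   \code{loadings} (genes x K), \code{sdev}, \code{var_explained}.
#' @export
reduce_dims <- function(x, n_components = 32, exclude_genes = NULL,
                        seed = 1L) {
  m <- if (inherits(x, "norm_result")) x$scaled else as.matrix(x)
  if (!is.null(exclude_genes))
    m <- m[setdiff(rownames(m), exclude_genes), , drop = FALSE]
  stopifnot(n_components >= 2)
  p <- stats::prcomp(t(m), center = TRUE, scale. = FALSE, rank. = n_components)
  tol <- max(dim(m)) * .Machine$double.eps * max(p$sdev)
  rank <- sum(p$sdev > tol)
  if (n_components > rank)
    stop(sprintf("n_components (%d) exceeds matrix rank (%d)",
                 n_components, rank))
  K <- min(n_components, ncol(p$rotation))
  scores <- p$x[, seq_len(K), drop = FALSE]
  loadings <- p$rotation[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 sdev = p$sdev[seq_len(K)],
                 var_explained = p$sdev[seq_len(K)]^2 / sum(p$sdev^2)),
            class = "embedding")
}
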