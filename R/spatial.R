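#' Select panel genes shared consistently between datasets
#'
#' A gene is kept when it is detected in at least \code{min_detection} of
#' cells in both datasets and the ratio of its per-cell mean counts
#' (query / reference) lies within [1/max_ratio, max_ratio].  Genes with
#' zero detection in either dataset (e.g. failed probes) are always
#' excluded.
#'
#' @param reference,query count_matrix objects with overlapping gene
#'   universes.
#' @param max_ratio maximal fold difference of mean counts per cell.
#' @param min_detection minimal detection fraction in each dataset.
#' @return character vector of selected genes.
#' @export
select_shared_features <- function(reference, query, max_ratio = 4,
                                   min_detection = 0.01) {
  genes <- intersect(rownames(reference$counts), rownames(query$counts))
  if (!length(genes)) stop("gene universes do not overlap")
  r <- reference$counts[genes, , drop = FALSE]
  q <- query$counts[genes, , drop = FALSE]
  det_r <- Matrix::rowSums(r > 0) / ncol(r)
  det_q <- Matrix::rowSums(q > 0) / ncol(q)
  mu_r <- Matrix::rowMeans(r)
  mu_q <- Matrix::rowMeans(q)
  ratio <- ifelse(mu_r > 0, mu_q / mu_r, Inf)
  keep <- det_r >= min_detection & det_q >= min_detection &
    det_r > 0 & det_q > 0 &
    ratio >= 1 / max_ratio & ratio <= max_ratio
  out <- genes[keep]
  if (!length(out))
    stop("no shared features pass the filters; relax max_ratio/min_detection")
  out
}

#' Find mutual-nearest-neighbour anchors between reference and query
#'
#' Both datasets are depth-normalized and z-scaled per dataset on the
#' shared genes; the query is projected onto the reference PCA, and
#' mutual nearest neighbours across datasets in that joint space become
#' anchors.  Each anchor is scored by the shared-neighbour overlap of its
#' two member cells: the fraction of the \code{k_score} nearest query
#' cells of the reference member that also neighbour the query member,
#' averaged with the same fraction on the reference side, clipped to
#' [0, 1].  Anchors joining cells embedded in different neighbourhoods
#' (e.g. a query population missing from the reference) score low.
#'
#' @param reference,query count_matrix objects.
#' @param shared_genes genes used for the joint space (>= 30).
#' @param k_anchor neighbours considered when looking for mutual pairs.
#' @param k_score neighbourhood size for anchor scoring.
#' @param n_components PCA dimensionality of the joint space.
#' @param seed integer seed (the decomposition is deterministic; kept for
#'   interface symmetry).
#' @return object of class \code{anchor_set}: \code{pairs} (data.frame
#'   ref, query, score), \code{ref_scores}, \code{query_scores},
#'   \code{ref_ids}, \code{query_ids}.
#' @export
find_anchors <- function(reference, query, shared_genes, k_anchor = 5,
                         k_score = 20, n_components = 20, seed = 1L) {
  if (length(shared_genes) < 30)
    stop("need at least 30 shared genes for a stable joint space")
  rs <- normalize_counts(reference[shared_genes, ])$scaled
  qs <- normalize_counts(query[shared_genes, ])$scaled
  n_components <- min(n_components, length(shared_genes) - 1,
                      ncol(rs) - 1)
  pr <- stats::prcomp(t(rs), center = TRUE, scale. = FALSE,
                      rank. = n_components)
  ref_scores <- pr$x
  query_scores <- scale(t(qs), center = pr$center, scale = FALSE) %*%
    pr$rotation
  # cross k-NN in both directions
  cross_nn <- function(a, b, k) {
    # k nearest rows of b for each row of a
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  k_anchor <- min(k_anchor, nrow(ref_scores), nrow(query_scores))
  r2q <- cross_nn(ref_scores, query_scores, k_anchor)
  q2r <- cross_nn(query_scores, ref_scores, k_anchor)
  e1 <- paste(rep(seq_len(nrow(r2q)), k_anchor), as.vector(r2q))
  e2 <- paste(as.vector(q2r), rep(seq_len(nrow(q2r)), k_anchor))
  mutual <- intersect(e1, e2)
  if (!length(mutual)) stop("no mutual nearest neighbour pairs found")
  idx <- do.call(rbind, strsplit(mutual, " ", fixed = TRUE))
  pairs <- data.frame(ref = as.integer(idx[, 1]), query = as.integer(idx[, 2]))
  pairs <- pairs[order(pairs$ref, pairs$query), , drop = FALSE]
  # score anchors by shared neighbourhoods on each side: the reference
  # member's nearest query cells vs the query member's own query
  # neighbourhood (self included), and symmetrically on the reference side
  ks <- min(k_score, nrow(ref_scores), nrow(query_scores))
  r2q_s <- cross_nn(ref_scores, query_scores, ks)   # ref -> query cells
  q2r_s <- cross_nn(query_scores, ref_scores, ks)   # query -> ref cells
  qq <- .knn_index(query_scores, ks)                # query -> query (self in)
  rr <- .knn_index(ref_scores, ks)                  # ref -> ref (self in)
  pairs$score <- vapply(seq_len(nrow(pairs)), function(i) {
    r <- pairs$ref[i]; q <- pairs$query[i]
    sq <- length(intersect(r2q_s[r, ], qq[q, ])) / ks
    sr <- length(intersect(q2r_s[q, ], rr[r, ])) / ks
    min(1, max(0, (sq + sr) / 2))
  }, numeric(1))
  structure(list(pairs = pairs, ref_scores = ref_scores,
                 query_scores = query_scores,
                 ref_ids = colnames(reference$counts),
                 query_ids = colnames(query$counts),
                 k_anchor = k_anchor, k_score = ks),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set: %d anchors between %d reference and %d query cells (mean score %.3f)\n",
              nrow(x$pairs), length(x$ref_ids), length(x$query_ids),
              mean(x$pairs$score)))
  invisible(x)
}

# per-query-cell weights over anchors: Gaussian kernel on joint-space
# distance to each anchor's query cell (bandwidth = distance to the
# k_weight-th nearest anchor), normalized to sum 1, then multiplied by the
# anchor score ("raw") or renormalized to a convex combination ("convex",
# for imputation); returns a query x n_anchor dense matrix (rows of a
# query cell with no usable anchor are all zero)
.anchor_weights <- function(anchors, k_weight = 10,
                            mode = c("raw", "convex")) {
  mode <- match.arg(mode)
  qpos <- anchors$query_scores
  apos <- anchors$query_scores[anchors$pairs$query, , drop = FALSE]
  nq <- nrow(qpos); na <- nrow(apos)
  k <- min(k_weight, na)
  d2 <- outer(rowSums(qpos^2), rowSums(apos^2), "+") - 2 * tcrossprod(qpos, apos)
  d2[d2 < 0] <- 0
  rpos <- anchors$ref_scores[anchors$pairs$ref, , drop = FALSE]
  W <- matrix(0, nq, na)
  # squared-distance tolerance for exact matches; distances are computed
  # via the expanded form, whose rounding error dominates true zeros
  eps <- 1e-6 * max(1, max(abs(qpos)))
  for (i in seq_len(nq)) {
    ord <- order(d2[i, ])[seq_len(k)]
    if (d2[i, ord[1]] <= eps) {
      # identity anchors — both ends coincide with the query cell in the
      # joint space — take all the weight (the query cell is in the
      # reference); otherwise fall back to all zero-distance anchors
      ord <- ord[d2[i, ord] <= eps]
      dref <- rowSums((rpos[ord, , drop = FALSE] -
                         matrix(qpos[i, ], length(ord), ncol(qpos),
                                byrow = TRUE))^2)
      if (any(dref <= eps)) ord <- ord[dref <= eps]
      w <- rep(1 / length(ord), length(ord)) * anchors$pairs$score[ord]
    } else {
      bw2 <- d2[i, ord[k]]
      w <- exp(-d2[i, ord] / (2 * bw2))
      w <- (w / sum(w)) * anchors$pairs$score[ord]
    }
    if (mode == "convex" && sum(w) > 0) w <- w / sum(w)
    W[i, ord] <- w
  }
  W
}

#' Transfer reference labels onto query cells through anchors
#'
#' Each query cell's label scores are the summed weights of its nearest
#' anchors carrying that reference label: Gaussian-kernel weights
#' normalized to sum 1 per cell, each multiplied by its anchor score.  The
#' prediction is the argmax and the similarity score its weight, so label
#' scores sum to at most 1 — exactly 1 when every contributing anchor has
#' score 1 — and cells in expression territory the reference does not
#' cover (novel populations, poorly anchored regions) receive depressed
#' similarity scores.  Cells whose maximal score does not exceed
#' \code{score_threshold} are flagged low-confidence; cells with no usable
#' anchor get score 0 and label \code{"unassigned"}.
#'
#' @param anchors \code{\link{find_anchors}} result.
#' @param ref_labels labels over the reference cells (anchor order).
#' @param k_weight anchors averaged per query cell.
#' @param score_threshold high-confidence gate on the similarity score.
#' @return object of class \code{transfer_result}: data.frame \code{cells}
#'   (cell_id, predicted, score, high_confidence) and matrix
#'   \code{label_scores} (query x label, rows sum to the cell's total
#'   anchor-score-weighted mass, at most 1).
#' @export
transfer_labels <- function(anchors, ref_labels, k_weight = 10,
                            score_threshold = 0.5) {
  stopifnot(nrow(anchors$pairs) > 0)
  ref_labels <- as.character(ref_labels)
  stopifnot(length(ref_labels) == length(anchors$ref_ids))
  W <- .anchor_weights(anchors, k_weight)
  alab <- ref_labels[anchors$pairs$ref]
  labs <- sort(unique(ref_labels))
  M <- vapply(labs, function(l) rowSums(W[, alab == l, drop = FALSE]),
              numeric(nrow(W)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(NULL, labs))
  rownames(M) <- anchors$query_ids
  score <- apply(M, 1, max)
  predicted <- ifelse(score > 0, labs[apply(M, 1, which.max)], "unassigned")
  structure(list(
    cells = data.frame(cell_id = anchors$query_ids, predicted = predicted,
                       score = score,
                       high_confidence = score > score_threshold,
                       row.names = anchors$query_ids),
    label_scores = M, score_threshold = score_threshold,
    k_weight = k_weight), class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("transfer_result: %d query cells, %d (%.1f%%) high-confidence (score > %g), mean score %.3f\n",
              nrow(x$cells), sum(x$cells$high_confidence),
              100 * mean(x$cells$high_confidence), x$score_threshold,
              mean(x$cells$score)))
  invisible(x)
}

#' Impute reference-transcriptome expression onto query cells
#'
#' Each query cell's imputed profile is the anchor-weighted average of the
#' anchored reference cells' normalized expression, extending the query to
#' genes absent from its panel.
#'
#' @param anchors \code{\link{find_anchors}} result.
#' @param ref_norm log-normalized reference matrix (genes x cells) or
#'   \code{norm_result}; all its genes are imputed.
#' @param k_weight anchors averaged per query cell.
#' @return dense genes x query-cells matrix (all-zero columns for
#'   unanchored cells).
#' @export
impute_expression <- function(anchors, ref_norm, k_weight = 10) {
  if (inherits(ref_norm, "norm_result")) ref_norm <- ref_norm$norm
  stopifnot(ncol(ref_norm) == length(anchors$ref_ids))
  W <- .anchor_weights(anchors, k_weight, mode = "convex")
  ref_prof <- ref_norm[, anchors$pairs$ref, drop = FALSE]
  out <- as.matrix(ref_prof %*% t(W))
  dimnames(out) <- list(rownames(ref_norm), anchors$query_ids)
  out
}

#' Per-gene fidelity of imputed against measured expression
#'
#' Pearson correlation per gene across cells with non-zero values in both
#' the measured and the imputed matrix; genes with fewer than
#' \code{min_cells} such cells are reported NA (probe failures land here).
#'
#' @param imputed genes x cells matrix from \code{\link{impute_expression}}.
#' @param measured measured query matrix on the same cells (count_matrix,
#'   norm_result or matrix).
#' @param genes genes to evaluate (default: genes present in both).
#' @param min_cells minimum number of doubly non-zero cells.
#' @return data.frame: gene, r, n_cells; histogram-ready.
#' @export
imputation_fidelity <- function(imputed, measured, genes = NULL,
                                min_cells = 10) {
  if (inherits(measured, "count_matrix")) measured <- measured$counts
  if (inherits(measured, "norm_result")) measured <- measured$norm
  if (is.null(genes)) genes <- intersect(rownames(imputed), rownames(measured))
  stopifnot(all(genes %in% rownames(imputed)),
            all(genes %in% rownames(measured)))
  cells <- intersect(colnames(imputed), colnames(measured))
  imp <- imputed[genes, cells, drop = FALSE]
  mea <- as.matrix(measured[genes, cells, drop = FALSE])
  out <- data.frame(gene = genes, r = NA_real_, n_cells = 0L,
                    row.names = genes)
  for (g in genes) {
    nz <- which(imp[g, ] != 0 & mea[g, ] != 0)
    out[g, "n_cells"] <- length(nz)
    if (length(nz) >= min_cells &&
        stats::sd(imp[g, nz]) > 0 && stats::sd(mea[g, nz]) > 0)
      out[g, "r"] <- stats::cor(imp[g, nz], mea[g, nz])
  }
  out
}

#' Cluster-correspondence flow table between two labelings
#'
#' Contingency counts of cells flowing from each source cluster to each
#' target cluster, expressed as fractions of the source; flows below
#' \code{min_flow} are dropped (fractions per source sum to 1 before
#' thresholding).
#'
#' @param labels_a,labels_b label vectors over the same cells (named, or
#'   aligned by position).
#' @param min_flow minimum fraction of the source cluster retained.
#' @return data.frame: source, target, n_cells, fraction.
#' @export
correspondence_flows <- function(labels_a, labels_b, min_flow = 0.10) {
  stopifnot(length(labels_a) == length(labels_b))
  tt <- table(source = as.character(labels_a), target = as.character(labels_b))
  df <- as.data.frame(tt, stringsAsFactors = FALSE)
  names(df)[3] <- "n_cells"
  df <- df[df$n_cells > 0, ]
  df$fraction <- df$n_cells / rowSums(tt)[df$source]
  df <- df[df$fraction >= min_flow, ]
  df[order(df$source, -df$fraction), , drop = FALSE]
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd fill rule (polygon winding is ignored);
#' points exactly on an edge or vertex count as inside.
#'
#' @param x,y point coordinates.
#' @param poly 2-column matrix of polygon vertices (open ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  nv <- length(px)
  jx <- px[c(2:nv, 1)]; jy <- py[c(2:nv, 1)]
  eps <- 1e-9
  vapply(seq_along(x), function(i) {
    X <- x[i]; Y <- y[i]
    # boundary: point on any segment counts as inside
    on <- any(
      abs((jx - px) * (Y - py) - (X - px) * (jy - py)) <= eps *
        pmax(1, abs(jx - px) + abs(jy - py)) &
      X >= pmin(px, jx) - eps & X <= pmax(px, jx) + eps &
      Y >= pmin(py, jy) - eps & Y <= pmax(py, jy) + eps)
    if (on) return(TRUE)
    cross <- ((py > Y) != (jy > Y)) &
      (X < px + (jx - px) * (Y - py) / (jy - py))
    sum(cross) %% 2 == 1
  }, logical(1))
}

#' Assign cells to named regions by point-in-polygon
#'
#' The first polygon (in priority order) containing a cell wins; boundary
#' points count as inside; cells in no polygon are labeled
#' \code{"elsewhere"}.
#'
#' @param cells data.frame with \code{x_um}/\code{y_um} columns (e.g.
#'   \code{cell_meta}), or a count_matrix carrying them.
#' @param regions named list of 2-column polygon matrices in priority
#'   order (see \code{\link{read_regions_geojson}}).
#' @return character vector of region labels, named by cell where possible.
#' @export
assign_regions <- function(cells, regions) {
  if (inherits(cells, "count_matrix")) cells <- cells$cell_meta
  if (is.null(cells$x_um) || is.null(cells$y_um))
    stop("cells must carry x_um and y_um coordinates")
  ok <- vapply(regions, function(p)
    is.matrix(p) && ncol(p) == 2 && nrow(p) >= 3, TRUE)
  if (!all(ok))
    stop("malformed polygon(s): ", paste(names(regions)[!ok], collapse = ", "))
  out <- rep("elsewhere", nrow(cells))
  unassigned <- rep(TRUE, nrow(cells))
  for (nm in names(regions)) {
    if (!any(unassigned)) break
    hit <- point_in_polygon(cells$x_um[unassigned], cells$y_um[unassigned],
                            regions[[nm]])
    idx <- which(unassigned)[hit]
    out[idx] <- nm
    unassigned[idx] <- FALSE
  }
  names(out) <- rownames(cells)
  out
}

#' Regional composition tables
#'
#' Cross-tabulates region labels against cluster (or family) labels and
#' returns both normalizations: composition within each region (rows sum
#' to 1) and distribution of each cluster across regions (columns sum to
#' 1).
#'
#' @param region_labels,group_labels label vectors over the same cells.
#' @return list: \code{counts}, \code{by_region}, \code{by_group}.
#' @export
regional_composition <- function(region_labels, group_labels) {
  stopifnot(length(region_labels) == length(group_labels))
  counts <- table(region = as.character(region_labels),
                  group = as.character(group_labels))
  by_region <- sweep(counts, 1, pmax(1, rowSums(counts)), "/")
  by_group <- sweep(counts, 2, pmax(1, colSums(counts)), "/")
  list(counts = counts, by_region = by_region, by_group = by_group)
}
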