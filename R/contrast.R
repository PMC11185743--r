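#' Genotype differential expression within a scope
#'
#' Wilcoxon rank-sum differential expression between two conditions,
#' restricted to a scope (all cells, one family, or one cluster).  Genes
#' are pre-filtered only on detection (>= \code{min_detection} in either
#' condition); no fold-change or detection-difference filter is applied,
#' and BH correction runs across all tested genes.  Summary counts report
#' FDR-significant genes and the up/down subsets with |log2fc| > 0.5.
#'
#' Note the per-cell test treats cells as independent samples, which
#' inflates significance when cells share a library; the result carries a
#' \code{pseudoreplication_warning} field to surface this.
#'
#' @param norm log-normalized matrix (or \code{norm_result}).
#' @param condition per-cell condition labels (exactly 2 levels in scope).
#' @param scope_cells cell ids/indices to restrict to (default all).
#' @param scope_name label recorded in the result.
#' @param min_detection detection filter (fraction, default 0.10).
#' @param alpha FDR level for the summary counts.
#' @return object of class \code{de_result}: \code{table} (MarkerRow
#'   data.frame, condition A = first level vs B), \code{background}
#'   (tested-gene universe), \code{summary}, \code{scope},
#'   \code{pseudoreplication_warning}.
#' @export
condition_de <- function(norm, condition, scope_cells = NULL,
                         scope_name = "all", min_detection = 0.10,
                         alpha = 0.05) {
  if (inherits(norm, "norm_result")) norm <- norm$norm
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(norm))
  if (is.null(scope_cells)) scope_cells <- seq_len(ncol(norm))
  if (is.character(scope_cells))
    scope_cells <- match(scope_cells, colnames(norm))
  cond <- condition[scope_cells]
  levs <- sort(unique(cond))
  if (length(levs) != 2)
    stop(sprintf("scope '%s' must contain exactly 2 conditions, found %d",
                 scope_name, length(levs)))
  a <- scope_cells[cond == levs[1]]
  b <- scope_cells[cond == levs[2]]
  tab <- rank_markers(norm, a, b, min_pct = min_detection,
                      min_diff_pct = 0, logfc_threshold = 0)
  sig <- tab[!is.na(tab$p_adj) & tab$p_adj < alpha, , drop = FALSE]
  summary <- list(
    n_tested = nrow(tab),
    n_significant = nrow(sig),
    n_up_gt_0.5 = sum(sig$log2fc > 0.5),
    n_down_gt_0.5 = sum(sig$log2fc < -0.5))
  structure(list(table = tab, background = tab$gene, scope = scope_name,
                 conditions = levs, alpha = alpha, summary = summary,
                 pseudoreplication_warning = paste(
                   "cells treated as independent samples;",
                   "p-values are optimistic when libraries are shared")),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result [%s]: %s vs %s — %d tested, %d FDR<%g (%d up / %d down with |log2fc|>0.5)\n",
              x$scope, x$conditions[1], x$conditions[2],
              x$summary$n_tested, x$summary$n_significant, x$alpha,
              x$summary$n_up_gt_0.5, x$summary$n_down_gt_0.5))
  invisible(x)
}

#' Overlap of significant genes between two DE results
#'
#' @param result_a,result_b \code{\link{condition_de}} results on the same
#'   contrast (e.g. two families).
#' @param alpha FDR cut for significance.
#' @return list: \code{shared}, \code{only_a}, \code{only_b} gene vectors
#'   and their counts — the numbers behind a two-set Venn diagram.
#' @export
shared_de <- function(result_a, result_b, alpha = 0.05) {
  sa <- result_a$table$gene[result_a$table$p_adj < alpha]
  sb <- result_b$table$gene[result_b$table$p_adj < alpha]
  list(shared = intersect(sa, sb),
       only_a = setdiff(sa, sb), only_b = setdiff(sb, sa),
       n_shared = length(intersect(sa, sb)),
       n_only_a = length(setdiff(sa, sb)),
       n_only_b = length(setdiff(sb, sa)))
}

#' Permutation test for per-cluster proportion shifts between conditions
#'
#' Tests whether any cluster's share of cells differs between two
#' conditions: the observed |proportion difference| per cluster is
#' compared to a null built by permuting the condition labels.
#'
#' @param labels per-cell cluster labels.
#' @param condition per-cell condition labels (2 levels).
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer seed.
#' @return data.frame per cluster: prop_a, prop_b, delta (b - a),
#'   p (permutation, with +1 smoothing), p_adj (BH).
#' @export
proportion_shift <- function(labels, condition, n_perm = 1000, seed = 1L) {
  labels <- as.character(labels); condition <- as.character(condition)
  stopifnot(length(labels) == length(condition))
  levs <- sort(unique(condition))
  stopifnot(length(levs) == 2)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null")
  clusters <- sort(unique(labels))
  prop <- function(cond) {
    pa <- table(factor(labels[cond == levs[1]], clusters)) /
      max(1, sum(cond == levs[1]))
    pb <- table(factor(labels[cond == levs[2]], clusters)) /
      max(1, sum(cond == levs[2]))
    cbind(a = as.numeric(pa), b = as.numeric(pb))
  }
  obs <- prop(condition)
  dobs <- abs(obs[, "b"] - obs[, "a"])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- numeric(length(clusters))
  for (i in seq_len(n_perm)) {
    pp <- prop(sample(condition))
    exceed <- exceed + (abs(pp[, "b"] - pp[, "a"]) >= dobs - 1e-12)
  }
  p <- (1 + exceed) / (n_perm + 1)
  data.frame(cluster = clusters, prop_a = obs[, "a"], prop_b = obs[, "b"],
             delta = obs[, "b"] - obs[, "a"], p = p, p_adj = bh_adjust(p),
             row.names = NULL)
}

#' Variable genes for cross-dataset similarity, binned by expression
#'
#' Per dataset, genes are split into \code{n_bins} equal-frequency bins by
#' mean expression; within every bin except the top one, genes whose
#' variance-to-mean dispersion exceeds the bin median are called variable.
#' The intersection of the per-dataset variable sets is returned.
#'
#' @param matrices list of count_matrix (or normalized matrices) sharing a
#'   gene universe.
#' @param n_bins number of expression bins (default 10 = deciles).
#' @param min_genes warn when fewer genes are selected.
#' @return character vector of genes.
#' @export
select_similarity_genes <- function(matrices, n_bins = 10, min_genes = 50) {
  pick <- function(m) {
    if (inherits(m, "count_matrix")) m <- m$counts
    if (inherits(m, "norm_result")) m <- m$norm
    mu <- Matrix::rowMeans(m)
    n <- ncol(m)
    v <- (Matrix::rowMeans(m^2) - mu^2) * n / max(1, n - 1)
    disp <- ifelse(mu > 0, v / mu, 0)
    bin <- .equal_freq_bin(mu, n_bins)
    sel <- logical(length(mu))
    for (b in seq_len(max(bin))) {
      if (b == max(bin)) next             # top expression bin excluded
      idx <- which(bin == b)
      if (!length(idx)) next
      sel[idx] <- disp[idx] > stats::median(disp[idx])
    }
    rownames(m)[sel]
  }
  sets <- lapply(matrices, pick)
  out <- Reduce(intersect, sets)
  if (length(out) < min_genes)
    warning(sprintf("only %d similarity genes selected", length(out)))
  out
}

# equal-frequency binning by rank; ties share the bin of their mean rank
.equal_freq_bin <- function(x, n_bins) {
  n_bins <- max(1L, min(n_bins, length(unique(x))))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / (length(x) / n_bins)))
}

# AUROC of score discriminating pos (TRUE) from neg cells
.auroc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Neighbour-voting cluster similarity across two datasets
#'
#' For every cluster pair (a in A, b in B): each B cell's vote for cluster
#' a is its mean Spearman correlation (over the selected genes) to a's
#' cells; the entry is the AUROC with which those votes rank b's cells
#' above other B cells.  A diagonal of high AUROCs indicates matched
#' subtype structure across conditions.
#'
#' @param norm_a,norm_b log-normalized matrices (or norm_result) for the
#'   two datasets.
#' @param labels_a,labels_b per-cell cluster labels.
#' @param genes gene set used for the correlations (e.g.
#'   \code{\link{select_similarity_genes}}).
#' @return object of class \code{similarity_matrix}: \code{auroc}
#'   (clusters_B x clusters_A, NA for size-1 clusters), \code{genes}.
#' @export
cluster_similarity <- function(norm_a, labels_a, norm_b, labels_b, genes) {
  if (inherits(norm_a, "norm_result")) norm_a <- norm_a$norm
  if (inherits(norm_b, "norm_result")) norm_b <- norm_b$norm
  stopifnot(all(genes %in% rownames(norm_a)), all(genes %in% rownames(norm_b)))
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  A <- as.matrix(norm_a[genes, , drop = FALSE])
  B <- as.matrix(norm_b[genes, , drop = FALSE])
  cc <- stats::cor(A, B, method = "spearman")   # cellsA x cellsB
  cls_a <- sort(unique(labels_a)); cls_b <- sort(unique(labels_b))
  out <- matrix(NA_real_, length(cls_b), length(cls_a),
                dimnames = list(cls_b, cls_a))
  for (a in cls_a) {
    ia <- labels_a == a
    if (sum(ia) < 2) next
    votes <- colMeans(cc[ia, , drop = FALSE])
    for (b in cls_b) {
      ib <- labels_b == b
      if (sum(ib) < 2) next
      out[b, a] <- .auroc(votes, ib)
    }
  }
  structure(list(auroc = out, genes = genes), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d x %d clusters, %d genes\n",
              nrow(x$auroc), ncol(x$auroc), length(x$genes)))
  print(round(x$auroc, 3))
  invisible(x)
}
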