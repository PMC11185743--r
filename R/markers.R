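# two-sided Wilcoxon rank-sum p with normal approximation, tie correction
# and continuity correction, on a numeric vector split into two groups
.wilcox_p <- function(xa, xb) {
  na <- length(xa); nb <- length(xb); n <- na + nb
  r <- rank(c(xa, xb))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(r)
  sig2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#' @param p vector of p-values
#' @return adjusted p-values (monotone step-up FDR)
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Wilcoxon marker statistics between two cell groups
#'
#' For every gene: detection fractions \code{pct1}/\code{pct2} in the two
#' groups; fold change \code{log2fc = log2((mean(expm1 x_A) + 1) /
#' (mean(expm1 x_B) + 1))} on the log-normalized scale (pseudocount 1); a
#' gene is tested only if \code{max(pct1, pct2) >= min_pct},
#' \code{|pct1 - pct2| >= min_diff_pct} and \code{|log2fc| >=
#' logfc_threshold}.  Tested genes get a two-sided Wilcoxon rank-sum p
#' (normal approximation with tie and continuity correction) and a BH
#' adjustment across tested genes.  Rows are sorted by decreasing
#' \code{|log2fc|}, then p, then gene name — the ordering is fully
#' deterministic (no manual curation step).
#'
#' @param norm log-normalized genes x cells matrix (the \code{norm} slot of
#'   \code{\link{normalize_counts}}), or a \code{norm_result}.
#' @param cells_a,cells_b non-empty, disjoint cell id or index vectors.
#' @param min_pct minimum detection fraction in the better-detected group.
#' @param min_diff_pct minimum detection-fraction difference.
#' @param logfc_threshold minimum absolute log2 fold change.
#' @return data.frame: gene, log2fc, pct1, pct2, p, p_adj (possibly empty).
#' @export
rank_markers <- function(norm, cells_a, cells_b, min_pct = 0.2,
                         min_diff_pct = 0.25, logfc_threshold = 1) {
  if (inherits(norm, "norm_result")) norm <- norm$norm
  a <- norm[, cells_a, drop = FALSE]
  b <- norm[, cells_b, drop = FALSE]
  stopifnot(ncol(a) > 0, ncol(b) > 0)
  pct1 <- Matrix::rowSums(a > 0) / ncol(a)
  pct2 <- Matrix::rowSums(b > 0) / ncol(b)
  log2fc <- log2((Matrix::rowMeans(expm1_sparse(a)) + 1) /
                 (Matrix::rowMeans(expm1_sparse(b)) + 1))
  tested <- pmax(pct1, pct2) >= min_pct &
    abs(pct1 - pct2) >= min_diff_pct &
    abs(log2fc) >= logfc_threshold
  if (!any(tested))
    return(data.frame(gene = character(0), log2fc = numeric(0),
                      pct1 = numeric(0), pct2 = numeric(0),
                      p = numeric(0), p_adj = numeric(0)))
  genes <- rownames(norm)[tested]
  da <- as.matrix(a[tested, , drop = FALSE])
  db <- as.matrix(b[tested, , drop = FALSE])
  p <- vapply(seq_along(genes), function(i) .wilcox_p(da[i, ], db[i, ]),
              numeric(1))
  out <- data.frame(gene = genes, log2fc = log2fc[tested],
                    pct1 = pct1[tested], pct2 = pct2[tested],
                    p = p, p_adj = bh_adjust(p), row.names = NULL)
  out[order(-abs(out$log2fc), out$p, out$gene), , drop = FALSE]
}

# expm1 on the nonzeros of a sparse (or dense) matrix
expm1_sparse <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- expm1(m@x)
    m
  } else expm1(m)
}
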