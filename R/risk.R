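#' Load a GWAS gene z-score table as a weighted risk gene set
#'
#' Reads a (gene, z) table, optionally maps human symbols to mouse
#' orthologs (a human gene mapping to several mouse genes passes its z to
#' each), and intersects with the genes present in the expression matrix.
#'
#' @param z_table data.frame with columns \code{gene}, \code{z}, or a path
#'   to a TSV with those columns.
#' @param matrix_genes gene universe of the expression matrix.
#' @param ortholog_map optional data.frame (or TSV path) with columns
#'   \code{human}, \code{mouse}.
#' @param min_overlap minimal number of mapped genes required (default 25).
#' @return object of class \code{risk_gene_set}: named numeric \code{z}
#'   over matrix genes, \code{unmapped} (symbols lost in mapping or
#'   intersection), \code{ortholog_mapped} flag.
#' @export
load_risk_genes <- function(z_table, matrix_genes, ortholog_map = NULL,
                            min_overlap = 25) {
  if (is.character(z_table) && length(z_table) == 1)
    z_table <- utils::read.delim(z_table, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "z") %in% names(z_table)),
            all(is.finite(z_table$z)))
  genes <- z_table$gene; z <- z_table$z
  mapped <- !is.null(ortholog_map)
  if (mapped) {
    if (is.character(ortholog_map) && length(ortholog_map) == 1)
      ortholog_map <- utils::read.delim(ortholog_map, stringsAsFactors = FALSE)
    stopifnot(all(c("human", "mouse") %in% names(ortholog_map)))
    hit <- merge(data.frame(human = genes, z = z), ortholog_map, by = "human")
    unmapped <- setdiff(genes, hit$human)
    genes <- hit$mouse; z <- hit$z
  } else unmapped <- character(0)
  keep <- genes %in% matrix_genes
  unmapped <- c(unmapped, setdiff(genes[!keep], matrix_genes))
  genes <- genes[keep]; z <- z[keep]
  z <- c(tapply(z, genes, max))  # collapse duplicates to the strongest signal
  if (length(z) < min_overlap)
    stop(sprintf("only %d risk genes overlap the matrix (min_overlap = %d)",
                 length(z), min_overlap))
  structure(list(z = z, unmapped = unique(unmapped),
                 ortholog_mapped = mapped),
            class = "risk_gene_set")
}

#' Bin genes by expression mean, then by variance within each mean bin
#'
#' Equal-frequency binning on gene means of the log-normalized matrix;
#' within each mean bin, equal-frequency binning on gene variances.  The
#' (mean, variance) bin of a gene defines the pool its matched control
#' genes are drawn from.
#'
#' @param norm log-normalized matrix (or norm_result).
#' @param n_mean_bin,n_var_bin bin counts (defaults 20 x 20); collapsed
#'   with a warning when there are fewer genes than bins.
#' @return data.frame per gene: mean, var, mean_bin, var_bin, bin
#'   (combined id).
#' @export
bin_genes <- function(norm, n_mean_bin = 20, n_var_bin = 20) {
  if (inherits(norm, "norm_result")) norm <- norm$norm
  mu <- Matrix::rowMeans(norm)
  n <- ncol(norm)
  v <- (Matrix::rowMeans(norm^2) - mu^2) * n / max(1, n - 1)
  if (length(mu) < n_mean_bin * n_var_bin)
    warning("fewer genes than bins; bins collapsed")
  mean_bin <- .equal_freq_bin(mu, n_mean_bin)
  var_bin <- integer(length(mu))
  for (b in unique(mean_bin)) {
    idx <- which(mean_bin == b)
    var_bin[idx] <- .equal_freq_bin(v[idx], min(n_var_bin, length(idx)))
  }
  data.frame(gene = rownames(norm), mean = mu, var = v,
             mean_bin = mean_bin, var_bin = var_bin,
             bin = paste(mean_bin, var_bin, sep = "."),
             row.names = rownames(norm))
}

#' Cell-level polygenic disease-relevance scores
#'
#' Each risk gene gets weight \code{w = z / (sd + eps)} (inverse-variance
#' "vs" weighting, eps = 0.05); the raw cell score is the w-weighted
#' average of the gene's normalized expression, \code{sum(w x) /
#' sum(|w|)}.  Each of \code{n_ctrl} control sets replaces every risk gene
#' by a uniformly drawn gene from the same (mean, variance) bin, which
#' inherits its z.  Every score vector — the risk score and each control
#' score — is first standardized across cells (mean 0, SD 1), which
#' removes the gene-set-level offset that would otherwise shift all cells
#' of a replicate together; the normalized score is then the standardized
#' raw score re-standardized by the per-cell control mean and SD.  A
#' per-cell Monte-Carlo p-value \code{(1 + #\{ctrl >= raw\}) /
#' (n_ctrl + 1)} is also emitted.
#'
#' @param norm log-normalized matrix (or norm_result).
#' @param risk \code{\link{load_risk_genes}} result (or named z vector).
#' @param bins \code{\link{bin_genes}} on the same matrix.
#' @param n_ctrl number of matched control sets.
#' @param eps variance-weight regularizer.
#' @param seed integer seed.
#' @return object of class \code{risk_scores}: data.frame \code{cells}
#'   (cell_id, raw, norm, p_mc), \code{params}, \code{null_flag} (TRUE
#'   when the risk set carried no signal and normalized scores were forced
#'   to 0).
#' @export
score_cells <- function(norm, risk, bins, n_ctrl = 1000, eps = 0.05,
                        seed = 1L) {
  if (inherits(norm, "norm_result")) norm <- norm$norm
  z <- if (inherits(risk, "risk_gene_set")) risk$z else risk
  stopifnot(all(names(z) %in% rownames(norm)))
  genes <- rownames(norm)
  sd_g <- sqrt(pmax(bins[genes, "var"], 0))
  names(sd_g) <- genes
  X <- as.matrix(norm)
  weight_for <- function(gs, zz) zz / (sd_g[gs] + eps)
  raw_score <- function(gs, zz) {
    w <- weight_for(gs, zz)
    if (sum(abs(w)) == 0) return(rep(0, ncol(X)))
    as.numeric(crossprod(X[gs, , drop = FALSE], w)) / sum(abs(w))
  }
  rg <- names(z)
  raw <- raw_score(rg, unname(z))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # pool of candidate genes per (mean, var) bin
  pool <- split(bins$gene, bins$bin)
  bin_of <- stats::setNames(bins$bin, bins$gene)
  # pre-resolve each risk gene's pool; empty pools fall back to the
  # nearest mean bin (same var bin where possible)
  gene_pool <- lapply(rg, function(g) {
    p <- pool[[bin_of[[g]]]]
    if (length(p)) p else bins$gene[bins$mean_bin == bins[g, "mean_bin"]]
  })
  ctrl <- matrix(0, ncol(X), n_ctrl)
  for (j in seq_len(n_ctrl)) {
    cg <- vapply(gene_pool, function(p) p[sample.int(length(p), 1L)], "")
    ctrl[, j] <- raw_score(cg, unname(z))
  }
  std <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(v - mean(v))
    (v - mean(v)) / s
  }
  raw_std <- std(raw)
  ctrl <- apply(ctrl, 2, std)
  mu_c <- rowMeans(ctrl)
  sd_c <- apply(ctrl, 1, stats::sd)
  null_flag <- all(z == 0) || all(sd_c == 0)
  nrm <- ifelse(sd_c > 0, (raw_std - mu_c) / sd_c, 0)
  if (null_flag) nrm <- rep(0, length(raw))
  p_mc <- (1 + rowSums(ctrl >= raw_std)) / (n_ctrl + 1)
  structure(list(
    cells = data.frame(cell_id = colnames(norm), raw = raw, norm = nrm,
                       p_mc = p_mc, row.names = colnames(norm)),
    params = list(n_ctrl = n_ctrl, eps = eps, weighting = "vs",
                  n_mean_bin = max(bins$mean_bin),
                  n_var_bin = max(bins$var_bin), seed = seed),
    null_flag = null_flag), class = "risk_scores")
}

#' @export
print.risk_scores <- function(x, ...) {
  cat(sprintf("risk_scores: %d cells, mean normalized score %.3f (n_ctrl=%d)\n",
              nrow(x$cells), mean(x$cells$norm), x$params$n_ctrl))
  invisible(x)
}

#' Bootstrap group-level means and confidence intervals of risk scores
#'
#' Per group (cluster or family), cells are resampled with replacement
#' \code{n_boot} times; the CI is the (alpha/2, 1 - alpha/2) percentile
#' interval of the resampled means, and a group is significant iff the CI
#' excludes 0 (the null of no association).
#'
#' @param scores per-cell normalized scores (numeric vector, or a
#'   \code{risk_scores} object).
#' @param groups per-cell group labels.
#' @param n_boot bootstrap resamples (default 10000).
#' @param alpha two-sided level (default 0.05 for a 95 percent CI).
#' @param seed integer seed.
#' @return data.frame per group: n, mean, ci_lo, ci_hi, significant
#'   (NA row with a warning for single-cell groups).
#' @export
group_bootstrap <- function(scores, groups, n_boot = 10000, alpha = 0.05,
                            seed = 1L) {
  if (inherits(scores, "risk_scores")) scores <- scores$cells$norm
  groups <- as.character(groups)
  stopifnot(length(scores) == length(groups))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(sort(unique(groups)), function(g) {
    s <- scores[groups == g]
    n <- length(s)
    if (n < 2) {
      warning(sprintf("group '%s' has a single cell; CI undefined", g))
      return(data.frame(group = g, n = n, mean = mean(s), ci_lo = NA_real_,
                        ci_hi = NA_real_, significant = NA))
    }
    bm <- colMeans(matrix(s[sample.int(n, n * n_boot, replace = TRUE)],
                          nrow = n))
    ci <- stats::quantile(bm, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    data.frame(group = g, n = n, mean = mean(s), ci_lo = ci[1],
               ci_hi = ci[2], significant = ci[1] > 0 | ci[2] < 0)
  })
  do.call(rbind, rows)
}
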