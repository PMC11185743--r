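#' Per-cell quality-control metrics
#'
#' Computes total UMIs, detected genes, and the fractions of counts coming
#' from mitochondrial and ribosomal genes (flagged in \code{gene_meta}).
#' Fractions are on the [0, 1] scale; filter windows written on the
#' conventional percent scale should be divided by 100 first (see
#' \code{\link{qc_window}}).
#'
#' @param x a \code{\link{count_matrix}} whose \code{gene_meta} carries
#'   \code{is_mito} / \code{is_ribo} flags.
#' @return data.frame with one row per cell: \code{cell_id}, \code{sample},
#'   \code{n_counts}, \code{n_features}, \code{pct_mito}, \code{pct_ribo},
#'   \code{volume_um3} (NA when absent) and \code{all_zero}.
#' @export
compute_qc <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  cnt <- x$counts
  n_counts <- Matrix::colSums(cnt)
  n_features <- Matrix::colSums(cnt > 0)
  mito <- Matrix::colSums(cnt[x$gene_meta$is_mito, , drop = FALSE])
  ribo <- Matrix::colSums(cnt[x$gene_meta$is_ribo, , drop = FALSE])
  denom <- ifelse(n_counts == 0, 1, n_counts)
  smp <- if (!is.null(x$cell_meta$sample)) x$cell_meta$sample else "all"
  vol <- if (!is.null(x$cell_meta$volume_um3)) x$cell_meta$volume_um3 else NA_real_
  data.frame(cell_id = colnames(cnt), sample = smp,
             n_counts = as.numeric(n_counts),
             n_features = as.numeric(n_features),
             pct_mito = mito / denom, pct_ribo = ribo / denom,
             volume_um3 = vol,
             all_zero = n_counts == 0,
             row.names = colnames(cnt))
}

#' Define a per-sample QC filter window
#'
#' Bounds are open intervals: a cell survives only if each present metric is
#' strictly inside its bounds, matching the strict inequalities conventional
#' in per-sample subset filters (e.g. features > 1200 and < 7800).  Any
#' bound may be omitted.
#'
#' @param applies_to sample id this window governs, or \code{"all"}.
#' @param min_counts,max_counts open bounds on total UMIs.
#' @param min_features,max_features open bounds on detected genes.
#' @param max_pct_mito,max_pct_ribo open upper bounds on the mito/ribo count
#'   fractions, on the [0,1] fraction scale (a Seurat-style
#'   \code{percent.mt < 0.5} reads as 0.5 percent, i.e. 0.005 here).
#' @return a \code{qc_window} list.
#' @export
qc_window <- function(applies_to = "all",
                      min_counts = NULL, max_counts = NULL,
                      min_features = NULL, max_features = NULL,
                      max_pct_mito = NULL, max_pct_ribo = NULL) {
  w <- list(applies_to = applies_to,
            min_counts = min_counts, max_counts = max_counts,
            min_features = min_features, max_features = max_features,
            max_pct_mito = max_pct_mito, max_pct_ribo = max_pct_ribo)
  chk <- function(lo, hi, what)
    if (!is.null(lo) && !is.null(hi) && lo >= hi)
      stop(sprintf("window %s: min must be < max", what))
  chk(min_counts, max_counts, "counts")
  chk(min_features, max_features, "features")
  structure(w, class = "qc_window")
}

#' Filter cells by per-sample QC windows
#'
#' @param qc a table from \code{\link{compute_qc}}.
#' @param windows list of \code{\link{qc_window}}s.  Each cell must be
#'   governed by exactly one window (its sample's, or an \code{"all"}
#'   window).
#' @return character vector of kept cell ids.
#' @export
filter_cells <- function(qc, windows) {
  if (inherits(windows, "qc_window")) windows <- list(windows)
  targets <- vapply(windows, `[[`, "", "applies_to")
  unknown <- setdiff(targets, c("all", unique(qc$sample)))
  if (length(unknown))
    stop("window references unknown sample(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(qc))
  for (w in windows) {
    in_scope <- if (w$applies_to == "all") rep(TRUE, nrow(qc))
                else qc$sample == w$applies_to
    ok <- rep(TRUE, nrow(qc))
    gt <- function(v, b) if (is.null(b)) TRUE else v > b
    lt <- function(v, b) if (is.null(b)) TRUE else v < b
    ok <- ok & gt(qc$n_counts, w$min_counts) & lt(qc$n_counts, w$max_counts)
    ok <- ok & gt(qc$n_features, w$min_features) & lt(qc$n_features, w$max_features)
    ok <- ok & lt(qc$pct_mito, w$max_pct_mito) & lt(qc$pct_ribo, w$max_pct_ribo)
    keep <- keep & (!in_scope | ok)
  }
  qc$cell_id[keep]
}

#' Filter spatial cells on segmentation volume and transcript count
#'
#' Keeps cells with volume inside [min_volume, max_volume] (cells outside
#' reflect poor segmentation) and at least \code{min_transcripts} total
#' transcripts.  Defaults follow the conventional MERFISH windows of
#' 500-4000 um^3 and >= 40 transcripts.
#'
#' @param qc table from \code{\link{compute_qc}}; \code{volume_um3} must be
#'   present for every cell.
#' @param min_volume,max_volume inclusive volume bounds in um^3.
#' @param min_transcripts minimum total transcripts (inclusive).
#' @return character vector of kept cell ids.
#' @export
filter_spatial_cells <- function(qc, min_volume = 500, max_volume = 4000,
                                 min_transcripts = 40) {
  bad <- qc$cell_id[is.na(qc$volume_um3)]
  if (length(bad))
    stop("cells missing volume: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  keep <- qc$volume_um3 >= min_volume & qc$volume_um3 <= max_volume &
    qc$n_counts >= min_transcripts
  qc$cell_id[keep]
}

#' Infer cell sex from sex-linked gene ratios
#'
#' Scores each cell as log2((male_counts + 1) / (female_counts + 1)) over
#' configured male-specific (e.g. Uty, Eif2s3y) and female-specific (e.g.
#' Xist, Tsix) gene lists, and calls male when the score is >= +tau, female
#' when <= -tau, otherwise indeterminate (cells with technical drop-out of
#' both sets fall here, the middle peak of the usual three-peak histogram).
#'
#' @param x count_matrix.
#' @param male_genes,female_genes non-empty gene lists present in \code{x}.
#' @param tau call threshold on the log2 ratio (default 1 = 2-fold).
#' @return data.frame per cell: \code{male_counts}, \code{female_counts},
#'   \code{ratio_score}, \code{call}; plus a \code{"calls"} attribute with
#'   the per-call cell counts.
#' @export
infer_sex <- function(x, male_genes, female_genes, tau = 1) {
  stopifnot(length(male_genes) > 0, length(female_genes) > 0)
  missing <- setdiff(c(male_genes, female_genes), rownames(x$counts))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  m <- Matrix::colSums(x$counts[male_genes, , drop = FALSE])
  f <- Matrix::colSums(x$counts[female_genes, , drop = FALSE])
  score <- log2((m + 1) / (f + 1))
  call <- ifelse(score >= tau, "male", ifelse(score <= -tau, "female",
                                              "indeterminate"))
  out <- data.frame(cell_id = colnames(x$counts),
                    male_counts = as.numeric(m), female_counts = as.numeric(f),
                    ratio_score = score, call = call,
                    row.names = colnames(x$counts))
  attr(out, "calls") <- table(factor(call, c("male", "female", "indeterminate")))
  out
}

#' Flag clusters of likely neuron-glia doublets
#'
#' A cluster is flagged when, for any of the given glial marker genes (e.g.
#' Mbp, Atp1a2), the fraction of member cells detecting the gene exceeds
#' \code{frac_expressing}.  Flagged clusters should be dropped before
#' dendrogram construction.
#'
#' @param x count_matrix.
#' @param labels per-cell cluster labels covering all cells.
#' @param marker_genes glial marker genes (absent genes count as undetected).
#' @param frac_expressing detection-fraction threshold.
#' @return character vector of flagged cluster ids.
#' @export
flag_doublet_clusters <- function(x, labels, marker_genes,
                                  frac_expressing = 0.5) {
  stopifnot(length(labels) == ncol(x$counts))
  labels <- as.character(labels)
  if (any(table(labels) == 0)) stop("empty cluster")
  present <- intersect(marker_genes, rownames(x$counts))
  if (!length(present)) return(character(0))
  det <- x$counts[present, , drop = FALSE] > 0
  flagged <- character(0)
  for (cl in unique(labels)) {
    idx <- labels == cl
    frac <- Matrix::rowSums(det[, idx, drop = FALSE]) / sum(idx)
    if (any(frac > frac_expressing)) flagged <- c(flagged, cl)
  }
  sort(flagged)
}
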