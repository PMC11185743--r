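#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then genes.  Symbols are
#' uppercased for matching.
#'
#' @param path GMT file.
#' @return named list of uppercase gene vectors, with a
#'   \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) toupper(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (any(!lengths(sets))) stop("GMT contains empty set(s)")
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of gene vectors.
#' @param path output file.
#' @param descriptions optional vector of set descriptions.
#' @return path, invisibly
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), ""),
    path)
  invisible(path)
}

# weighted Kolmogorov-Smirnov enrichment score (weight exponent 1):
# hits step up proportionally to |score|, misses step down uniformly;
# ES is the maximum-magnitude running-sum deviation
.gsea_es <- function(ranked_scores, hit_idx) {
  n <- length(ranked_scores)
  k <- length(hit_idx)
  if (k == 0 || k == n) return(0)
  inc <- abs(ranked_scores[hit_idx])
  if (sum(inc) == 0) inc <- rep(1, k)
  run <- numeric(n)
  steps <- rep(-1 / (n - k), n)
  steps[hit_idx] <- inc / sum(inc)
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment on a ranked gene
#' list: hit increments are proportional to |score| (weight exponent 1),
#' miss decrements are uniform.  The null for each set is built from
#' \code{n_perm} random gene sets of the same size; p is the two-sided
#' tail frequency with +1 smoothing, and NES divides ES by the mean |null
#' ES| of matching sign.  BH correction runs across all scored sets.
#'
#' @param ranked named numeric vector gene -> ranking score (unique genes,
#'   finite scores); matching is case-insensitive.
#' @param sets named list of gene vectors (e.g. \code{\link{read_gmt}}).
#' @param min_size,max_size set-size window after intersection with the
#'   ranking (defaults 25 / 500).
#' @param n_perm random gene sets per tested set.
#' @param seed integer seed.
#' @return data.frame: set, size, ES, NES, p, p_adj, plus a
#'   \code{"skipped"} attribute naming out-of-size sets.
#' @export
preranked_gsea <- function(ranked, sets, min_size = 25, max_size = 500,
                           n_perm = 1000, seed = 1L) {
  stopifnot(!anyDuplicated(names(ranked)), all(is.finite(ranked)))
  names(ranked) <- toupper(names(ranked))
  ord <- order(ranked, decreasing = TRUE)
  rs <- ranked[ord]
  universe <- names(rs)
  n <- length(rs)
  sizes <- vapply(sets, function(s) length(intersect(toupper(s), universe)), 0L)
  ok <- sizes >= min_size & sizes <= max_size
  skipped <- names(sets)[!ok]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(names(sets)[ok], function(nm) {
    hit <- which(universe %in% toupper(sets[[nm]]))
    es <- .gsea_es(rs, hit)
    k <- length(hit)
    null_es <- vapply(seq_len(n_perm), function(i)
      .gsea_es(rs, sort(sample.int(n, k))), numeric(1))
    p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
    same_sign <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else 0
    data.frame(set = nm, size = k, ES = es, NES = nes, p = p,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0))
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, -abs(out$NES)), , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

#' Hypergeometric over-representation with a custom background
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and
#' each gene set, against a caller-supplied expression background (e.g.
#' the >= 10 percent detection universe of the contrast that produced the
#' hits) so that results are not driven by cell-type-specific expression.
#'
#' @param hits gene list (must be contained in \code{background}).
#' @param background gene universe the hits were drawn from.
#' @param sets named list of gene vectors; matching is case-insensitive.
#' @return data.frame: set, overlap, set_in_background, n_hits,
#'   n_background, p, p_adj.
#' @export
overrepresentation <- function(hits, background, sets) {
  hits <- toupper(hits); background <- unique(toupper(background))
  out_of_bg <- setdiff(hits, background)
  if (length(out_of_bg))
    stop("hits outside the background: ",
         paste(utils::head(out_of_bg, 5), collapse = ", "))
  hits <- unique(hits)
  N <- length(background); n <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    K <- length(intersect(toupper(sets[[nm]]), background))
    k <- length(intersect(toupper(sets[[nm]]), hits))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_in_background = K,
               n_hits = n, n_background = N, p = p, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Read a synaptic-annotation table
#'
#' TSV with columns \code{gene}, \code{compartment}, \code{function}
#' (multiple rows per gene allowed).  Any compartment or function
#' annotation implies the gene is synaptic.
#'
#' @param path TSV file.
#' @return data.frame with uppercase \code{gene}.
#' @export
read_synaptic_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("gene", "compartment") %in% names(df)))
  if (is.null(df[["function."]]) && is.null(df[["function"]]))
    df[["function"]] <- NA_character_
  if (!is.null(df[["function."]])) names(df)[names(df) == "function."] <- "function"
  df$gene <- toupper(df$gene)
  df
}

#' Synaptic compartment and function fractions of a DEG list
#'
#' Reports the fraction of DEGs with any synaptic annotation; among those,
#' the fraction per compartment (presynaptic, postsynaptic, active zone,
#' ...) and per function class, with raw counts ("20/77"-style) alongside.
#'
#' @param degs gene list (case-insensitive).
#' @param annotation data.frame as from
#'   \code{\link{read_synaptic_annotation}}, or an ortholog-mapped one.
#' @return list: \code{n_degs}, \code{n_synaptic}, \code{frac_synaptic},
#'   \code{compartments} and \code{functions} (data.frames with count,
#'   frac_of_synaptic, frac_of_degs, label).
#' @export
synaptic_fractions <- function(degs, annotation) {
  degs <- unique(toupper(degs))
  if (!length(degs))
    return(list(n_degs = 0L, n_synaptic = 0L, frac_synaptic = NA_real_,
                compartments = NULL, functions = NULL))
  ann <- annotation[annotation$gene %in% degs, , drop = FALSE]
  syn_genes <- unique(ann$gene)
  tab <- function(col) {
    vals <- ann[[col]]
    keep <- !is.na(vals) & nzchar(vals)
    if (!any(keep)) return(NULL)
    counts <- vapply(split(ann$gene[keep], vals[keep]),
                     function(g) length(unique(g)), 0L)
    data.frame(class = names(counts), count = as.integer(counts),
               frac_of_synaptic = as.numeric(counts) / length(syn_genes),
               frac_of_degs = as.numeric(counts) / length(degs),
               label = sprintf("%d/%d", counts, length(syn_genes)),
               row.names = NULL)
  }
  list(n_degs = length(degs), n_synaptic = length(syn_genes),
       frac_synaptic = length(syn_genes) / length(degs),
       compartments = tab("compartment"),
       functions = tab("function"))
}
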