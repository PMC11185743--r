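#' Build the cluster dendrogram (taxonomy topology)
#'
#' Cluster centroids are computed in component space and joined by
#' agglomerative hierarchical clustering (average linkage on Euclidean
#' centroid distances), giving a rooted binary tree over clusters — the
#' scaffold on which node markers and stepwise codes are derived.
#'
#' @param embedding \code{\link{reduce_dims}} result over the same cells.
#' @param clustering \code{\link{cluster_cells}} result (>= 2 clusters).
#' @return object of class \code{taxonomy_tree}: \code{hc} (hclust),
#'   \code{leaves} (cluster ids as character), \code{nodes} (list of
#'   internal nodes with left/right leaf sets and child pointers; the last
#'   node is the root), plus empty slots for markers and codes.
#' @export
build_tree <- function(embedding, clustering) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else as.matrix(embedding)
  labels <- clustering$labels
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need >= 2 clusters to build a tree")
  cents <- t(vapply(clusters, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE]), numeric(ncol(scores))))
  rownames(cents) <- as.character(clusters)
  hc <- stats::hclust(stats::dist(cents), method = "average")
  leaves <- hc$labels
  nodes <- vector("list", nrow(hc$merge))
  members <- function(v)    # leaves under a merge entry
    if (v < 0) leaves[-v] else c(nodes[[v]]$left_leaves, nodes[[v]]$right_leaves)
  child <- function(v) if (v < 0) leaves[-v] else sprintf("N%d", v)
  for (i in seq_len(nrow(hc$merge))) {
    l <- hc$merge[i, 1]; r <- hc$merge[i, 2]
    nodes[[i]] <- list(id = sprintf("N%d", i),
                       left_child = child(l), right_child = child(r),
                       left_is_leaf = l < 0, right_is_leaf = r < 0,
                       left_leaves = members(l), right_leaves = members(r),
                       markers_left = NULL, markers_right = NULL,
                       flagged = FALSE)
  }
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  structure(list(hc = hc, leaves = leaves, nodes = nodes,
                 codes = NULL, names = NULL),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d leaves, %d internal nodes%s%s\n",
              length(x$leaves), length(x$nodes),
              if (!is.null(x$nodes[[length(x$nodes)]]$markers_left) ||
                  any(vapply(x$nodes, function(n) !is.null(n$markers_left), TRUE)))
                ", annotated" else "",
              if (!is.null(x$codes)) ", with codes" else ""))
  cat(tree_newick(x), "\n")
  invisible(x)
}

#' Newick string of a taxonomy tree (leaf names optional)
#' @param tree taxonomy_tree
#' @param leaf_names optional named character vector mapping cluster id to
#'   display name.
#' @return newick string
#' @export
tree_newick <- function(tree, leaf_names = NULL) {
  phy <- ape::as.phylo(tree$hc)
  if (!is.null(leaf_names))
    phy$tip.label <- unname(leaf_names[phy$tip.label])
  ape::write.tree(phy)
}

#' Annotate every dendrogram node with branch markers
#'
#' For each internal node, runs \code{\link{rank_markers}} between the cells
#' of its left-arm clusters and its right-arm clusters, using only cells
#' descending from that node (so each comparison is local to its branch
#' point).  Markers are stored per side with positive fold changes pointing
#' into that side.
#'
#' @param tree \code{\link{build_tree}} result.
#' @param norm log-normalized matrix (or \code{norm_result}).
#' @param clustering \code{\link{cluster_cells}} result.
#' @param min_pct,min_diff_pct,logfc_threshold passed to
#'   \code{\link{rank_markers}}.
#' @param min_cells arms with fewer cells than this leave the node
#'   un-annotated and flagged.
#' @return the tree with \code{markers_left} / \code{markers_right} filled
#'   on each node.
#' @export
annotate_nodes <- function(tree, norm, clustering, min_pct = 0.2,
                           min_diff_pct = 0.25, logfc_threshold = 1,
                           min_cells = 3) {
  if (inherits(norm, "norm_result")) norm <- norm$norm
  labels <- as.character(clustering$labels)
  for (id in names(tree$nodes)) {
    nd <- tree$nodes[[id]]
    a <- which(labels %in% nd$left_leaves)
    b <- which(labels %in% nd$right_leaves)
    if (length(a) < min_cells || length(b) < min_cells) {
      tree$nodes[[id]]$flagged <- TRUE
      next
    }
    mk <- rank_markers(norm, a, b, min_pct, min_diff_pct, logfc_threshold)
    left <- mk[mk$log2fc > 0, , drop = FALSE]
    right <- mk[mk$log2fc < 0, , drop = FALSE]
    # express right-side markers from the right arm's perspective
    if (nrow(right)) {
      right$log2fc <- -right$log2fc
      tmp <- right$pct1; right$pct1 <- right$pct2; right$pct2 <- tmp
      right <- right[order(-abs(right$log2fc), right$p, right$gene), , drop = FALSE]
    }
    tree$nodes[[id]]$markers_left <- left
    tree$nodes[[id]]$markers_right <- right
  }
  tree
}

# ordered internal-node path from the root to a leaf, with the side taken
.leaf_path <- function(tree, leaf) {
  path <- list()
  id <- tree$nodes[[length(tree$nodes)]]$id   # root = last merge
  repeat {
    nd <- tree$nodes[[id]]
    side <- if (leaf %in% nd$left_leaves) "left" else "right"
    path[[length(path) + 1L]] <- list(node = id, side = side)
    nxt <- if (side == "left") nd$left_child else nd$right_child
    if ((side == "left" && nd$left_is_leaf) ||
        (side == "right" && nd$right_is_leaf)) break
    id <- nxt
  }
  path
}

#' Derive unique stepwise marker codes for every leaf
#'
#' Following the branch points from the root to each leaf, the code records
#' the top marker of the side taken at every node — an ordered intersection
#' of positive expression gates that uniquely identifies the leaf (e.g.
#' \code{geneA+ & geneB+ & geneC+}).
#'
#' @param tree an annotated tree (\code{\link{annotate_nodes}}).
#' @param markers_per_node markers recorded per step (the first is the
#'   gate; extras are reported for context).
#' @param gate_by how the gate gene is picked from the side's marker list:
#'   \code{"detection_gap"} (default) takes the marker with the largest
#'   pct1 - pct2 — a deterministic stand-in for the manual curation of the
#'   most binary branch gene — while \code{"rank"} takes the fold-change
#'   ranked top marker.
#' @return tree with \code{codes}: per leaf a data.frame (node, gene, sign)
#'   and a \code{recipe} string.
#' @export
derive_codes <- function(tree, markers_per_node = 1,
                         gate_by = c("detection_gap", "rank")) {
  gate_by <- match.arg(gate_by)
  codes <- list()
  for (leaf in tree$leaves) {
    steps <- NULL
    for (st in .leaf_path(tree, leaf)) {
      nd <- tree$nodes[[st$node]]
      mk <- if (st$side == "left") nd$markers_left else nd$markers_right
      if (is.null(mk) || nrow(mk) == 0)
        stop(sprintf("node %s has no %s-side markers; annotate the tree or relax thresholds",
                     st$node, st$side))
      if (gate_by == "detection_gap")
        mk <- mk[order(-(mk$pct1 - mk$pct2), mk$p, mk$gene), , drop = FALSE]
      top <- utils::head(mk$gene, markers_per_node)
      steps <- rbind(steps, data.frame(node = st$node, gene = top[1],
                                       sign = "+",
                                       alternates = paste(top[-1], collapse = ","),
                                       row.names = NULL))
    }
    codes[[leaf]] <- steps
  }
  recipes <- vapply(codes, function(df)
    paste0(df$gene, df$sign, collapse = " & "), "")
  if (anyDuplicated(recipes))
    stop("stepwise codes are not unique across leaves")
  tree$codes <- codes
  tree$recipes <- recipes
  tree
}

#' Evaluate a stepwise code as literal expression gates
#'
#' A cell passes the code if it detects (count > 0) every gene in the code.
#' Used to measure how well a code isolates its target population.
#'
#' @param x count_matrix (raw counts; detection is count > 0).
#' @param code a per-leaf code data.frame from \code{\link{derive_codes}}.
#' @return logical vector over cells.
#' @export
evaluate_code <- function(x, code) {
  genes <- intersect(code$gene, rownames(x$counts))
  if (length(genes) < nrow(code))
    stop("code genes missing from matrix: ",
         paste(setdiff(code$gene, genes), collapse = ", "))
  det <- x$counts[code$gene, , drop = FALSE] > 0
  Matrix::colSums(det) == nrow(code)
}

#' Assign leaves to families by cutting the dendrogram
#'
#' Families are the subtrees obtained from the top-level divisions of the
#' tree (cutting at the highest \code{n_families - 1} merges).
#'
#' @param tree taxonomy_tree
#' @param n_families number of families (default 3).
#' @return named character vector leaf -> family id ("F1", "F2", ...);
#'   families are numbered in dendrogram order.
#' @export
tree_families <- function(tree, n_families = 3) {
  ct <- stats::cutree(tree$hc, k = min(n_families, length(tree$leaves)))
  # renumber in dendrogram display order for stable ids
  ord <- unique(ct[tree$hc$labels[tree$hc$order]])
  fam <- sprintf("F%d", match(ct, ord))
  names(fam) <- names(ct)
  fam
}

#' Shorthand cluster names from family membership and top markers
#'
#' Within each family, each cluster is compared against the rest of its
#' family (\code{\link{rank_markers}}, positive side) and named
#' \code{Family^TopGene}; a collision falls through to the next-ranked
#' gene, and a cluster with no passing markers (including single-cluster
#' families, where one-vs-rest is undefined) gets the fallback
#' \code{Family^cN}.  The top three genes per cluster are reported.
#'
#' @param tree taxonomy_tree
#' @param norm log-normalized matrix (or norm_result).
#' @param clustering cluster_cells result.
#' @param n_families number of top-level families.
#' @param min_pct,min_diff_pct,logfc_threshold marker thresholds.
#' @return data.frame: cluster, family, name, top_genes (comma-separated).
#' @export
name_clusters <- function(tree, norm, clustering, n_families = 3,
                          min_pct = 0.2, min_diff_pct = 0.25,
                          logfc_threshold = 1) {
  if (inherits(norm, "norm_result")) norm <- norm$norm
  labels <- as.character(clustering$labels)
  fam <- tree_families(tree, n_families)
  out <- NULL
  used <- character(0)
  for (leaf in tree$leaves) {
    f <- fam[[leaf]]
    siblings <- setdiff(names(fam)[fam == f], leaf)
    top <- character(0)
    if (length(siblings)) {
      a <- which(labels == leaf)
      b <- which(labels %in% siblings)
      mk <- rank_markers(norm, a, b, min_pct, min_diff_pct, logfc_threshold)
      top <- mk$gene[mk$log2fc > 0]
    }
    pick <- setdiff(top, used)
    nm <- if (length(pick)) paste0(f, "^", pick[1]) else paste0(f, "^c", leaf)
    used <- c(used, if (length(pick)) pick[1])
    out <- rbind(out, data.frame(
      cluster = leaf, family = f, name = nm,
      top_genes = paste(utils::head(top, 3), collapse = ","),
      row.names = NULL))
  }
  out
}

#' Export an annotated tree (topology, markers, codes) as JSON
#' @param tree taxonomy_tree
#' @param path output file
#' @return path, invisibly
#' @export
write_tree_json <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(nd) {
    nd$markers_left <- if (!is.null(nd$markers_left)) nd$markers_left
    nd$markers_right <- if (!is.null(nd$markers_right)) nd$markers_right
    nd
  })
  jsonlite::write_json(list(newick = tree_newick(tree), leaves = tree$leaves,
                            nodes = nodes, codes = tree$codes,
                            recipes = as.list(tree$recipes)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
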