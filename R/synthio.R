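#' Plant a ground-truth taxonomy for synthetic data
#'
#' Builds a \code{truth_spec}: a rooted binary tree of dopamine-neuron-like
#' subtypes grouped into families, with branch markers planted at every
#' internal node, leaf proportions, sex-linked genes, a glial doublet
#' profile, genotype effects, a reduced spatial gene panel with probe
#' failures, and a rectangular region layout.  Everything downstream of the
#' simulators can be scored against this object.
#'
#' The tree topology is: families are joined right-to-left under the root
#' (family 1 vs the rest, then family 2 vs family 3, ...), and leaves within
#' a family are split recursively in halves.  Each internal node carries
#' \code{markers_per_side} private marker genes per arm whose expression is
#' multiplied by \code{effect_size} in every leaf on that arm.
#'
#' @param n_genes total size of the gene universe.
#' @param leaves_per_family integer vector, number of leaves in each family
#'   (length = number of families, default three families of two).
#' @param seed integer seed; identical seeds give identical specs.
#' @param effect_size fold-change multiplier planted on the positive side of
#'   every node marker (and on leaf markers).
#' @param markers_per_side planted marker genes per node arm.
#' @param panel_size number of genes on the spatial panel (markers are always
#'   included; the remainder are random non-special genes).
#' @param n_probe_failures panel genes whose spatial detection is forced to
#'   zero, emulating faulty probes.
#' @param off_leak fraction of a marker's baseline expression leaking on
#'   the non-marked side.  Branch-code markers are near-binary genes
#'   (strongly on along their branch, near-silent elsewhere); the leak
#'   keeps off-branch detection around 10 percent rather than zero.
#' @param genotype_genes number of non-marker genes given a global
#'   genotype effect.
#' @param genotype_effect multiplicative expression effect in mutant cells.
#' @param doublet_fraction default fraction of glial-doublet cells used by
#'   \code{\link{simulate_counts}}.
#' @return An object of class \code{truth_spec}.
#' @export
make_truth <- function(n_genes = 600,
                       leaves_per_family = c(2L, 2L, 2L),
                       seed = 1L,
                       effect_size = 4,
                       markers_per_side = 8L,
                       off_leak = 0.05,
                       panel_size = 120L,
                       n_probe_failures = 2L,
                       genotype_genes = 10L,
                       genotype_effect = 2,
                       doublet_fraction = 0.03) {
  leaves_per_family <- as.integer(leaves_per_family)
  stopifnot(length(leaves_per_family) >= 1, all(leaves_per_family >= 1))
  n_fam <- length(leaves_per_family)
  leaves <- unlist(lapply(seq_len(n_fam), function(f)
    sprintf("L%d_%d", f, seq_len(leaves_per_family[f]))))
  families <- rep(sprintf("F%d", seq_len(n_fam)), leaves_per_family)
  names(families) <- leaves

  # count internal nodes of the planted topology: (n_fam - 1) joins above the
  # families plus (k - 1) per family of k leaves = total leaves - 1
  n_nodes <- length(leaves) - 1L
  n_marker_genes <- n_nodes * 2L * markers_per_side
  n_sex <- 4L
  n_glial <- 4L
  needed <- n_marker_genes + n_sex + n_glial + genotype_genes + 20L
  if (n_genes < needed)
    stop(sprintf("gene budget exhausted: need >= %d genes, got %d",
                 needed, n_genes))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # gene universe; roles are carved out of the front of the id space
  marker_pool <- sprintf("MK%03d", seq_len(n_marker_genes))
  sex_male <- sprintf("SEXM%d", 1:2)
  sex_female <- sprintf("SEXF%d", 1:2)
  glial <- sprintf("GLIA%d", seq_len(n_glial))
  n_bg <- n_genes - n_marker_genes - n_sex - n_glial
  bg <- sprintf("G%04d", seq_len(n_bg))
  genes <- c(marker_pool, sex_male, sex_female, glial, bg)

  # recursive topology over an ordered set of leaf blocks
  nodes <- list()
  take <- local({
    i <- 0L
    function(k) {
      out <- marker_pool[i + seq_len(k)]
      i <<- i + k
      out
    }
  })
  node_id <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      sprintf("N%d", i)
    }
  })
  # blocks: list of character vectors of leaves; returns newick fragment
  join <- function(left_leaves, right_leaves) {
    id <- node_id()
    nodes[[id]] <<- list(
      id = id,
      left_leaves = left_leaves, right_leaves = right_leaves,
      markers_left = take(markers_per_side),
      markers_right = take(markers_per_side))
    id
  }
  build_split <- function(lv) {
    # full binary split of an ordered leaf vector; returns newick string
    if (length(lv) == 1L) return(lv)
    h <- ceiling(length(lv) / 2)
    l <- lv[seq_len(h)]; r <- lv[-seq_len(h)]
    join(l, r)
    sprintf("(%s,%s)", build_split(l), build_split(r))
  }
  fam_leaves <- split(leaves, families[leaves])[unique(families)]
  build_forest <- function(blocks) {
    if (length(blocks) == 1L) return(build_split(blocks[[1]]))
    l <- blocks[[1]]; r <- unlist(blocks[-1])
    id <- join(l, r)
    sprintf("(%s,%s)", build_split(l), build_forest(blocks[-1]))
  }
  newick <- paste0(build_forest(fam_leaves), ";")

  # baseline relative expression, lognormal across genes; planted markers
  # sit in the binary on/off regime of curated branch markers: expressed
  # at effect_size x baseline along their branch, at off_leak x baseline
  # elsewhere, so detection, fold-change and literal gates all see them
  baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  names(baseline) <- genes
  baseline[marker_pool] <- stats::rlnorm(n_marker_genes, meanlog = -1,
                                         sdlog = 0.4)

  marker_table <- do.call(rbind, lapply(nodes, function(nd) {
    data.frame(node = nd$id,
               gene = c(nd$markers_left, nd$markers_right),
               side = rep(c("left", "right"), each = markers_per_side),
               fc = effect_size, row.names = NULL)
  }))

  lp <- rep(1 / length(leaves), length(leaves))
  names(lp) <- leaves

  gt_genes <- sample(bg, genotype_genes)
  genotype_effects <- data.frame(gene = gt_genes, scope = "global",
                                 effect = genotype_effect,
                                 row.names = NULL)

  # spatial panel: most planted markers (the last two of each node side
  # stay off-panel, as real reduced panels omit some informative genes)
  # plus random background genes
  panel_markers <- unlist(lapply(nodes, function(nd)
    c(utils::head(nd$markers_left, max(1L, markers_per_side - 2L)),
      utils::head(nd$markers_right, max(1L, markers_per_side - 2L)))))
  extra <- max(0L, panel_size - length(panel_markers))
  panel <- c(panel_markers, sample(setdiff(bg, gt_genes), extra))
  probe_failures <- sample(panel, n_probe_failures)

  # one rectangular region per family, side by side, coordinates in um
  regions <- lapply(seq_len(n_fam), function(f)
    cbind(x = c(0, 1200, 1200, 0) + (f - 1) * 1200,
          y = c(0, 0, 800, 800)))
  names(regions) <- c("SNc", "VTA", "RR", sprintf("R%d", seq_len(max(0, n_fam - 3)) + 3))[seq_len(n_fam)]
  region_layout <- names(regions)[match(families, unique(families))]
  names(region_layout) <- leaves

  structure(list(
    genes = genes, leaves = leaves, families = families,
    nodes = nodes, tree_newick = newick,
    marker_table = marker_table,
    leaf_proportions = lp,
    baseline = baseline,
    genotype_effects = genotype_effects,
    sex_genes = list(male = sex_male, female = sex_female),
    doublet_spec = list(markers = glial, fraction = doublet_fraction),
    panel = panel, probe_failures = probe_failures,
    regions = regions, region_layout = region_layout,
    effect_size = effect_size, off_leak = off_leak,
    seed = seed), class = "truth_spec")
}

#' @export
print.truth_spec <- function(x, ...) {
  cat(sprintf("truth_spec: %d genes, %d leaves in %d families, %d nodes\n",
              length(x$genes), length(x$leaves),
              length(unique(x$families)), length(x$nodes)))
  cat("topology:", x$tree_newick, "\n")
  invisible(x)
}

# expected relative expression rate per gene for one leaf (or glial/doublet
# profile), before depth scaling; genotype/sex applied by the simulators
.leaf_rates <- function(truth, leaf) {
  r <- truth$baseline
  # sex genes are handled per cell; keep them near silent in the base profile
  r[c(truth$sex_genes$male, truth$sex_genes$female)] <-
    r[c(truth$sex_genes$male, truth$sex_genes$female)] * 0.01
  r[truth$doublet_spec$markers] <- r[truth$doublet_spec$markers] * 0.01
  all_markers <- truth$marker_table$gene
  if (identical(leaf, "glial")) {
    # glia express none of the neuronal branch markers
    r[all_markers] <- r[all_markers] * truth$off_leak
    r[truth$doublet_spec$markers] <- truth$baseline[truth$doublet_spec$markers] * 20
    return(r)
  }
  r[all_markers] <- r[all_markers] * truth$off_leak
  for (nd in truth$nodes) {
    if (leaf %in% nd$left_leaves)
      r[nd$markers_left] <- truth$baseline[nd$markers_left] * truth$effect_size
    else if (leaf %in% nd$right_leaves)
      r[nd$markers_right] <- truth$baseline[nd$markers_right] * truth$effect_size
  }
  r
}

# matrix of per-leaf relative rates, genes x profiles
.profile_matrix <- function(truth, profiles) {
  vapply(profiles, function(p) {
    if (p == "doublet") {
      # doublets mix one random-ish leaf with glia; the sampling leaf is
      # chosen by the caller, this column is the 50/50 glial mix base
      stop("internal: doublet profiles are built by the caller")
    }
    .leaf_rates(truth, p)
  }, numeric(length(truth$genes)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a dissociated-profile count matrix from a planted taxonomy
#'
#' Cells are drawn from the leaf proportions; a fraction are 50/50
#' dopamine-glial doublet mixtures.  Per-gene means follow the baseline
#' times the planted node multipliers along the cell's root-to-leaf path,
#' times genotype effects for mutant cells; counts are negative binomial
#' with a shared dispersion and a lognormal per-cell depth factor
#' (sigma = 0.35).  Sex-linked genes are expressed according to an assigned
#' sex, with a small indeterminate class whose sex genes drop out.
#'
#' @param truth a \code{\link{make_truth}} spec.
#' @param n_cells number of cells.
#' @param depth_mean median-scale expected depth (UMIs per cell).
#' @param depth_sd lognormal sigma of the per-cell depth factor (0 gives
#'   every cell exactly \code{depth_mean} expected counts).
#' @param dispersion negative-binomial size parameter r (variance =
#'   mu + mu^2/r); larger is closer to Poisson.
#' @param doublet_fraction fraction of doublet cells; defaults to the value
#'   stored in \code{truth$doublet_spec}.
#' @param genotypes vector of genotype labels to assign (cells are split
#'   evenly; one sample per genotype).
#' @param sex_dropout fraction of cells whose sex genes drop out entirely.
#' @param seed integer seed.
#' @return a \code{\link{count_matrix}} with \code{truth_leaf},
#'   \code{truth_sex}, \code{sample} and \code{genotype} in
#'   \code{cell_meta}.
#' @export
simulate_counts <- function(truth, n_cells = 3000, depth_mean = 5000,
                            depth_sd = 0.35, dispersion = 2,
                            doublet_fraction = truth$doublet_spec$fraction,
                            genotypes = c("control", "mutant"),
                            sex_dropout = 0.05,
                            seed = 1L) {
  stopifnot(inherits(truth, "truth_spec"), n_cells >= length(truth$leaves),
            dispersion > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- truth$genes
  leaves <- truth$leaves

  is_doublet <- stats::runif(n_cells) < doublet_fraction
  leaf <- sample(leaves, n_cells, replace = TRUE,
                 prob = truth$leaf_proportions[leaves])
  mix_leaf <- leaf                      # doublets remember their DA half
  truth_leaf <- ifelse(is_doublet, "doublet", leaf)
  if (!all(leaves %in% truth_leaf[!is_doublet]))
    warning("some leaves received no cells at this n_cells")

  sex <- sample(c("male", "female"), n_cells, replace = TRUE)
  dropout <- stats::runif(n_cells) < sex_dropout
  truth_sex <- ifelse(dropout, "indeterminate", sex)

  genotype <- rep(genotypes, length.out = n_cells)[sample.int(n_cells)]
  sample_id <- paste0(genotype, "_s1")

  prof <- .profile_matrix(truth, stats::setNames(leaves, leaves))
  glial <- .leaf_rates(truth, "glial")

  depth <- stats::rlnorm(n_cells, meanlog = log(depth_mean), sdlog = depth_sd)

  gt_idx <- match(truth$genotype_effects$gene, genes)
  counts <- matrix(0L, length(genes), n_cells,
                   dimnames = list(genes, sprintf("cell%05d", seq_len(n_cells))))
  for (c_i in seq_len(n_cells)) {
    r <- if (is_doublet[c_i]) 0.5 * (prof[, mix_leaf[c_i]] + glial)
         else prof[, leaf[c_i]]
    if (truth_sex[c_i] == "male")
      r[truth$sex_genes$male] <- truth$baseline[truth$sex_genes$male] * 20
    else if (truth_sex[c_i] == "female")
      r[truth$sex_genes$female] <- truth$baseline[truth$sex_genes$female] * 20
    if (genotype[c_i] != genotypes[1])  # first label is the reference genotype
      r[gt_idx] <- r[gt_idx] * truth$genotype_effects$effect
    mu <- depth[c_i] * r / sum(r)
    counts[, c_i] <- stats::rnbinom(length(genes), mu = mu, size = dispersion)
  }

  cm <- data.frame(sample = sample_id, genotype = genotype,
                   truth_leaf = truth_leaf, truth_sex = truth_sex,
                   row.names = colnames(counts))
  gm <- data.frame(is_mito = grepl("^MT", genes), is_ribo = grepl("^RP", genes),
                   row.names = genes)
  count_matrix(counts, cm, gm)
}

# uniform sample inside a polygon by bounding-box rejection
.runif_polygon <- function(n, poly) {
  if (abs(.polygon_area(poly)) < .Machine$double.eps)
    stop("region polygon is degenerate (area 0)")
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 2L + 8L
    x <- stats::runif(m, min(poly[, 1]), max(poly[, 1]))
    y <- stats::runif(m, min(poly[, 2]), max(poly[, 2]))
    ok <- which(point_in_polygon(x, y, poly))
    take <- utils::head(ok, n - got)
    if (length(take)) {
      out[got + seq_along(take), ] <- cbind(x[take], y[take])
      got <- got + length(take)
    }
  }
  out
}

.polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i <- seq_len(nrow(poly)); j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x[i] * y[j] - x[j] * y[i]) / 2
}

#' Simulate a spatial-panel (MERFISH-style) count matrix
#'
#' Cells carry only the planted panel genes; probe-failure genes are forced
#' to zero detection.  Coordinates are drawn uniformly inside the region
#' polygon assigned to each leaf, in micrometres with origin at the bottom
#' left; cell volumes are lognormal.  Depth is typically much lower than in
#' the dissociated simulation, as in imaging-based panels.
#'
#' @param truth a \code{\link{make_truth}} spec.
#' @param reference optional reference \code{count_matrix}; only used to
#'   check gene-universe compatibility.
#' @param n_cells number of cells (0 gives an empty matrix with the panel
#'   gene axis intact).
#' @param depth_mean expected transcripts per cell over the panel.
#' @param dispersion negative-binomial size parameter.
#' @param leaves leaves to simulate (default all); restricting this emulates
#'   under-sampled regions.
#' @param seed integer seed.
#' @return a \code{\link{count_matrix}} over \code{truth$panel} with
#'   \code{x_um}, \code{y_um}, \code{volume_um3}, \code{truth_leaf} and
#'   \code{truth_region} in \code{cell_meta}.
#' @export
simulate_spatial <- function(truth, reference = NULL, n_cells = 1500,
                             depth_mean = 400, dispersion = 2,
                             leaves = truth$leaves, seed = 1L) {
  stopifnot(inherits(truth, "truth_spec"), length(truth$panel) > 0)
  if (!is.null(reference) &&
      !all(truth$panel %in% rownames(reference$counts)))
    stop("panel genes missing from the reference gene universe")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  panel <- truth$panel
  pidx <- match(panel, truth$genes)

  if (n_cells == 0) {
    m <- matrix(0L, length(panel), 0, dimnames = list(panel, character(0)))
    return(count_matrix(m))
  }
  lp <- truth$leaf_proportions[leaves] / sum(truth$leaf_proportions[leaves])
  leaf <- sample(leaves, n_cells, replace = TRUE, prob = lp)
  region <- truth$region_layout[leaf]
  depth <- stats::rlnorm(n_cells, meanlog = log(depth_mean), sdlog = 0.35)

  prof <- .profile_matrix(truth, stats::setNames(leaves, leaves))[pidx, , drop = FALSE]
  prof[match(truth$probe_failures, panel), ] <- 0

  counts <- matrix(0L, length(panel), n_cells,
                   dimnames = list(panel, sprintf("sp%05d", seq_len(n_cells))))
  for (c_i in seq_len(n_cells)) {
    p <- prof[, leaf[c_i]]
    mu <- depth[c_i] * p / sum(p)
    counts[, c_i] <- stats::rnbinom(length(panel), mu = mu, size = dispersion)
  }

  xy <- matrix(NA_real_, n_cells, 2)
  for (rg in unique(region)) {
    idx <- which(region == rg)
    xy[idx, ] <- .runif_polygon(length(idx), truth$regions[[rg]])
  }
  vol <- stats::rlnorm(n_cells, meanlog = log(1500), sdlog = 0.3)

  cm <- data.frame(sample = "section1", x_um = xy[, 1], y_um = xy[, 2],
                   volume_um3 = vol, truth_leaf = leaf, truth_region = region,
                   row.names = colnames(counts))
  count_matrix(counts, cm)
}

#' Write a truth spec to JSON
#' @param truth truth_spec
#' @param path output file
#' @return path, invisibly
#' @export
write_truth_json <- function(truth, path) {
  x <- truth
  x$regions <- lapply(x$regions, function(m) unname(apply(m, 1, c, simplify = FALSE)))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write region polygons as a GeoJSON FeatureCollection
#'
#' Each polygon becomes a Feature with a \code{name} property; rings are
#' closed on output.  Coordinates are micrometres.
#'
#' @param regions named list of 2-column coordinate matrices.
#' @param path output file.
#' @return path, invisibly
#' @export
write_regions_geojson <- function(regions, path) {
  feats <- lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    ring <- rbind(m, m[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           apply(ring, 1, c, simplify = FALSE)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region polygons from a GeoJSON FeatureCollection
#'
#' Polygons are returned in file order (the priority order used by
#' \code{\link{assign_regions}}); the closing vertex is dropped.
#'
#' @param path GeoJSON file with Polygon features carrying a \code{name}
#'   property.
#' @return named list of 2-column matrices.
#' @export
read_regions_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) stop("not a FeatureCollection")
  out <- list()
  for (f in g$features) {
    nm <- f$properties$name
    if (is.null(nm)) stop("feature without a name property")
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon geometries are supported")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    if (nrow(ring) < 4) stop(sprintf("degenerate polygon '%s'", nm))
    if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("x", "y")
    out[[nm]] <- ring
  }
  out
}
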