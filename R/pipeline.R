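#' Derive a stage-specific seed from a global seed
#'
#' Stable fan-out: the stage name is hashed and folded into the global
#' seed modulo 2^31 - 1, so adding or reordering stages does not shift the
#' random streams of other stages.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Read a run configuration (YAML or JSON)
#' @param path config file; .yml/.yaml needs the yaml package.
#' @return nested list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

.cfg <- function(config, name, default) {
  if (!is.null(config[[name]])) config[[name]] else default
}

#' Run the full synthetic-to-results pipeline
#'
#' Executes the stages in order — simulate, qc, taxonomy (normalize /
#' reduce / cluster / tree / codes / names), spatial transfer, genotype
#' contrasts, risk scoring — writing every result table under
#' \code{out_dir} and returning a manifest with parameter snapshots and
#' output hashes.  All randomness is derived from the single global seed
#' via \code{\link{derive_seed}}, so two runs of the same config are
#' byte-identical.
#'
#' @param config nested list (or a path readable by
#'   \code{\link{read_run_config}}).  Recognised top-level keys: seed,
#'   out_dir, stages (subset of the above, default all), and per-stage
#'   parameter blocks \code{simulate} (n_genes, leaves_per_family,
#'   effect_size, n_cells, depth_mean, spatial_cells), \code{taxonomy}
#'   (n_components, k_neighbors, resolution), \code{transfer}
#'   (score_threshold, min_flow), \code{risk} (n_ctrl, n_boot, alpha,
#'   n_risk_genes).
#' @return list of class \code{run_manifest}: per-stage parameters, output
#'   paths and md5 hashes.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- .cfg(config, "seed", 1L)
  out_dir <- .cfg(config, "out_dir", tempfile("dopatax_run"))
  stages <- .cfg(config, "stages",
                 c("simulate", "qc", "taxonomy", "spatial", "contrast", "risk"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, out_dir = out_dir, stages = list())
  emit <- function(stage, name, df) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  done <- function(stage, params, paths) {
    manifest$stages[[stage]] <<- list(
      params = params, outputs = paths,
      md5 = as.character(tools::md5sum(unlist(paths))))
  }

  sim <- .cfg(config, "simulate", list())
  truth <- make_truth(
    n_genes = .cfg(sim, "n_genes", 600),
    leaves_per_family = .cfg(sim, "leaves_per_family", c(2, 2, 2)),
    seed = derive_seed(seed, "truth"),
    effect_size = .cfg(sim, "effect_size", 4))
  counts <- simulate_counts(truth,
                            n_cells = .cfg(sim, "n_cells", 3000),
                            depth_mean = .cfg(sim, "depth_mean", 5000),
                            seed = derive_seed(seed, "simulate"))
  spatial <- simulate_spatial(truth, counts,
                              n_cells = .cfg(sim, "spatial_cells", 1200),
                              seed = derive_seed(seed, "spatial_sim"))
  if ("simulate" %in% stages) {
    p1 <- file.path(out_dir, "reference"); write_count_matrix(counts, p1)
    p2 <- file.path(out_dir, "spatial"); write_count_matrix(spatial, p2)
    write_regions_geojson(truth$regions, file.path(out_dir, "regions.geojson"))
    write_truth_json(truth, file.path(out_dir, "truth.json"))
    done("simulate", sim, list(file.path(p1, "matrix.mtx"),
                               file.path(p2, "matrix.mtx"),
                               file.path(out_dir, "regions.geojson")))
  }

  qc <- compute_qc(counts)
  if ("qc" %in% stages) {
    kept <- filter_cells(qc, list(qc_window("all")))
    sex <- infer_sex(counts, truth$sex_genes$male, truth$sex_genes$female)
    done("qc", list(), list(emit("qc", "qc_cells", qc),
                            emit("qc", "sex_calls", sex)))
  }

  tax <- .cfg(config, "taxonomy", list())
  sex_genes <- unlist(truth$sex_genes)
  nr <- normalize_counts(counts)
  emb <- reduce_dims(nr, .cfg(tax, "n_components", 32),
                     exclude_genes = sex_genes)
  cl <- cluster_cells(emb, .cfg(tax, "k_neighbors", 40),
                      .cfg(tax, "resolution", 1.0),
                      seed = derive_seed(seed, "cluster"))
  flagged <- flag_doublet_clusters(counts, cl$labels, truth$doublet_spec$markers)
  keep <- !(as.character(cl$labels) %in% flagged)
  counts_k <- counts[, keep]
  nr_k <- normalize_counts(counts_k)
  emb_k <- reduce_dims(nr_k, .cfg(tax, "n_components", 32),
                       exclude_genes = sex_genes)
  cl_k <- cluster_cells(emb_k, .cfg(tax, "k_neighbors", 40),
                        .cfg(tax, "resolution", 1.0),
                        seed = derive_seed(seed, "recluster"))
  tree <- build_tree(emb_k, cl_k)
  tree <- annotate_nodes(tree, nr_k, cl_k)
  tree <- derive_codes(tree)
  names_df <- name_clusters(tree, nr_k, cl_k,
                            n_families = length(unique(truth$families)))
  if ("taxonomy" %in% stages) {
    marker_tab <- do.call(rbind, lapply(names(tree$nodes), function(id) {
      nd <- tree$nodes[[id]]
      rbind(
        if (!is.null(nd$markers_left) && nrow(nd$markers_left))
          cbind(node = id, side = "left", nd$markers_left),
        if (!is.null(nd$markers_right) && nrow(nd$markers_right))
          cbind(node = id, side = "right", nd$markers_right))
    }))
    codes_tab <- data.frame(cluster = names(tree$recipes),
                            recipe = unname(tree$recipes))
    writeLines(tree_newick(tree), file.path(out_dir, "tree.nwk"))
    done("taxonomy", tax,
         list(emit("taxonomy", "clusters",
                   data.frame(cell_id = names(cl_k$labels),
                              cluster = cl_k$labels)),
              emit("taxonomy", "node_markers", marker_tab),
              emit("taxonomy", "stepwise_codes", codes_tab),
              emit("taxonomy", "cluster_names", names_df),
              file.path(out_dir, "tree.nwk")))
  }

  tr_cfg <- .cfg(config, "transfer", list())
  if ("spatial" %in% stages) {
    shared <- select_shared_features(counts_k, spatial)
    anchors <- find_anchors(counts_k, spatial, shared,
                            seed = derive_seed(seed, "anchors"))
    trans <- transfer_labels(anchors, cl_k$labels,
                             score_threshold = .cfg(tr_cfg, "score_threshold", 0.5))
    regions <- assign_regions(spatial, truth$regions)
    comp <- regional_composition(regions, trans$cells$predicted)
    flows <- correspondence_flows(spatial$cell_meta$truth_leaf,
                                  trans$cells$predicted,
                                  min_flow = .cfg(tr_cfg, "min_flow", 0.10))
    done("spatial", tr_cfg,
         list(emit("spatial", "transfer", trans$cells),
              emit("spatial", "region_labels",
                   data.frame(cell_id = names(regions), region = regions)),
              emit("spatial", "region_composition",
                   as.data.frame(comp$by_region)),
              emit("spatial", "flows", flows)))
  }

  if ("contrast" %in% stages) {
    de <- condition_de(nr_k, counts_k$cell_meta$genotype)
    prop <- proportion_shift(cl_k$labels, counts_k$cell_meta$genotype,
                             n_perm = 200,
                             seed = derive_seed(seed, "proportions"))
    done("contrast", list(),
         list(emit("contrast", "genotype_de", de$table),
              emit("contrast", "proportion_shift", prop)))
  }

  rk <- .cfg(config, "risk", list())
  if ("risk" %in% stages) {
    bins <- bin_genes(nr_k, .cfg(rk, "n_mean_bin", 10),
                      .cfg(rk, "n_var_bin", 3))
    leaf1 <- truth$leaves[1]
    nd <- truth$nodes[[which(vapply(truth$nodes, function(n)
      identical(n$left_leaves, leaf1), TRUE))[1]]]
    risk_genes <- if (!is.null(nd)) nd$markers_left else truth$marker_table$gene[1:5]
    risk <- structure(list(z = stats::setNames(rep(5, length(risk_genes)),
                                               risk_genes),
                           unmapped = character(0), ortholog_mapped = FALSE),
                      class = "risk_gene_set")
    sc <- score_cells(nr_k, risk, bins, n_ctrl = .cfg(rk, "n_ctrl", 200),
                      seed = derive_seed(seed, "risk"))
    gb <- group_bootstrap(sc, counts_k$cell_meta$truth_leaf,
                          n_boot = .cfg(rk, "n_boot", 2000),
                          alpha = .cfg(rk, "alpha", 0.05),
                          seed = derive_seed(seed, "bootstrap"))
    done("risk", rk, list(emit("risk", "cell_scores", sc$cells),
                          emit("risk", "group_scores", gb)))
  }

  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %d, %d stage(s) in %s\n",
              x$seed, length(x$stages), x$out_dir))
  for (nm in names(x$stages))
    cat(sprintf("  %s: %d output(s)\n", nm, length(x$stages[[nm]]$outputs)))
  invisible(x)
}
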