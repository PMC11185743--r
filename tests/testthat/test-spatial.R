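test_that("shared-feature selection matches a brute-force ratio filter", {
  tr <- fx_truth()
  cm <- fx_counts()
  sp <- fx_spatial()
  shared <- select_shared_features(cm, sp, max_ratio = 4,
                                   min_detection = 0.01)
  expect_false(any(tr$probe_failures %in% shared))

  # identical datasets keep every mutually detected gene
  self <- select_shared_features(cm, cm, max_ratio = 4, min_detection = 0)
  det <- Matrix::rowSums(cm$counts > 0) > 0
  expect_setequal(self, rownames(cm$counts)[det])

  # brute force over the spatial pair
  genes <- intersect(rownames(cm$counts), rownames(sp$counts))
  mu_r <- Matrix::rowMeans(cm$counts[genes, ])
  mu_q <- Matrix::rowMeans(sp$counts[genes, ])
  det_r <- Matrix::rowSums(cm$counts[genes, ] > 0) / ncol(cm$counts)
  det_q <- Matrix::rowSums(sp$counts[genes, ] > 0) / ncol(sp$counts)
  brute <- genes[det_r >= 0.01 & det_q >= 0.01 & det_q > 0 & det_r > 0 &
                   mu_q / mu_r >= 0.25 & mu_q / mu_r <= 4]
  expect_setequal(shared, brute)
})

test_that("anchors are mutual, scored in [0,1], and mostly leaf-true", {
  tr <- fx_truth()
  cm <- fx_counts()
  an <- fx_anchors()
  expect_true(all(an$pairs$score >= 0 & an$pairs$score <= 1))
  agree <- mean(cm$cell_meta$truth_leaf[an$pairs$ref] ==
                  fx_spatial()$cell_meta$truth_leaf[an$pairs$query])
  expect_gte(agree, 0.8)

  # query = copy of the reference: every cell self-anchored at score 1
  sub <- cm[, 1:400]
  shared <- select_shared_features(cm, fx_spatial())
  an_self <- find_anchors(sub, sub, shared, seed = 3)
  self_pairs <- an_self$pairs[an_self$pairs$ref == an_self$pairs$query, ]
  expect_equal(nrow(self_pairs), 400)
  expect_true(all(self_pairs$score == 1))
})

test_that("anchors never cross well-separated populations at k_anchor 1", {
  tr <- fx_truth()
  cm <- fx_counts()
  two <- cm$cell_meta$truth_leaf %in% c("L1_1", "L3_2")  # opposite families
  ref <- cm[, two]
  an <- find_anchors(ref, ref, select_shared_features(cm, fx_spatial()),
                     k_anchor = 1, seed = 4)
  same <- ref$cell_meta$truth_leaf[an$pairs$ref] ==
    ref$cell_meta$truth_leaf[an$pairs$query]
  expect_true(all(same))
})

test_that("label transfer normalizes scores and gates confidence", {
  cm <- fx_counts()
  sp <- fx_spatial()
  an <- fx_anchors()
  trf <- transfer_labels(an, cm$cell_meta$truth_leaf)
  sums <- rowSums(trf$label_scores)
  assigned <- trf$cells$predicted != "unassigned"
  expect_true(all(sums[assigned] <= 1 + 1e-9))
  expect_identical(trf$cells$high_confidence, trf$cells$score > 0.5)

  # with perfect anchors (score 1) the label scores sum to exactly 1,
  # and a single-label reference gives that label score 1
  an1 <- an
  an1$pairs$score <- 1
  trf1 <- transfer_labels(an1, cm$cell_meta$truth_leaf)
  expect_true(all(abs(rowSums(trf1$label_scores) - 1) < 1e-9))
  trf_one <- transfer_labels(an1, rep("only", ncol(cm$counts)))
  expect_true(all(abs(trf_one$cells$score - 1) < 1e-9))

  # accuracy rises with the score gate (thresholds with a usable number
  # of gated cells; a one-cell dip within binomial noise is tolerated)
  truth <- sp$cell_meta$truth_leaf
  acc <- vapply(seq(0.1, 0.9, by = 0.2), function(th) {
    keep <- trf$cells$score > th
    if (sum(keep) < 20) return(NA_real_)
    mean(trf$cells$predicted[keep] == truth[keep])
  }, numeric(1))
  acc <- acc[!is.na(acc)]
  expect_gte(length(acc), 2)
  expect_true(all(diff(acc) >= -0.01))
  expect_gt(acc[length(acc)], acc[1] - 0.01)
})

test_that("imputation is an anchor-weighted convex average", {
  cm <- fx_counts()
  nr <- fx_norm()
  an <- fx_anchors()
  imp <- impute_expression(an, nr)
  expect_identical(dim(imp), c(nrow(nr$norm), length(an$query_ids)))
  # convexity: imputed values bounded by the contributing profiles
  rng <- range(nr$norm)
  expect_gte(min(imp), rng[1] - 1e-9)
  expect_lte(max(imp), rng[2] + 1e-9)

  # single anchor with weight 1 reproduces that reference profile
  single <- structure(list(
    pairs = data.frame(ref = 5L, query = 1L, score = 1),
    ref_scores = matrix(0, 10, 2), query_scores = matrix(0, 1, 2),
    ref_ids = colnames(cm$counts)[1:10], query_ids = "q1"),
    class = "anchor_set")
  imp1 <- impute_expression(single, nr$norm[, 1:10])
  expect_equal(unname(imp1[, 1]), unname(as.matrix(nr$norm[, 5])[, 1]))
})

test_that("off-panel planted markers impute higher in their own leaf", {
  tr <- fx_truth()
  sp <- fx_spatial()
  imp <- impute_expression(fx_anchors(), fx_norm())
  off_panel <- setdiff(tr$marker_table$gene, tr$panel)
  # take one off-panel marker for a leaf-level node side
  nd <- tr$nodes[[which(vapply(tr$nodes, function(n)
    identical(n$left_leaves, "L1_1"), TRUE))]]
  g <- setdiff(nd$markers_left, tr$panel)[1]
  pos <- sp$cell_meta$truth_leaf == "L1_1"
  expect_gte(oracle_auroc(imp[g, ], pos), 0.8)
})

test_that("imputation fidelity matches a dense Pearson oracle", {
  set.seed(8)
  genes <- sprintf("g%02d", 1:50)
  measured <- matrix(rpois(50 * 40, 3), 50,
                     dimnames = list(genes, sprintf("c%02d", 1:40)))
  imputed <- measured + matrix(rnorm(50 * 40, 0, 0.5), 50)
  fid <- imputation_fidelity(imputed, measured, genes)
  for (g in genes[1:10]) {
    nz <- measured[g, ] != 0 & imputed[g, ] != 0
    if (sum(nz) >= 10)
      expect_equal(fid[g, "r"], cor(imputed[g, nz], measured[g, nz]),
                   tolerance = 1e-12)
  }
  # identical matrices: r = 1 where defined
  fid2 <- imputation_fidelity(measured + 0.0, measured, genes)
  expect_true(all(abs(fid2$r[!is.na(fid2$r)] - 1) < 1e-12))
})

test_that("correspondence flows form a thresholded contingency table", {
  a <- c("x", "x", "y", "y", "y", "z")
  fl <- correspondence_flows(a, a, min_flow = 0)
  diag_rows <- fl[fl$source == fl$target, ]
  expect_true(all(diag_rows$fraction == 1))
  expect_equal(nrow(fl), 3)

  set.seed(9)
  la <- sample(letters[1:3], 200, replace = TRUE)
  lb <- sample(letters[1:4], 200, replace = TRUE)
  fl2 <- correspondence_flows(la, lb, min_flow = 0)
  # conservation and crosstab oracle
  for (s in unique(la)) {
    expect_equal(sum(fl2$fraction[fl2$source == s]), 1, tolerance = 1e-12)
    for (t in unique(lb)) {
      row <- fl2[fl2$source == s & fl2$target == t, ]
      n <- sum(la == s & lb == t)
      if (n > 0) expect_equal(row$n_cells, n)
    }
  }
  thr <- correspondence_flows(la, lb, min_flow = 0.3)
  expect_true(all(thr$fraction >= 0.3))
})

test_that("point-in-polygon matches an independent oracle and boundary rule", {
  poly <- cbind(x = c(0, 4, 4, 2, 0), y = c(0, 0, 3, 4, 3))  # convex-ish
  set.seed(10)
  x <- runif(1000, -1, 5); y <- runif(1000, -1, 5)
  ours <- point_in_polygon(x, y, poly)
  oracle <- as.logical(mgcv::in.out(rbind(poly, poly[1, ]), cbind(x, y)))
  expect_identical(ours, oracle)
  # vertices and edge midpoints count as inside
  expect_true(all(point_in_polygon(poly[, 1], poly[, 2], poly)))
  expect_true(point_in_polygon(2, 0, poly))
})

test_that("region assignment honors priority order and elsewhere", {
  regions <- list(inner = cbind(c(2, 4, 4, 2), c(2, 2, 4, 4)),
                  outer = cbind(c(0, 6, 6, 0), c(0, 0, 6, 6)))
  cells <- data.frame(x_um = c(3, 5, 10), y_um = c(3, 5, 10))
  expect_identical(unname(assign_regions(cells, regions)),
                   c("inner", "outer", "elsewhere"))
  expect_error(assign_regions(cells, list(bad = cbind(1, 2))), "malformed")
  expect_error(assign_regions(data.frame(a = 1), regions), "x_um")

  tr <- fx_truth()
  sp <- fx_spatial()
  lab <- assign_regions(sp, tr$regions)
  expect_gte(mean(lab == sp$cell_meta$truth_region), 0.99)
})

test_that("regional composition tables normalize on both margins", {
  rc <- regional_composition(rep("A", 5), rep("x", 5))
  expect_equal(as.numeric(rc$by_region), 1)
  tr <- fx_truth()
  sp <- fx_spatial()
  rc2 <- regional_composition(sp$cell_meta$truth_region,
                              sp$cell_meta$truth_leaf)
  expect_true(all(abs(rowSums(rc2$by_region) - 1) < 1e-12))
  expect_true(all(abs(colSums(rc2$by_group) - 1) < 1e-12))
  # planted placement: each leaf concentrated in its layout region
  for (leaf in tr$leaves) {
    expect_equal(unname(rc2$by_group[tr$region_layout[[leaf]], leaf]), 1)
  }
})
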