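test_that("per-cell QC metrics match hand arithmetic and a dense oracle", {
  m <- matrix(c(5, 3, 2,
                0, 0, 0), nrow = 3,
              dimnames = list(c("gA", "gB", "mt1"), c("c1", "c2")))
  x <- count_matrix(m, gene_meta = data.frame(
    is_mito = c(FALSE, FALSE, TRUE), is_ribo = FALSE,
    row.names = c("gA", "gB", "mt1")))
  qc <- compute_qc(x)
  expect_equal(qc["c1", "n_counts"], 10)
  expect_equal(qc["c1", "n_features"], 3)
  expect_equal(qc["c1", "pct_mito"], 0.2)
  expect_equal(qc["c2", "n_counts"], 0)
  expect_equal(qc["c2", "n_features"], 0)
  expect_true(qc["c2", "all_zero"])

  x2 <- toy_counts(50, 20, seed = 11)
  qc2 <- compute_qc(x2)
  dense <- as.matrix(x2$counts)
  expect_equal(qc2$n_counts, unname(colSums(dense)))
  expect_equal(qc2$n_features, unname(colSums(dense > 0)))
})

test_that("window filtering uses strict open intervals per sample", {
  qc <- data.frame(cell_id = c("a", "b", "c"), sample = "s1",
                   n_counts = c(5000, 5000, 5000),
                   n_features = c(1200, 1201, 7800),
                   pct_mito = 0.001, pct_ribo = 0.001,
                   row.names = c("a", "b", "c"))
  w <- qc_window("s1", min_features = 1200, max_features = 7800)
  expect_identical(filter_cells(qc, list(w)), "b")   # 1200 is dropped
  expect_identical(filter_cells(qc, list(qc_window("s1"))), c("a", "b", "c"))
  expect_error(filter_cells(qc, list(qc_window("nope", min_counts = 1))),
               "unknown sample")
  expect_error(qc_window(min_features = 10, max_features = 5), "min must be")
})

test_that("window filtering equals a brute-force scan and composes", {
  qc <- compute_qc(fx_counts())[1:1000, ]
  lo <- quantile(qc$n_counts, 0.05); hi <- quantile(qc$n_counts, 0.95)
  flo <- quantile(qc$n_features, 0.05)
  kept <- filter_cells(qc, list(qc_window("all", min_counts = lo,
                                          max_counts = hi,
                                          min_features = flo)))
  brute <- qc$cell_id[qc$n_counts > lo & qc$n_counts < hi &
                        qc$n_features > flo]
  expect_identical(kept, brute)

  # two sequential windows equal the intersected window
  a <- filter_cells(qc, list(qc_window("all", min_counts = lo)))
  two <- filter_cells(qc[a, ], list(qc_window("all", max_counts = hi)))
  both <- filter_cells(qc, list(qc_window("all", min_counts = lo,
                                          max_counts = hi)))
  expect_identical(two, both)
})

test_that("spatial volume/transcript filter applies the documented windows", {
  qc <- data.frame(cell_id = sprintf("c%d", 1:5),
                   n_counts = c(100, 100, 39, 40, 100),
                   volume_um3 = c(450, 1000, 1000, 1000, 4500))
  expect_identical(filter_spatial_cells(qc), c("c2", "c4"))
  expect_identical(filter_spatial_cells(qc, 0, Inf, 0), qc$cell_id)
  qc$volume_um3[2] <- NA
  expect_error(filter_spatial_cells(qc), "missing volume")
})

test_that("sex inference scores, calls, and recovers planted sexes", {
  m <- matrix(c(20, 0,
                0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("uty", "xist"), c("c1", "c2")))
  x <- count_matrix(m)
  sx <- infer_sex(x, "uty", "xist")
  expect_equal(sx["c1", "ratio_score"], log2(21), tolerance = 1e-12)
  expect_identical(sx["c1", "call"], "male")
  expect_equal(sx["c2", "ratio_score"], 0)
  expect_identical(sx["c2", "call"], "indeterminate")
  expect_error(infer_sex(x, "uty", "nope"), "absent")

  # doubling depth preserves the score sign
  x2 <- count_matrix(m * 2)
  expect_identical(sign(infer_sex(x2, "uty", "xist")$ratio_score),
                   sign(sx$ratio_score))

  tr <- fx_truth()
  cm <- fx_counts()
  sx2 <- infer_sex(cm, tr$sex_genes$male, tr$sex_genes$female)
  known <- cm$cell_meta$truth_sex != "indeterminate"
  acc <- mean(sx2$call[known] == cm$cell_meta$truth_sex[known])
  expect_gte(acc, 0.98)
})

test_that("doublet-cluster flagging is marker-driven and monotone", {
  set.seed(3)
  m <- matrix(rpois(200, 2), 10, 20,
              dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:20)))
  m["g1", 1:10] <- 5; m["g1", 11:20] <- 0   # cluster A expresses the marker
  x <- count_matrix(m)
  labels <- rep(c("A", "B"), each = 10)
  expect_identical(flag_doublet_clusters(x, labels, "g1", 0.5), "A")
  expect_identical(flag_doublet_clusters(x, labels, "absent", 0.5),
                   character(0))
  lo <- flag_doublet_clusters(x, labels, "g1", 0.1)
  expect_true(all(flag_doublet_clusters(x, labels, "g1", 0.5) %in% lo))

  tr <- fx_truth()
  cl <- fx_clustering()
  flagged <- flag_doublet_clusters(fx_counts(), cl$labels,
                                   tr$doublet_spec$markers)
  maj <- majority_leaf(cl$labels, fx_counts()$cell_meta$truth_leaf)
  expect_setequal(names(maj)[maj == "doublet"], flagged)
})
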