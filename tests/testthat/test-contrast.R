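test_that("scoped genotype DE finds planted effects with correct signs", {
  tr <- fx_truth()
  cm <- fx_counts()
  nr <- fx_norm()
  de <- condition_de(nr, cm$cell_meta$genotype)
  expect_identical(de$conditions, c("control", "mutant"))
  planted <- de$table[de$table$gene %in% tr$genotype_effects$gene, ]
  expect_gte(sum(planted$p_adj < 0.05), 8)   # 10 planted doubled genes
  # control vs mutant: up-in-mutant genes get negative log2fc
  expect_true(all(planted$log2fc[planted$p_adj < 0.05] < 0))
  expect_true(is.character(de$pseudoreplication_warning))
  expect_error(condition_de(nr, rep("control", ncol(nr$norm))),
               "exactly 2 conditions")
})

test_that("swapping condition labels negates the fold changes", {
  cm <- fx_counts()
  nr <- fx_norm()
  sub <- 1:400
  cond <- cm$cell_meta$genotype[sub]
  d1 <- condition_de(nr$norm[, sub], cond)
  # renaming flips the sort order of the levels, i.e. swaps A and B
  d2 <- condition_de(nr$norm[, sub],
                     ifelse(cond == "control", "z_ctrl", "a_mut"))
  m <- match(d1$table$gene, d2$table$gene)
  expect_equal(d1$table$log2fc, -d2$table$log2fc[m], tolerance = 1e-12)
})

test_that("shared DE overlap is exact set algebra", {
  mk <- function(genes, p) list(table = data.frame(gene = genes, p_adj = p))
  a <- mk(c("g1", "g2", "g3"), c(0.01, 0.01, 0.5))
  b <- mk(c("g2", "g4"), c(0.01, 0.01))
  ov <- shared_de(a, b)
  expect_identical(ov$shared, "g2")
  expect_identical(ov$only_a, "g1")
  expect_identical(ov$only_b, "g4")
  expect_equal(shared_de(a, a)$n_shared, 2)
  disj <- shared_de(mk("g1", 0.01), mk("g2", 0.01))
  expect_equal(disj$n_shared, 0)
})

test_that("proportion shifts: null is flat, planted shift detected, exact toy", {
  set.seed(12)
  labels <- sample(letters[1:4], 800, replace = TRUE)
  cond <- rep(c("wt", "mut"), 400)
  null <- proportion_shift(labels, cond, n_perm = 300, seed = 1)
  expect_true(all(null$p_adj > 0.05))

  # plant cluster "a" at twice the frequency in one condition
  lab2 <- c(sample(c("a", "b", "c"), 2000, TRUE, prob = c(.5, .25, .25)),
            sample(c("a", "b", "c"), 2000, TRUE, prob = c(.25, .375, .375)))
  cond2 <- rep(c("mut", "wt"), each = 2000)
  ps <- proportion_shift(lab2, cond2, n_perm = 500, seed = 2)
  expect_lt(ps$p_adj[ps$cluster == "a"], 0.05)

  # exhaustive enumeration oracle on a 10-cell toy
  lab3 <- c("a", "a", "a", "b", "b", "a", "b", "b", "b", "a")
  cond3 <- rep(c("x", "y"), each = 5)
  ps3 <- proportion_shift(lab3, cond3, n_perm = 4000, seed = 3)
  combos <- combn(10, 5)
  d_obs <- abs(mean(lab3[1:5] == "a") - mean(lab3[6:10] == "a"))
  d_all <- apply(combos, 2, function(ix)
    abs(mean(lab3[ix] == "a") - mean(lab3[-ix] == "a")))
  exact <- mean(d_all >= d_obs - 1e-12)
  expect_equal(ps3$p[ps3$cluster == "a"], exact, tolerance = 0.03)
})

test_that("similarity gene selection is idempotent and bin-aware", {
  cm <- fx_counts()
  half1 <- cm[, 1:1500]; half2 <- cm[, 1501:3000]
  one <- select_similarity_genes(list(half1))
  dup <- select_similarity_genes(list(half1, half1))
  expect_identical(one, dup)

  # top-decile genes never selected
  mu <- Matrix::rowMeans(half1$counts)
  top <- rownames(half1$counts)[rank(mu, ties.method = "first") >
                                  0.9 * length(mu)]
  expect_false(any(one %in% top))

  # brute-force oracle on a 300-gene toy
  set.seed(13)
  m <- matrix(rnbinom(300 * 80, mu = rexp(300, 0.2), size = 1), 300,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("c%02d", 1:80)))
  x <- count_matrix(m)
  sel <- select_similarity_genes(list(x), n_bins = 10)
  mu2 <- rowMeans(m); v2 <- apply(m, 1, var)
  disp <- ifelse(mu2 > 0, v2 / mu2, 0)
  bin <- as.integer(ceiling(rank(mu2, ties.method = "first") / 30))
  brute <- unlist(lapply(1:9, function(b) {
    idx <- bin == b
    rownames(m)[idx][disp[idx] > median(disp[idx])]
  }))
  expect_setequal(sel, brute)
})

test_that("neighbour-voting AUROC is rank-invariant with matched diagonal", {
  cm <- fx_counts()
  nr <- fx_norm()
  truth <- cm$cell_meta$truth_leaf
  keep <- truth != "doublet"
  idx_a <- which(keep)[1:600]
  idx_b <- which(keep)[601:1200]
  genes <- fx_truth()$marker_table$gene
  sm <- cluster_similarity(nr$norm[, idx_a], truth[idx_a],
                           nr$norm[, idx_b], truth[idx_b], genes)
  expect_true(all(sm$auroc >= 0 & sm$auroc <= 1, na.rm = TRUE))
  # self-similarity structure: argmax of each B row is the same leaf
  for (b in rownames(sm$auroc))
    expect_identical(names(which.max(sm$auroc[b, ])), b)

  # invariance under a monotone per-cell transform (Spearman)
  mono <- nr$norm[, idx_b]
  mono@x <- exp(mono@x)
  sm2 <- cluster_similarity(nr$norm[, idx_a], truth[idx_a],
                            mono, truth[idx_b], genes)
  expect_equal(sm$auroc, sm2$auroc, tolerance = 1e-12)

  # single-cell cluster gives NA
  lab_b <- truth[idx_b]
  lab_b[1] <- "solo"
  sm3 <- cluster_similarity(nr$norm[, idx_a], truth[idx_a],
                            nr$norm[, idx_b], lab_b, genes)
  expect_true(all(is.na(sm3$auroc["solo", ])))
})
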