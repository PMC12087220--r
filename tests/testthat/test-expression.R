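test_that("cell QC applies inclusive count and gene thresholds", {
  # cell a: 999 counts over many genes; cell b: exactly 1000 over exactly
  # 100 genes; cell c: plenty
  m <- matrix(0L, 120, 3,
              dimnames = list(sprintf("g%03d", 1:120), c("a", "b", "c")))
  m[1:111, "a"] <- 9L               # 999 counts, 111 genes
  m[1:100, "b"] <- 10L              # 1000 counts, 100 genes
  m[, "c"] <- 50L
  kept <- suppressMessages(filter_cells(m))
  expect_identical(colnames(kept), c("b", "c"))
  expect_identical(rownames(kept), rownames(m))
  # idempotent
  expect_identical(suppressMessages(filter_cells(kept)), kept)
  # everything below threshold: empty result plus warning
  low <- m[, "a", drop = FALSE]
  expect_warning(res <- suppressMessages(filter_cells(low)), "all cells")
  expect_identical(ncol(res), 0L)
})

test_that("pseudo-bulk sums cells and TMM normalization behaves", {
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  bulk <- c(g1 = 5, g2 = 5)
  res <- pseudobulk_and_normalize(m, bulk)
  expect_equal(unname(res$pseudobulk), c(3, 7))
  # identical libraries: both factors 1
  b2 <- matrix(c(3, 7), 2, 1, dimnames = list(c("g1", "g2"), "bulk"))
  res2 <- pseudobulk_and_normalize(m, b2)
  expect_equal(unname(res2$norm_factors), c(1, 1), tolerance = 1e-12)
  # a pure 3x library rescaling leaves normalized CPMs unchanged
  set.seed(1)
  genes <- sprintf("g%03d", 1:400)
  cellm <- matrix(rpois(400 * 10, 30), 400, 10,
                  dimnames = list(genes, sprintf("c%02d", 1:10)))
  pseudo <- rowSums(cellm)
  bulk3 <- matrix(3 * pseudo, ncol = 1, dimnames = list(genes, "bulk"))
  res3 <- pseudobulk_and_normalize(cellm, bulk3)
  expect_equal(res3$cpm[, "pseudobulk"], res3$cpm[, "bulk"],
               tolerance = 1e-9)
  # geometric mean of factors is 1
  expect_equal(exp(mean(log(res3$norm_factors))), 1, tolerance = 1e-9)
  # zero library is refused by name
  bad <- matrix(0, 400, 1, dimnames = list(genes, "empty_bulk"))
  expect_error(pseudobulk_and_normalize(cellm, bad), "empty_bulk")
})

test_that("clr and the divergence test satisfy their contracts", {
  expect_equal(clr(c(1, 1, 1, 1)), c(0, 0, 0, 0))
  expect_error(clr(c(1, 0, 2)), "positive")
  # pseudo identical to bulk: zero residuals, nothing flagged
  x <- stats::setNames(exp(rnorm(50, 5)), sprintf("g%02d", 1:50))
  rep0 <- clr_divergence(x, x, toxin_ids = names(x)[1:5])
  expect_equal(unname(rep0$residuals), rep(0, 50), tolerance = 1e-10)
  expect_false(any(rep0$flags))
  expect_lt(rep0$interval[1], rep0$interval[2] + 1e-15)
  expect_equal(sum(rep0$clr_pseudobulk), 0, tolerance = 1e-8)
  expect_error(clr_divergence(x[1:9], x[1:9], character()), "10 non-toxin")
})

test_that("divergence null calibration flags ~1% of null genes", {
  set.seed(42)
  n <- 5000
  genes <- c(sprintf("n%04d", 1:n), "toxin_hot")
  base <- rnorm(n + 1, 0, 2)
  noise <- rnorm(n + 1, 0, 0.5)
  bulk <- exp(base)
  pseudo <- exp(base + noise)
  pseudo[n + 1] <- exp(base[n + 1] + 8)  # planted far-out toxin
  names(bulk) <- names(pseudo) <- genes
  rep <- clr_divergence(pseudo, bulk, toxin_ids = "toxin_hot")
  expect_true(rep$flags[["toxin_hot"]])
  out_frac <- mean(rep$residuals[sprintf("n%04d", 1:n)] < rep$interval[1] |
                     rep$residuals[sprintf("n%04d", 1:n)] > rep$interval[2])
  expect_gt(out_frac, 0.005)
  expect_lt(out_frac, 0.015)
})

test_that("divergence flags are invariant to gene order", {
  set.seed(7)
  genes <- sprintf("g%03d", 1:200)
  bulk <- stats::setNames(exp(rnorm(200, 4)), genes)
  pseudo <- stats::setNames(bulk * exp(rnorm(200, 0, 0.3)), genes)
  tox <- genes[1:20]
  r1 <- clr_divergence(pseudo, bulk, tox)
  perm <- sample(genes)
  r2 <- clr_divergence(pseudo[perm], bulk[perm], tox)
  expect_equal(r1$flags[tox], r2$flags[tox])
})

test_that("clustering separates well-split populations and is deterministic", {
  set.seed(5)
  n_per <- 100
  genes <- sprintf("g%03d", 1:60)
  a <- matrix(rpois(60 * n_per, 5), 60, n_per)
  a[1:20, ] <- a[1:20, ] + matrix(rpois(20 * n_per, 200), 20)
  b <- matrix(rpois(60 * n_per, 5), 60, n_per)
  b[41:60, ] <- b[41:60, ] + matrix(rpois(20 * n_per, 200), 20)
  m <- cbind(a, b)
  dimnames(m) <- list(genes, sprintf("c%03d", 1:(2 * n_per)))
  truth <- rep(1:2, each = n_per)
  cl <- cluster_cells(m, seed = 1)
  expect_equal(ari(cl, truth), 1)
  expect_identical(cl, cluster_cells(m, seed = 1))
  # degenerate input: all cells identical -> one community
  same <- matrix(5L, 30, 40, dimnames = list(sprintf("g%02d", 1:30),
                                             sprintf("c%02d", 1:40)))
  expect_identical(unique(unname(cluster_cells(same, k_neighbors = 5))), 0L)
  expect_error(cluster_cells(m, k_neighbors = 500), "k_neighbors")
})

test_that("toxin-cell classification applies both cluster thresholds", {
  genes <- c("T1", "T2", "LAMA3", "EPCAM", "H1", "H2")
  secretory <- matrix(c(30, 30, 3, 3, 20, 14), 6, 20,
                      dimnames = list(genes, sprintf("s%02d", 1:20)))
  other <- matrix(c(0, 0, 0, 0, 60, 40), 6, 20,
                  dimnames = list(genes, sprintf("o%02d", 1:20)))
  m <- cbind(secretory, other)
  cl <- stats::setNames(rep(c(0L, 1L), each = 20), colnames(m))
  ann <- classify_toxin_cells(m, cl, c("LAMA3", "EPCAM"), c("T1", "T2"))
  expect_true(all(ann$is_toxin_cell[1:20]))
  expect_false(any(ann$is_toxin_cell[21:40]))
  expect_true(all(ann$toxin_fraction >= 0 & ann$toxin_fraction <= 1))
  # no toxin expression anywhere: no toxin cells
  m0 <- m; m0[c("T1", "T2"), ] <- 0
  ann0 <- classify_toxin_cells(m0, cl, c("LAMA3", "EPCAM"), c("T1", "T2"))
  expect_false(any(ann0$is_toxin_cell))
  expect_error(classify_toxin_cells(m, cl, "NOPE", "T1"), "NOPE")
})

test_that("spearman co-expression matches rank identities and the oracle", {
  # filler gene keeps library sizes equal so CPM preserves the raw ranks
  m <- matrix(c(1, 3, 6,
                2, 1, 7,
                3, 2, 5), 3, 3, byrow = TRUE,
              dimnames = list(c("x", "y", "filler"), c("c1", "c2", "c3")))
  # x = (1,2,3), y = (3,1,2) across cells
  rho <- spearman_coexpression(m)
  expect_equal(unname(rho["x", "y"]), -0.5, tolerance = 1e-12)
  # filler equalizes library sizes so CPM keeps the stated orderings
  mono <- matrix(c(1, 2, 3, 4,
                   2, 4, 9, 20,
                   20, 9, 4, 2,
                   5, 5, 5, 5,
                   12, 20, 19, 9), 5, 4, byrow = TRUE,
                 dimnames = list(c("a", "up", "down", "flat", "fill"),
                                 sprintf("c%d", 1:4)))
  stopifnot(length(unique(colSums(mono))) == 1)
  expect_warning(r2 <- spearman_coexpression(mono), "constant")
  expect_equal(unname(r2["a", "up"]), 1)
  expect_equal(unname(r2["up", "down"]), -1)
  expect_true(all(is.na(r2["flat", ])))
  # brute-force oracle: rank then Pearson on log1p-CPM
  for (s in 1:5) {
    cm <- random_counts(10, 20, seed = 40 + s)
    got <- spearman_coexpression(cm)
    lc <- log1p(sweep(cm, 2, colSums(cm), "/") * 1e6)
    ranks <- apply(t(lc), 2, rank)
    want <- cor(ranks)
    expect_equal(unclass(got), want, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_error(spearman_coexpression(m[, 1:2]), "3 cells")
})
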