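# helper: build a 2-gene expression matrix with an exactly known correlation
expr_with_cor <- function(r, n = 40, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  z <- stats::residuals(lm(rnorm(n) ~ x))
  z <- scale(z)[, 1]
  y <- r * x + sqrt(1 - r^2) * z
  rbind(g1 = x, g2 = y)
}

test_that("adjacency implements the soft-threshold transforms", {
  e <- expr_with_cor(1)
  e[2, ] <- e[1, ]
  expect_equal(unname(adjacency_matrix(e, 6)[1, 2]), 1, tolerance = 1e-12)
  e0 <- expr_with_cor(0, seed = 3)
  expect_equal(unname(adjacency_matrix(e0, 6)[1, 2]), 0, tolerance = 1e-10)
  em <- expr_with_cor(-0.5, seed = 4)
  a <- adjacency_matrix(em, 2)
  expect_equal(unname(a[1, 2]), 0.25, tolerance = 1e-10)
  expect_equal(unname(diag(a)), c(0, 0))
  s <- adjacency_matrix(em, 2, signed = TRUE)
  expect_equal(unname(s[1, 2]), ((1 - 0.5) / 2)^2, tolerance = 1e-10)
  e_const <- rbind(g1 = rnorm(20), g2 = rep(1, 20))
  expect_warning(ac <- adjacency_matrix(e_const, 2), "constant")
  expect_equal(unname(ac[1, 2]), 0)
  expect_error(adjacency_matrix(rbind(a = rep(1, 10), b = rep(2, 10)), 2),
               "constant")
  expect_error(adjacency_matrix(e, 0.5), ">= 1")
})

test_that("topological overlap matches its defining formula", {
  # empty graph
  z <- matrix(0, 4, 4)
  expect_true(all(tom_similarity(z)[upper.tri(z)] == 0))
  # saturated complete graph
  ones <- matrix(1, 5, 5); diag(ones) <- 0
  expect_true(all(abs(tom_similarity(ones) - 1) < 1e-12))
  # worked triangle: a12 = a13 = a23 = 0.5 -> TOM12 = 0.75 / 1.5 = 0.5
  tri <- matrix(0.5, 3, 3); diag(tri) <- 0
  expect_equal(unname(tom_similarity(tri)[1, 2]), 0.5, tolerance = 1e-12)
  # random adjacencies vs the direct-formula oracle
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(runif(100), 10, 10)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    got <- tom_similarity(a)
    expect_equal(got, oracle_tom(a), tolerance = 1e-12)
    expect_true(isSymmetric(got))
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
  }
  bad <- matrix(runif(9), 3, 3); diag(bad) <- 0
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("soft-threshold selection reports fits and falls back with warning", {
  sim <- planted_block_expr(c(30, 30), 60, seed = 2)
  # singleton power list: that power is chosen and reported
  one <- suppressWarnings(pick_soft_threshold(sim$expr, powers_tested = 6))
  expect_identical(one$power, 6)
  expect_identical(nrow(one$table), 1L)
  expect_true(one$table$r2 >= 0 && one$table$r2 <= 1)
  # independent straight-line-fit oracle for the R^2 table
  res <- suppressWarnings(pick_soft_threshold(sim$expr, powers_tested = c(2, 6)))
  for (i in seq_len(nrow(res$table))) {
    b <- res$table$power[i]
    a <- abs(cor(t(sim$expr)))^b
    diag(a) <- 0
    k <- rowSums(a)
    breaks <- unique(quantile(k, seq(0, 1, 0.1)))
    bin <- cut(k, breaks, include.lowest = TRUE)
    pk <- as.numeric(table(bin)) / length(k)
    km <- tapply(k, bin, mean)
    keep <- pk > 0 & !is.na(km)
    if (sd(log10(pk[keep])) == 0) {
      r2 <- 0
    } else {
      fit <- lm(log10(pk[keep]) ~ log10(km[keep]))
      r2 <- cor(log10(km[keep]), log10(pk[keep]))^2
      if (coef(fit)[2] > 0) r2 <- 0
    }
    expect_equal(res$table$r2[i], unname(r2), tolerance = 1e-8)
  }
  # a target nothing reaches triggers the fallback warning
  expect_warning(fb <- pick_soft_threshold(sim$expr, powers_tested = 1:3,
                                           target_r2 = 0.999),
                 "no power")
  expect_identical(fb$power, fb$table$power[which.max(fb$table$r2)])
  expect_error(pick_soft_threshold(sim$expr[1:10, ]), ">= 30 genes")
})

test_that("module detection recovers planted blocks and applies the size rule", {
  sim <- planted_block_expr(c(40, 40), 200, n_noise = 0, seed = 8)
  a <- adjacency_matrix(sim$expr, 6)
  part <- detect_modules(tom_similarity(a))
  expect_identical(sort(unique(unname(part$assignment))), c("M1", "M2"))
  expect_equal(ari(part$assignment, sim$truth), 1)
  # 20 mutually uncorrelated genes, min size 30: all unassigned
  noise <- planted_block_expr(integer(0), 100, n_noise = 20, seed = 9)
  pn <- suppressWarnings(
    detect_modules(tom_similarity(adjacency_matrix(noise$expr, 6))))
  expect_true(all(pn$assignment == "unassigned"))
  # one block of 29 correlated genes is below the minimum size
  b29 <- planted_block_expr(29, 100, n_noise = 15, seed = 10)
  p29 <- detect_modules(tom_similarity(adjacency_matrix(b29$expr, 6)))
  expect_true(all(p29$assignment[b29$truth == 1] == "unassigned"))
})

test_that("eigengenes and kME follow the principal-component contract", {
  # identical standardized profiles: eigengene is that profile, kME = 1
  base <- rnorm(30)
  expr <- do.call(rbind, replicate(5, base + 0, simplify = FALSE))
  rownames(expr) <- sprintf("g%d", 1:5)
  colnames(expr) <- sprintf("s%d", 1:30)
  part <- structure(list(assignment = stats::setNames(rep("M1", 5),
                                                      rownames(expr))),
                    class = "module_partition")
  filled <- eigengenes_and_membership(expr, part)
  expect_equal(abs(cor(filled$eigengenes["M1", ], base)), 1,
               tolerance = 1e-10)
  expect_equal(unname(filled$kme[, "M1"]), rep(1, 5), tolerance = 1e-10)
  expect_equal(sd(filled$eigengenes["M1", ]), 1, tolerance = 1e-10)
  # a gene orthogonal to the eigengene has kME 0
  ortho <- stats::residuals(lm(rnorm(30) ~ filled$eigengenes["M1", ]))
  expr2 <- rbind(expr, g6 = ortho)
  part2 <- structure(list(assignment = stats::setNames(
    c(rep("M1", 5), "unassigned"), rownames(expr2))),
    class = "module_partition")
  filled2 <- eigengenes_and_membership(expr2, part2)
  expect_equal(unname(filled2$kme["g6", "M1"]), 0, tolerance = 1e-10)
  # kME equals the direct per-pair Pearson oracle
  sim <- planted_block_expr(c(10, 10), 40, seed = 12)
  p3 <- detect_modules(tom_similarity(adjacency_matrix(sim$expr, 6)),
                       min_module_size = 5)
  f3 <- eigengenes_and_membership(sim$expr, p3)
  for (m in rownames(f3$eigengenes)) {
    for (g in sample(rownames(sim$expr), 5)) {
      expect_equal(f3$kme[g, m], cor(sim$expr[g, ], f3$eigengenes[m, ]),
                   tolerance = 1e-10)
    }
  }
  expect_error(eigengenes_and_membership(expr[, 1, drop = FALSE], part),
               "one sample")
})

test_that("module merging honours the eigengene dissimilarity cut", {
  set.seed(3)
  n <- 60
  driver <- rnorm(n)
  near <- driver * 0.95 + rnorm(n, 0, sqrt(1 - 0.95^2))  # cor ~ 0.95
  far <- rnorm(n)                                          # cor ~ 0
  mk <- function(base, k, tag) {
    m <- do.call(rbind, lapply(seq_len(k), function(i)
      base + rnorm(n, 0, 0.1)))
    rownames(m) <- paste0(tag, seq_len(k))
    m
  }
  expr <- rbind(mk(driver, 10, "a"), mk(near, 10, "b"), mk(far, 10, "c"))
  colnames(expr) <- sprintf("s%02d", seq_len(n))
  part <- structure(list(assignment = stats::setNames(
    rep(c("M1", "M2", "M3"), each = 10), rownames(expr))),
    class = "module_partition")
  merged <- merge_modules(expr, part, merge_dissimilarity = 0.2)
  # the two highly correlated modules merged, the unrelated one did not
  mods <- merged$assignment
  expect_identical(length(unique(mods)), 2L)
  expect_identical(unique(mods[paste0("a", 1:10)]),
                   unique(mods[paste0("b", 1:10)]))
  expect_false(unique(mods[paste0("c", 1:10)]) ==
                 unique(mods[paste0("a", 1:10)]))
  # fixed point: no remaining pair below the cut
  d <- 1 - cor(t(merged$eigengenes))
  diag(d) <- Inf
  expect_true(min(d) >= 0.2)
  # merging never shrinks a module below its constituents' union
  expect_identical(sum(mods == unique(mods[paste0("a", 1:10)])), 20L)
})

test_that("module-trait correlation matches the correlation-test oracle", {
  sim <- planted_block_expr(c(12, 12), 50, seed = 20)
  part <- detect_modules(tom_similarity(adjacency_matrix(sim$expr, 6)),
                         min_module_size = 5)
  filled <- eigengenes_and_membership(sim$expr, part)
  trait <- filled$eigengenes[1, ]
  mt <- module_trait_correlation(filled$eigengenes, trait)
  expect_equal(mt$r[1], 1, tolerance = 1e-10)
  for (i in seq_len(nrow(mt))) {
    ct <- cor.test(filled$eigengenes[mt$module[i], ], trait)
    expect_equal(mt$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(mt$p[i], ct$p.value, tolerance = 1e-10)
  }
  expect_error(module_trait_correlation(filled$eigengenes, rep(1, 50)),
               "zero variance")
  expect_error(module_trait_correlation(filled$eigengenes, trait[1:10]),
               "length")
})
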