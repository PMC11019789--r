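# Rarefaction, Bray-Curtis, PCoA, ANOSIM, phase comparisons.

test_that("rarefaction hits the target depth exactly and deterministically", {
  set.seed(2)
  m <- matrix(rpois(60, 400), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  depth <- min(colSums(m)) - 10
  r1 <- rarefy(m, depth, seed = 5)
  r2 <- rarefy(m, depth, seed = 5)
  expect_identical(unclass(r1), unclass(r2))
  expect_true(all(colSums(r1) == depth))
  expect_true(all(r1 <= m))
  # a column already at depth is untouched
  m2 <- m; m2[, 1] <- m2[, 1] * 0; m2[1, 1] <- depth
  expect_equal(rarefy(m2, depth, seed = 1)[, 1], m2[, 1])
  expect_error(rarefy(m, max(colSums(m)) + 1, seed = 1), "below rarefaction depth")
})

test_that("rarefying a 10,000-read sample to 9,450 leaves exactly 9,450 reads", {
  set.seed(9)
  col <- rmultinom(1, 10000, prob = runif(50))
  m <- cbind(col, col)
  dimnames(m) <- list(paste0("f", 1:50), c("s1", "s2"))
  r <- rarefy(m, 9450, seed = 1)
  expect_identical(unname(colSums(r)), c(9450, 9450))
})

test_that("Bray-Curtis matches the closed form and the vegan oracle", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(bray_curtis(m)["a", "b"], 1.0)
  ident <- matrix(c(3, 4, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(bray_curtis(ident)["a", "b"], 0.0)
  m3 <- matrix(c(2, 2, 1, 3), 2, 2, dimnames = list(NULL, c("x", "y")))
  expect_equal(bray_curtis(m3)["x", "y"], 0.25)
  skip_if_not_installed("vegan")
  set.seed(31)
  rnd <- matrix(rpois(80, 20), 8, 10,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  expect_equal(bray_curtis(rnd),
               as.matrix(vegan::vegdist(t(rnd), method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rarefied Bray-Curtis is invariant to joint feature permutation", {
  set.seed(13)
  m <- matrix(rpois(120, 100), 12, 10,
              dimnames = list(paste0("f", 1:12), paste0("s", 1:10)))
  r <- rarefy(m, min(colSums(m)), seed = 2)
  perm <- sample(12)
  expect_equal(bray_curtis(r), bray_curtis(r[perm, ]))
})

test_that("PCoA recovers collinear geometry and reconstructs Euclidean input", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  ord <- pcoa(d)
  expect_length(ord$eigenvalues, 1L)
  expect_equal(ord$eigenvalues, 2, tolerance = 1e-10)
  coords <- ord$coordinates[, 1]
  expect_equal(sort(coords), c(-1, 0, 1), tolerance = 1e-10)
  # reconstruction: random 2-D point clouds
  set.seed(17)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    dd <- as.matrix(dist(pts))
    rec <- pcoa(dd)$coordinates
    expect_equal(as.matrix(dist(rec)), dd, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # equidistant triangle: two equal positive eigenvalues
  deq <- matrix(1, 3, 3) - diag(3)
  eq <- pcoa(deq)
  expect_length(eq$eigenvalues, 2L)
  expect_equal(eq$eigenvalues[1], eq$eigenvalues[2], tolerance = 1e-10)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA agrees with cmdscale on non-Euclidean dissimilarities", {
  set.seed(23)
  m <- matrix(rpois(60, 30), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  d <- bray_curtis(m)
  ord <- pcoa(d)
  ref <- cmdscale(as.dist(d), k = 2, eig = TRUE)
  expect_equal(ord$eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-8)
  expect_equal(abs(ord$coordinates[, 1:2]), abs(ref$points),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ANOSIM statistic hits its extremes and matches vegan", {
  # all between-distances exceed all within-distances -> R = 1
  pts <- c(seq(0, 0.4, 0.1), seq(10, 10.4, 0.1))
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 5)
  an <- anosim(d, g, n_permutations = 999, seed = 1)
  expect_equal(an$R, 1)
  expect_lt(an$p, 0.05)
  # all distances equal -> R = 0
  deq <- matrix(1, 10, 10) - diag(10)
  expect_equal(anosim(deq, g, n_permutations = 99, seed = 1)$R, 0)
  expect_error(anosim(d, c("a", rep("b", 9)), 99, 1), ">= 2 members")
  skip_if_not_installed("vegan")
  set.seed(41)
  rnd <- matrix(rpois(80, 20), 8, 10,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  db <- bray_curtis(rnd)
  grp <- rep(c("x", "y"), 5)
  expect_equal(anosim(db, grp, n_permutations = 99, seed = 1)$R,
               as.numeric(vegan::anosim(as.dist(db), grp, permutations = 0)$statistic),
               tolerance = 1e-12)
})

test_that("ANOSIM R stays in [-1, 1] and p in (0, 1] on random inputs", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(c(8, 10, 12), 1)
    d <- as.matrix(dist(rnorm(n)))
    g <- sample(rep(c("a", "b"), n / 2))
    an <- anosim(d, g, n_permutations = 49, seed = i)
    expect_gte(an$R, -1); expect_lte(an$R, 1)
    expect_gt(an$p, 0); expect_lte(an$p, 1)
  }
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(1), 1)
  expect_equal(bonferroni(0.2), 0.2)
})

test_that("phase comparison flags only phases with a real shift", {
  grid <- expand.grid(treatment = c("control", "CIF", "HIF"),
                      replicate = c("I", "II", "III"), day = 0:7,
                      stringsAsFactors = FALSE)
  set.seed(61)
  grid$cells_per_ml <- 1e6 * exp(rnorm(nrow(grid), sd = 0.05))
  grid$particles_per_ml <- 2e6 * exp(rnorm(nrow(grid), sd = 0.05))
  shift <- grid$treatment == "HIF" & grid$day >= 2
  grid$particles_per_ml[shift] <- grid$particles_per_ml[shift] + 5e6
  res <- phase_compare(cytometry_counts(grid), "particles")
  hif <- res[res$treatment_b == "HIF" | res$treatment_a == "HIF", ]
  expect_true(all(hif$significant[hif$phase %in% c("middle", "late")]))
  expect_false(any(hif$significant[hif$phase == "early"]))
  # identical treatments: nothing flagged
  res_cells <- phase_compare(cytometry_counts(grid), "cells")
  expect_false(any(res_cells$significant))
})
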