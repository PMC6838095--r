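test_that("phylogenetic covariance has shared-path structure", {
  # star tree: no shared history
  star <- ape::stree(4, "star")
  star$edge.length <- rep(3, 4)
  expect_equal(unname(phylo_covariance(star)), 3 * diag(4))

  tr <- read_timetree("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)
  # PSD: Cholesky exists
  expect_silent(chol(C))
})

test_that("kmult matches an explicit matrix-algebra oracle for one trait", {
  tr <- read_timetree("((A:1,B:1):1.5,(C:2,D:2):0.5);")
  x <- c(A = 0.3, B = -0.2, C = 1.7, D = 2.4)
  k <- kmult(tr, x, n_perm = 0)
  expect_equal(k$K, oracle_classic_K(tr, x), tolerance = 1e-10)

  # also on a tree with a fossil (non-contemporaneous) tip
  tr2 <- read_timetree("((A:1,B:0.4):1.5,(C:2,D:2):0.5);")
  x2 <- c(A = -1.1, B = 0.9, C = 0.25, D = 0.6)
  expect_equal(kmult(tr2, x2, n_perm = 0)$K, oracle_classic_K(tr2, x2),
               tolerance = 1e-10)
})

test_that("kmult is invariant to rotation and scaling of the trait matrix", {
  tr <- simulate_tree(24, 0, seed = 31)
  Y <- as.matrix(simulate_bm(tr, 1, n_traits = 4, seed = 32)[, -1])
  rownames(Y) <- tr$tip.label
  K0 <- kmult(tr, Y, n_perm = 0)$K
  expect_equal(kmult(tr, 3.7 * Y, n_perm = 0)$K, K0, tolerance = 1e-12)
  set.seed(33)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(kmult(tr, Y %*% Q, n_perm = 0)$K, K0, tolerance = 1e-10)
})

test_that("kmult permutation p-values are seeded and bounded below", {
  tr <- simulate_tree(20, 0, seed = 41)
  Y <- simulate_bm(tr, 1, n_traits = 2, seed = 42)
  k1 <- kmult(tr, Y, n_perm = 99, seed = 7)
  k2 <- kmult(tr, Y, n_perm = 99, seed = 7)
  expect_identical(k1$p_value, k2$p_value)
  expect_gte(k1$p_value, 1 / 100)
  expect_error(kmult(tr, rep(1, 20)), "constant|degenerate")
})

test_that("shuffled tip data lose phylogenetic signal", {
  tr <- simulate_tree(40, 0, seed = 51)
  ks <- sapply(1:20, function(i) {
    Y <- as.matrix(simulate_bm(tr, 1, n_traits = 3, seed = 100 + i)[, -1])
    rownames(Y) <- tr$tip.label
    set.seed(200 + i)
    Yp <- Y[sample(nrow(Y)), , drop = FALSE]
    rownames(Yp) <- tr$tip.label
    c(bm = kmult(tr, Y, n_perm = 0)$K, shuf = kmult(tr, Yp, n_perm = 0)$K)
  })
  expect_lt(median(ks["shuf", ]), median(ks["bm", ]))
  # BM data should usually reject the no-signal null
  ps <- sapply(1:10, function(i) {
    Y <- simulate_bm(tr, 1, n_traits = 3, seed = 300 + i)
    kmult(tr, Y, n_perm = 99, seed = i)$p_value
  })
  expect_gt(mean(ps <= 0.05), 0.5)
})

test_that("D-PGLS: perfect allometry gives r2 = 1; star tree equals OLS", {
  tr <- simulate_tree(16, 0, seed = 61)
  x <- simulate_bm(tr, 1, seed = 62)$trait1
  names(x) <- tr$tip.label
  B <- c(0.5, -2, 1)
  Y <- outer(x, B)
  rownames(Y) <- tr$tip.label
  expect_equal(dpgls_shape_size(tr, Y, x, n_perm = 0)$r2, 1, tolerance = 1e-10)

  star <- ape::stree(10, "star")
  star$edge.length <- rep(2, 10)
  set.seed(63)
  xs <- rnorm(10)
  Ys <- outer(xs, B) + matrix(rnorm(30, 0, 0.6), 10)
  names(xs) <- star$tip.label
  rownames(Ys) <- star$tip.label
  r2_pgls <- dpgls_shape_size(star, Ys, xs, n_perm = 0)$r2
  rss_full <- sum(stats::lm.fit(cbind(1, xs), Ys)$residuals^2)
  rss_red <- sum(stats::lm.fit(matrix(1, 10), Ys)$residuals^2)
  expect_equal(r2_pgls, 1 - rss_full / rss_red, tolerance = 1e-10)
})

test_that("r2 never decreases when pure-noise predictors are added", {
  tr <- simulate_tree(20, 0, seed = 71)
  Y <- as.matrix(simulate_bm(tr, 1, n_traits = 4, seed = 72)[, -1])
  x <- as.matrix(simulate_bm(tr, 1, seed = 73)[, -1])
  rownames(Y) <- rownames(x) <- tr$tip.label
  r1 <- dpgls_shape_size(tr, Y, x, n_perm = 0)$r2
  set.seed(74)
  for (q in 1:3) {
    x <- cbind(x, rnorm(20))
    rownames(x) <- tr$tip.label
    r2 <- dpgls_shape_size(tr, Y, x, n_perm = 0)$r2
    expect_gte(r2 + 1e-12, r1)
    r1 <- r2
  }
})

test_that("D-PGLS permutation p is seeded and reproducible", {
  tr <- simulate_tree(18, 0, seed = 81)
  Y <- simulate_bm(tr, 1, n_traits = 3, seed = 82)
  x <- simulate_bm(tr, 1, seed = 83)
  d1 <- dpgls_shape_size(tr, Y, x, n_perm = 99, seed = 5)
  d2 <- dpgls_shape_size(tr, Y, x, n_perm = 99, seed = 5)
  expect_identical(d1$p_value, d2$p_value)
  expect_true(d1$r2 >= 0 && d1$r2 <= 1)
})
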