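test_that("BM likelihood: closed-form value and location invariance", {
  tr <- read_timetree("(A:1,B:1);")
  f <- bm_loglik(tr, c(A = 0, B = 0), sigma2 = 1)
  expect_equal(f$log_lik, -log(2 * pi), tolerance = 1e-12)

  tr2 <- simulate_tree(12, 0, seed = 3)
  x <- simulate_bm(tr2, 1, seed = 4)$trait1
  names(x) <- tr2$tip.label
  expect_equal(bm_loglik(tr2, x)$log_lik, bm_loglik(tr2, x + 17.3)$log_lik,
               tolerance = 1e-9)
})

test_that("BM rate is recovered on average", {
  tr <- simulate_tree(100, 0, seed = 5)
  s2 <- sapply(1:40, function(i) {
    bm_loglik(tr, setNames(simulate_bm(tr, 2, seed = i)$trait1,
                           tr$tip.label))$sigma2
  })
  expect_equal(mean(s2), 2, tolerance = 0.1)
})

test_that("OU weight matrix: normalization, limits, hand integral", {
  tr <- read_timetree("(A:1,B:1);")
  p0 <- regime_painting(tr)
  W0 <- ou_weight_matrix(tr, p0, alpha = 0.8)
  expect_equal(unname(W0[, 1]), c(1, 1), tolerance = 1e-12)

  # shift on A's terminal branch: weights are integrated exponentials
  eA <- which(tr$edge[, 2] == match("A", tr$tip.label))
  p1 <- regime_painting(tr, eA)
  a <- 1.0
  W1 <- ou_weight_matrix(tr, p1, a)
  expect_equal(unname(W1["A", ]), c(exp(-a), 1 - exp(-a)), tolerance = 1e-12)
  expect_equal(unname(W1["B", ]), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(rowSums(W1)), c(1, 1), tolerance = 1e-12)

  # fast-adaptation limit: the tip branch's regime takes all the weight
  Wfast <- ou_weight_matrix(tr, p1, 100)
  expect_equal(unname(Wfast["A", 2]), 1, tolerance = 1e-10)

  expect_error(ou_weight_matrix(tr, p1, 0), "Brownian")
})

test_that("OU covariance: BM limit, stationary diagonal, PSD", {
  set.seed(6)
  tru <- ape::rtree(10)
  Cu <- phylo_covariance(tru)
  V <- ou_covariance(tru, alpha = 1e-8, sigma2 = 1.3)
  expect_lt(max(abs(V - 1.3 * Cu)), 1e-5)

  # contemporaneous tips: diagonal equals the stationary-variance formula
  tr <- simulate_tree(10, 0, seed = 6)
  a <- 0.4; s2 <- 2
  V2 <- ou_covariance(tr, a, s2)
  Tdep <- max(ape::node.depth.edgelength(tr))
  expect_equal(unname(diag(V2)), rep(s2 / (2 * a) * (1 - exp(-2 * a * Tdep)), 10),
               tolerance = 1e-9)

  for (al in c(0.01, 0.1, 1, 10)) {
    ev <- eigen(ou_covariance(tr, al, 1), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
  expect_error(ou_covariance(tr, -1), "non-negative")
})

test_that("AICc arithmetic and parameter-free limit", {
  expect_equal(aicc(-5, 2, 10), 10 + 4 + 12 / 7)
  expect_equal(aicc(-5, 0, 10), 10)
  expect_error(aicc(-5, 9, 10), "undefined")
})

test_that("half-life identities and Brownian limit", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(2 * log(2)), 0.5)
  expect_warning(hl <- half_life(0), "Brownian")
  expect_identical(hl, Inf)
})

test_that("hansen fit recovers parameters of a painted OU model", {
  tr <- simulate_tree(100, 0, seed = 8)
  sh <- pick_shift_edges(tr, 1, 0.4)
  p <- regime_painting(tr, sh)
  reps <- lapply(1:10, function(i) {
    Y <- simulate_mvou(tr, p, alpha = 2, sigma2 = 1,
                       theta = matrix(c(0, 5), 2), seed = 900 + i)
    f <- hansen_fit(tr, p, Y)
    c(th1 = f$thetas[1, 1], th2 = f$thetas[2, 1], alpha = f$traits$alpha)
  })
  m <- colMeans(do.call(rbind, reps))
  expect_lt(abs(m["th1"] - 0), 0.25)      # 5% of the 5-unit separation
  expect_equal(unname(m["th2"]), 5, tolerance = 0.05)
  med_a <- median(sapply(reps, `[[`, "alpha"))
  expect_gt(med_a, 2 / 1.5)
  expect_lt(med_a, 2 * 1.5)
})

test_that("hansen AICc is consistent with its own formula and half-lives", {
  tr <- simulate_tree(30, 0, seed = 9)
  p <- regime_painting(tr, pick_shift_edges(tr, 1, 0.3))
  Y <- simulate_mvou(tr, p, 1, 1, matrix(c(0, 3), 2), seed = 10)
  f <- hansen_fit(tr, p, Y)
  expect_equal(f$aicc, aicc(f$log_lik, f$n_params, f$n_obs))
  expect_equal(f$traits$half_life, log(2) / f$traits$alpha)
})

test_that("unestimable regimes are flagged", {
  # a regime painted only on a zero-length branch, with its descendants
  # repainted by downstream shifts, puts no weight on any tip
  tr <- simulate_tree(12, 0, seed = 12)
  cherries <- tr$edge[tr$edge[, 2] > 13, 2]
  stem <- NA
  for (nd in cherries) {
    kids <- tr$edge[tr$edge[, 1] == nd, 2]
    if (all(kids <= 12)) { stem <- nd; break }
  }
  e_stem <- which(tr$edge[, 2] == stem)
  kid_edges <- which(tr$edge[, 1] == stem)
  tr$edge.length[e_stem] <- 0
  p <- regime_painting(tr, c(e_stem, kid_edges))
  Y <- simulate_mvou(tr, p, 1, 1, matrix(c(0, 1, 2, 3), 4), seed = 11)
  expect_warning(f <- hansen_fit(tr, p, Y), "unestimable")
  expect_true(anyNA(f$thetas))
})

test_that("regime paintings flow tipward and merge correctly", {
  tr <- read_timetree("((A:1,B:1):1,(C:1,D:1):1);")
  eAB <- which(tr$edge[, 2] == 6)
  eA <- which(tr$edge[, 2] == match("A", tr$tip.label))
  p <- regime_painting(tr, c(eAB, eA))
  expect_equal(p$n_regimes, 3L)
  expect_equal(p$regime_of_node[match("A", tr$tip.label)], 3L)
  expect_equal(p$regime_of_node[match("B", tr$tip.label)], 2L)
  expect_equal(p$regime_of_node[match("C", tr$tip.label)], 1L)
  m <- peakshift:::merge_regimes(p, 2L, 3L)
  expect_equal(m$n_regimes, 2L)
  expect_equal(m$regime_of_node[match("A", tr$tip.label)],
               m$regime_of_node[match("B", tr$tip.label)])
  expect_equal(peakshift:::convergent_regimes(m), 2L)
})
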