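test_that("likelihood machinery: fast stepwise path equals the direct fit", {
  sc <- three_regime_scenario(101, n_tips = 32)
  Y <- as_trait_matrix(sc$traits, sc$tree)
  grid <- peakshift:::default_alpha_grid()
  pre <- peakshift:::surface_precompute(sc$tree, Y, grid, "root-theta")
  ev <- peakshift:::surface_eval(pre, sc$painting, "tips_x_traits", 1)
  cache <- peakshift:::ou_cache(sc$tree)
  direct <- sapply(seq_len(ncol(Y)), function(j) {
    max(sapply(grid, function(a) {
      peakshift:::ou_trait_loglik(Y[, j], a, sc$painting, cache)$log_lik
    }))
  })
  expect_equal(ev$trait_log_lik, direct, tolerance = 1e-8)
})

test_that("forward search finds a strong shift and its AICc path decreases", {
  tr <- simulate_tree(64, 0, seed = 201)
  true_edge <- pick_shift_edges(tr, 1, 0.3)
  p <- regime_painting(tr, true_edge)
  # 10-SD optimum separation
  th <- rbind(c(0, 0), c(10, 0)) * sqrt(1 / 6)
  hits <- sapply(1:10, function(i) {
    Y <- simulate_mvou(tr, p, 3, 1, th, seed = 400 + i)
    fw <- surface_forward(tr, Y)
    expect_true(all(diff(fw$history$aicc) < 0))
    found <- fw$painting$shift_edges
    as.integer(length(found) >= 1 &&
                 any(found %in% edge_neighbourhood(tr, true_edge)))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("single-regime OU data yields no extra shifts in most replicates", {
  extras <- sapply(1:15, function(seed) {
    tr <- simulate_tree(64, 0, seed = 600 + seed)
    Y <- simulate_mvou(tr, regime_painting(tr), 3, 1, matrix(0, 1, 3),
                       seed = 700 + seed)
    length(surface_forward(tr, Y)$painting$shift_edges)
  })
  expect_gt(mean(extras == 0), 0.5)
})

test_that("collapse never raises the likelihood of identical-optimum regimes", {
  sc <- convergent_scenario(301)
  fw <- surface_forward(sc$tree, sc$traits)
  bw <- surface_backward(sc$tree, sc$traits, fw)
  expect_lte(bw$k_prime, bw$k)
  expect_true(all(diff(bw$history$aicc) < 0))
  # nesting: the collapsed model's logL can only be below the full model's
  expect_lte(bw$fit$log_lik, fw$fit$log_lik + 1e-6)
})

test_that("well-separated optima are not collapsed", {
  res <- sapply(1:8, function(seed) {
    tr <- simulate_tree(64, 0, seed = 800 + seed)
    sh <- pick_shift_edges(tr, 2, 0.08, non_sister = TRUE)[1:2]
    p <- regime_painting(tr, sh)
    th <- rbind(c(0, 0, 0), c(5, 0, 0), c(-5, 3, 0)) * sqrt(1 / 6)
    Y <- simulate_mvou(tr, p, 3, 1, th, seed = 900 + seed)
    s <- surface_fit(tr, Y)
    as.integer(s$k_prime == s$k)
  })
  expect_gt(mean(res), 0.5)
})

test_that("model comparison behaves under BM and multi-regime data", {
  # BM data: BM within 2 AICc of the best model, few or no shifts added
  res <- sapply(1:6, function(seed) {
    tr <- simulate_tree(48, 0, seed = 1000 + seed)
    Y <- simulate_bm(tr, 1, n_traits = 3, seed = 1100 + seed)
    cmp <- compare_models(tr, Y)
    s <- attr(cmp, "surface")
    c(bm_close = as.integer(cmp$delta_aicc[cmp$model == "BM"] <= 2),
      no_shift = as.integer(length(s$painting$shift_edges) == 0))
  })
  expect_gt(mean(res["bm_close", ]), 0.5)
  expect_gt(mean(res["no_shift", ]), 0.5)

  # strong 3-regime data: the stepwise model beats BM and OU1
  sc <- three_regime_scenario(77, n_tips = 64)
  cmp <- compare_models(sc$tree, sc$traits)
  expect_equal(cmp$delta_aicc[cmp$model == "surface"], 0)
  expect_gt(cmp$delta_aicc[cmp$model == "BM"], 0)
  expect_gt(cmp$delta_aicc[cmp$model == "OU1"], 0)
})

test_that("surface results are deterministic given identical inputs", {
  sc <- three_regime_scenario(55, n_tips = 48)
  s1 <- surface_fit(sc$tree, sc$traits)
  s2 <- surface_fit(sc$tree, sc$traits)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$painting$shift_edges, s2$painting$shift_edges)
  expect_equal(s1$fit$aicc, s2$fit$aicc)
})
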