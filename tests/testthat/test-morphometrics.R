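# small helper: build a landmark_set from a list of k x 3 configs
configs_to_lms <- function(configs, species = names(configs)) {
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    tibble::tibble(specimen = names(configs)[i], species = species[i],
                   landmark = seq_len(nrow(cfg)),
                   x = cfg[, 1], y = cfg[, 2], z = cfg[, 3])
  })
  landmark_set(dplyr::bind_rows(rows))
}

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                           c(0, 0, 1))

test_that("centroid size: hand value, rigid invariance, homogeneity", {
  expect_equal(centroid_size(rbind(c(0, 0, 0), c(3, 4, 0))), sqrt(12.5))
  set.seed(1)
  cfg <- matrix(rnorm(30), 10, 3)
  expect_equal(centroid_size(cfg %*% rot_z(0.7)), centroid_size(cfg))
  expect_equal(centroid_size(sweep(cfg, 2, c(5, -2, 1), "+")),
               centroid_size(cfg))
  expect_equal(centroid_size(3 * cfg), 3 * centroid_size(cfg))
})

test_that("GPA is invariant to rigid motion + scaling of any specimen", {
  set.seed(42)
  base <- peakshift:::template_landmarks(10)
  configs <- lapply(1:5, function(i) base + matrix(rnorm(30, 0, 0.02), 10, 3))
  names(configs) <- paste0("s", 1:5)
  a1 <- gpa(configs_to_lms(configs))

  for (target in c(1L, 3L)) { # including the specimen seeding the consensus
    configs2 <- configs
    configs2[[target]] <- 2.5 * configs2[[target]] %*% rot_z(pi / 2) +
      matrix(rep(c(10, -4, 2), each = 10), 10, 3)
    a2 <- gpa(configs_to_lms(configs2))
    expect_lt(max(abs(a1$coords - a2$coords)), 1e-9)
  }
})

test_that("identical configurations have zero Procrustes distance", {
  set.seed(5)
  base <- peakshift:::template_landmarks(8)
  configs <- list(s1 = base, s2 = base %*% rot_z(1.1) + 3,
                  s3 = base + matrix(rnorm(24, 0, 0.05), 8, 3))
  al <- gpa(configs_to_lms(configs))
  expect_lt(sqrt(sum((al$coords[, , 1] - al$coords[, , 2])^2)), 1e-9)
})

test_that("GPA is idempotent at its fixed point", {
  set.seed(9)
  base <- peakshift:::template_landmarks(12)
  configs <- lapply(1:6, function(i) base + matrix(rnorm(36, 0, 0.01), 12, 3))
  names(configs) <- paste0("s", 1:6)
  a1 <- gpa(configs_to_lms(configs))
  cfgs2 <- lapply(seq_len(6), function(i) a1$coords[, , i])
  names(cfgs2) <- paste0("s", 1:6)
  a2 <- gpa(configs_to_lms(cfgs2))
  expect_lt(max(abs(a1$coords - a2$coords)), 1e-5)
})

test_that("degenerate configurations are rejected", {
  flat <- cbind(1:6, (1:6)^2, 0) # rank 2
  expect_error(gpa(configs_to_lms(list(s1 = flat, s2 = flat))), "degenerate")
})

test_that("two-group bgPCA has one axis with symmetric group scores", {
  set.seed(2)
  base <- peakshift:::template_landmarks(10)
  shift <- matrix(rnorm(30, 0, 0.05), 10, 3)
  configs <- list(a1 = base, a2 = base, b1 = base + shift, b2 = base + shift)
  lms <- configs_to_lms(configs, species = c("A", "A", "B", "B"))
  sp <- bgpca(gpa(lms))
  expect_equal(length(sp$eigenvalues), 1L)
  gs <- sp$group_scores$PC1
  expect_equal(gs[1], -gs[2], tolerance = 1e-10)
})

test_that("axis count is at most g - 1 and scores are centred", {
  set.seed(3)
  base <- peakshift:::template_landmarks(10)
  g <- 5
  configs <- list()
  species <- character(0)
  for (j in seq_len(g)) {
    dev <- matrix(rnorm(30, 0, 0.04), 10, 3)
    for (i in 1:3) {
      nm <- sprintf("g%d_%d", j, i)
      configs[[nm]] <- base + dev + matrix(rnorm(30, 0, 0.005), 10, 3)
      species <- c(species, paste0("sp", j))
    }
  }
  sp <- bgpca(gpa(configs_to_lms(configs, species = species)))
  expect_lte(length(sp$eigenvalues), g - 1L)
  sc <- as.matrix(sp$group_scores[paste0("PC", seq_along(sp$eigenvalues))])
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  # eigenvalue conservation: total variance among group means
  gm <- sp$group_means
  S <- stats::cov(gm)
  expect_equal(sum(sp$eigenvalues), sum(diag(S)), tolerance = 1e-10)
})

test_that("bgPCA equals ordinary PCA for balanced groups with no scatter", {
  set.seed(4)
  base <- peakshift:::template_landmarks(10)
  g <- 4
  configs <- list()
  species <- character(0)
  for (j in seq_len(g)) {
    dev <- matrix(rnorm(30, 0, 0.05), 10, 3)
    for (i in 1:2) {
      configs[[sprintf("g%d_%d", j, i)]] <- base + dev
      species <- c(species, paste0("sp", j))
    }
  }
  al <- gpa(configs_to_lms(configs, species = species))
  sp <- bgpca(al)
  X <- t(matrix(al$coords, ncol = dim(al$coords)[3]))
  pc <- stats::prcomp(X, center = TRUE)
  for (j in seq_along(sp$eigenvalues)) {
    expect_equal(abs(sum(sp$eigenvectors[, j] * pc$rotation[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("projection is consistent with the eigenanalysis", {
  set.seed(6)
  base <- peakshift:::template_landmarks(10)
  configs <- list()
  species <- character(0)
  for (j in 1:4) {
    dev <- matrix(rnorm(30, 0, 0.05), 10, 3)
    for (i in 1:2) {
      configs[[sprintf("g%d_%d", j, i)]] <- base + dev +
        matrix(rnorm(30, 0, 0.004), 10, 3)
      species <- c(species, paste0("sp", j))
    }
  }
  sp <- bgpca(gpa(configs_to_lms(configs, species = species)))
  m <- length(sp$eigenvalues)

  # grand mean projects to the origin
  z <- project_shapes(sp, matrix(sp$center, nrow = 1))
  expect_lt(max(abs(as.matrix(z))), 1e-12)

  # center + c * eigenvector_1 projects to (c, 0, ...)
  cc <- 0.37
  z2 <- project_shapes(sp, matrix(sp$center + cc * sp$eigenvectors[, 1],
                                  nrow = 1))
  expect_equal(unname(as.matrix(z2)[1, ]), c(cc, rep(0, m - 1)),
               tolerance = 1e-10)

  # projecting a group's mean reproduces its eigen-score
  z3 <- project_shapes(sp, sp$group_means)
  expect_equal(unname(as.matrix(z3)),
               unname(as.matrix(sp$group_scores[paste0("PC", seq_len(m))])),
               tolerance = 1e-10)

  expect_error(project_shapes(sp, matrix(0, 2, 7)), "mismatch")
})

test_that("excluded groups are projected without altering the eigenbasis", {
  set.seed(8)
  base <- peakshift:::template_landmarks(10)
  configs <- list()
  species <- character(0)
  for (j in 1:4) {
    dev <- matrix(rnorm(30, 0, 0.05), 10, 3)
    configs[[sprintf("g%d", j)]] <- base + dev
    species <- c(species, paste0("sp", j))
  }
  lms <- configs_to_lms(configs, species = species)
  al <- gpa(lms)
  full <- bgpca(al)
  part <- bgpca(al, include = c("sp1", "sp2", "sp3"))
  expect_equal(length(part$eigenvalues), 2L)
  # the excluded group still receives scores
  expect_true("sp4" %in% part$group_scores$group)
  expect_false(part$group_scores$in_eigenanalysis[
    part$group_scores$group == "sp4"])
  expect_error(bgpca(al, include = c("sp1", "nope")), "absent")
})
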