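#' Simulate a pure-birth chronogram, optionally with fossil tips
#'
#' Draws a birth-death tree conditioned on the tip count (death rate 0),
#' rescales it to a fixed root age (default 40 Ma, the depth of an
#' anthropoid-scale radiation), and truncates a fraction of terminal
#' branches so those tips end at positive ages, mimicking fossil taxa.
#'
#' @param n_tips Number of tips (>= 4).
#' @param fossil_fraction Fraction of tips truncated to positive ages.
#' @param seed Optional integer seed.
#' @param root_age Root age in Ma.
#' @return A `phylo` chronogram.
#' @export
simulate_tree <- function(n_tips, fossil_fraction = 0, seed = NULL,
                          root_age = 40) {
  stopifnot(n_tips >= 4L, fossil_fraction >= 0, fossil_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * root_age / depth
  n_fossil <- round(fossil_fraction * n_tips)
  if (n_fossil > 0L) {
    tips <- sample.int(n_tips, n_fossil)
    for (tip in tips) {
      e <- match(tip, tr$edge[, 2L])
      tr$edge.length[e] <- tr$edge.length[e] * runif(1, 0.2, 0.7)
    }
  }
  tr
}

#' Simulate Brownian motion along a tree
#'
#' Recursive Gaussian increments along branches; tip values have covariance
#' `sigma2 * C` around the root state.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Brownian intensity (>= 0; 0 copies the root state to every
#'   tip).
#' @param n_traits Number of independent traits.
#' @param x0 Root state (recycled over traits).
#' @param seed Optional integer seed.
#' @return A tibble with a `species` column and `trait1..p` columns.
#' @export
simulate_bm <- function(tree, sigma2 = 1, n_traits = 1L, x0 = 0,
                        seed = NULL) {
  stopifnot(sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  vals <- matrix(NA_real_, nn, n_traits)
  vals[root, ] <- rep_len(x0, n_traits)
  ord <- stats::reorder(tree, "cladewise")
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  idx <- match(paste(ord$edge[, 1L], ord$edge[, 2L]), key)
  for (e in idx) {
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    vals[ch, ] <- vals[p, ] + rnorm(n_traits, 0, sqrt(sigma2 * len))
  }
  out <- tibble::as_tibble(as.data.frame(vals[seq_len(ntip), , drop = FALSE]))
  names(out) <- paste0("trait", seq_len(n_traits))
  dplyr::bind_cols(tibble::tibble(species = tree$tip.label), out)
}

#' Simulate a multi-regime OU process along a painted tree
#'
#' Exact transition sampling per branch: a child value is drawn from
#' `Normal(theta_r + (x_parent - theta_r) exp(-alpha t),
#' sigma2 (1 - exp(-2 alpha t)) / (2 alpha))` for a branch of length `t`
#' painted with regime r. Traits are independent; `alpha = 0` delegates to
#' [simulate_bm()]. The root takes the root regime's optimum.
#'
#' @param tree A `phylo` object.
#' @param painting A [regime_painting()].
#' @param alpha Adaptation rate (1/Ma).
#' @param sigma2 Brownian intensity.
#' @param theta Regimes x traits matrix of optima (vector for one trait).
#' @param seed Optional integer seed.
#' @return A tibble with `species` and one column per trait.
#' @export
simulate_mvou <- function(tree, painting, alpha, sigma2, theta,
                          seed = NULL) {
  theta <- if (is.matrix(theta)) theta else matrix(theta, ncol = 1L)
  stopifnot(nrow(theta) == painting$n_regimes, alpha >= 0, sigma2 > 0)
  if (alpha == 0) {
    return(simulate_bm(tree, sigma2, ncol(theta),
                       x0 = theta[painting$root_regime, ], seed = seed))
  }
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  p <- ncol(theta)
  vals <- matrix(NA_real_, nn, p)
  vals[root, ] <- theta[painting$root_regime, ]
  ord <- stats::reorder(tree, "cladewise")
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  idx <- match(paste(ord$edge[, 1L], ord$edge[, 2L]), key)
  for (e in idx) {
    par <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    r <- painting$regime_of_edge[e]
    decay <- exp(-alpha * len)
    v <- sigma2 * (-expm1(-2 * alpha * len)) / (2 * alpha)
    mu <- theta[r, ] + (vals[par, ] - theta[r, ]) * decay
    vals[ch, ] <- mu + rnorm(p, 0, sqrt(v))
  }
  out <- tibble::as_tibble(as.data.frame(vals[seq_len(ntip), , drop = FALSE]))
  names(out) <- paste0("trait", seq_len(p))
  dplyr::bind_cols(tibble::tibble(species = tree$tip.label), out)
}

# A fixed, non-degenerate 3D template: k points on a tapering helix.
# Unit-free; think of it as a stylised long-bone epiphysis.
template_landmarks <- function(k = 14L) {
  stopifnot(k >= 4L)
  t <- seq(0, 3 * pi, length.out = k)
  cbind(x = (1 + 0.3 * t / pi) * cos(t),
        y = (1 + 0.3 * t / pi) * sin(t),
        z = t / pi)
}

# Orthonormal shape-change directions at a template, orthogonal to the
# similarity group (translations, scaling, rotations) so that added
# variation survives Procrustes alignment.
shape_basis <- function(template, n_axes) {
  k <- nrow(template)
  cen <- sweep(template, 2L, colMeans(template))
  cen <- cen / sqrt(sum(cen^2))
  trans <- kronecker(diag(3), rep(1, k)) # columns: shift x, y, z
  skew <- list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
               rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)),
               rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  rots <- vapply(skew, function(G) as.vector(cen %*% t(G)), numeric(3 * k))
  sim <- cbind(trans, as.vector(cen), rots)
  raw <- vapply(seq_len(n_axes), function(a) {
    j <- seq_len(3 * k)
    sin(a * pi * j / (3 * k)) + 0.5 * cos((a + 2) * j / 3)
  }, numeric(3 * k))
  Q <- qr.Q(qr(cbind(sim, raw)))
  B <- Q[, ncol(sim) + seq_len(n_axes), drop = FALSE]
  B
}

#' Simulate landmark data with known evolutionary ground truth
#'
#' Species mean shapes are the template plus a linear combination of
#' orthonormal shape-basis vectors whose coefficients evolve under a
#' multi-regime OU process ([simulate_mvou()]); individual specimens add
#' isotropic Gaussian landmark noise, and (optionally) a Brownian
#' log-size factor scales each species' configuration so centroid size
#' carries an evolutionary signal.
#'
#' @param tree A `phylo` object.
#' @param painting A [regime_painting()].
#' @param alpha,sigma2,theta OU parameters passed to [simulate_mvou()]
#'   (`theta`: regimes x shape axes).
#' @param k Number of landmarks.
#' @param n_specimens Specimens per species.
#' @param noise_sd Within-species isotropic landmark noise SD (in template
#'   units; the template has centroid size 1 after scaling).
#' @param size_sigma2 Brownian rate of the log-size factor (0 disables size
#'   evolution).
#' @param base_size Baseline centroid size in mm.
#' @param seed Optional integer seed.
#' @return A list with `landmarks` (a [landmark_set()]), `true_scores`
#'   (tibble of species-level basis coefficients), `true_ln_size`, the
#'   `basis`, and the `template`.
#' @export
simulate_landmarks <- function(tree, painting, alpha, sigma2, theta,
                               k = 14L, n_specimens = 3L, noise_sd = 0.01,
                               size_sigma2 = 0.01, base_size = 50,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- if (is.matrix(theta)) theta else matrix(theta, ncol = 1L)
  n_axes <- ncol(theta)
  template <- template_landmarks(k)
  cen <- sweep(template, 2L, colMeans(template))
  cen <- cen / sqrt(sum(cen^2))
  B <- shape_basis(template, n_axes)
  scores <- simulate_mvou(tree, painting, alpha, sigma2, theta)
  sizes <- if (size_sigma2 > 0) {
    simulate_bm(tree, size_sigma2, 1L)$trait1
  } else {
    rep(0, ape::Ntip(tree))
  }
  ntip <- ape::Ntip(tree)
  S <- as.matrix(scores[, -1L, drop = FALSE])
  rows <- vector("list", ntip * n_specimens)
  ri <- 0L
  for (i in seq_len(ntip)) {
    mean_vec <- as.vector(cen) + B %*% S[i, ]
    mean_cfg <- matrix(mean_vec, k, 3L)
    scale_i <- base_size * exp(sizes[i])
    for (s in seq_len(n_specimens)) {
      cfg <- (mean_cfg + matrix(rnorm(3L * k, 0, noise_sd), k, 3L)) * scale_i
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        specimen = sprintf("%s_sp%02d", tree$tip.label[i], s),
        species = tree$tip.label[i],
        landmark = seq_len(k),
        x = cfg[, 1L], y = cfg[, 2L], z = cfg[, 3L]
      )
    }
  }
  lms <- landmark_set(dplyr::bind_rows(rows))
  list(landmarks = lms,
       true_scores = scores,
       true_ln_size = tibble::tibble(species = tree$tip.label,
                                     ln_size = log(base_size) + sizes),
       basis = B, template = template)
}

#' Pick well-separated candidate shift edges for a simulation scenario
#'
#' Deterministically selects internal edges subtending clades near a target
#' fraction of the tips, constrained to be mutually disjoint, providing
#' reproducible ground-truth shift placements for recovery experiments.
#'
#' @param tree A `phylo` object.
#' @param n_shifts Number of shift edges.
#' @param target_frac Target clade size as a fraction of the tip count.
#' @param non_sister If `TRUE`, no two chosen edges may share a parent
#'   node, so the union of two shifted clades is never itself a clade --
#'   required when simulating convergence that must be distinguishable
#'   from a single deeper shift.
#' @return Integer vector of edge indices (rows of `tree$edge`).
#' @export
pick_shift_edges <- function(tree, n_shifts, target_frac = 0.25,
                             non_sister = FALSE) {
  ntip <- ape::Ntip(tree)
  clades <- lapply(seq_len(nrow(tree$edge)), function(e) {
    nd <- tree$edge[e, 2L]
    if (nd <= ntip) nd else phangorn::Descendants(tree, nd, "tips")[[1L]]
  })
  sizes <- lengths(clades)
  ord <- order(abs(sizes - target_frac * ntip), sizes)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  chosen <- integer(0)
  used <- integer(0)
  for (e in ord) {
    if (sizes[e] < 2L) next
    # a shift on a root-adjacent branch is confounded with a shift on its
    # complement; keep ground-truth placements identifiable
    if (tree$edge[e, 1L] == root) next
    if (length(intersect(clades[[e]], used))) next
    if (non_sister && any(tree$edge[chosen, 1L] == tree$edge[e, 1L])) next
    chosen <- c(chosen, e)
    used <- c(used, clades[[e]])
    if (length(chosen) == n_shifts) break
  }
  if (length(chosen) < n_shifts) {
    stop("could not find ", n_shifts, " disjoint clades", call. = FALSE)
  }
  chosen
}
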