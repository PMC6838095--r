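#' Paint adaptive regimes onto a tree
#'
#' A painting starts in the root regime (id 1) and changes at the origin of
#' each shift edge: the new regime flows tipward until overridden by a
#' downstream shift. Shift edges are indexed into `tree$edge` rows.
#'
#' @param tree A `phylo` object.
#' @param shift_edges Integer vector of edge indices where new regimes
#'   begin; regimes are numbered 2, 3, ... in the order given.
#' @return An object of class `regime_painting` with `shift_edges`,
#'   `regime_of_edge` (one id per edge), `regime_of_node`, `root_regime`
#'   and `n_regimes`.
#' @export
regime_painting <- function(tree, shift_edges = integer(0)) {
  painting_builder(tree)(shift_edges)
}

# Hoists the preorder traversal so stepwise searches can paint thousands of
# candidate shift sets without re-deriving tree structure.
painting_builder <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  E <- nrow(tree$edge)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  ord <- stats::reorder(tree, "cladewise")$edge
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  idx <- match(paste(ord[, 1L], ord[, 2L]), key)
  parents <- tree$edge[, 1L]
  children <- tree$edge[, 2L]
  function(shift_edges = integer(0)) {
    shift_edges <- as.integer(shift_edges)
    if (length(shift_edges) && (anyDuplicated(shift_edges) ||
                                any(shift_edges < 1L | shift_edges > E))) {
      stop("invalid shift edge indices", call. = FALSE)
    }
    shift_regime <- integer(E)
    shift_regime[shift_edges] <- 1L + seq_along(shift_edges)
    regime_of_node <- integer(nn)
    regime_of_node[root] <- 1L
    regime_of_edge <- integer(E)
    for (e in idx) {
      reg <- if (shift_regime[e] > 0L) shift_regime[e] else
        regime_of_node[parents[e]]
      regime_of_edge[e] <- reg
      regime_of_node[children[e]] <- reg
    }
    structure(list(shift_edges = shift_edges,
                   regime_of_edge = regime_of_edge,
                   regime_of_node = regime_of_node,
                   root_regime = 1L,
                   n_regimes = length(shift_edges) + 1L),
              class = "regime_painting")
  }
}

# Merge regime `from` into regime `to`, compacting ids. Shift edges are
# retained (the transition still exists; the regimes now share an optimum).
merge_regimes <- function(painting, to, from) {
  stopifnot(to != from)
  map <- seq_len(painting$n_regimes)
  map[from] <- to
  map <- match(map, sort(unique(map)))
  painting$regime_of_edge <- map[painting$regime_of_edge]
  painting$regime_of_node <- map[painting$regime_of_node]
  painting$root_regime <- map[painting$root_regime]
  painting$n_regimes <- max(map)
  painting
}

# Regimes reached from more than one origin (the root counts as the origin
# of the root regime; every shift edge is an origin of its regime).
convergent_regimes <- function(painting) {
  origins <- c(painting$root_regime,
               painting$regime_of_edge[painting$shift_edges])
  tab <- table(origins)
  as.integer(names(tab)[tab > 1L])
}

# Per-tree geometry shared by all OU computations: node depths from the
# root, tip depths T, shared times C, patristic distances D, and the
# flattened root-to-tip path segments (tip, edge, t0, t1).
ou_cache <- function(tree) {
  validate_timetree(tree)
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  Tdep <- depth[seq_len(n)]
  C <- ape::vcv.phylo(tree)
  D <- outer(Tdep, Tdep, `+`) - 2 * C
  E <- nrow(tree$edge)
  parent_edge <- match(tree$edge[, 1L], tree$edge[, 2L]) # NA for root children
  seg_tip <- integer(0)
  seg_edge <- integer(0)
  for (tip in seq_len(n)) {
    e <- match(tip, tree$edge[, 2L])
    while (!is.na(e)) {
      seg_tip <- c(seg_tip, tip)
      seg_edge <- c(seg_edge, e)
      e <- parent_edge[e]
    }
  }
  list(n = n, E = E, depth = depth, T = Tdep, C = C, D = D,
       t0 = depth[tree$edge[, 1L]], t1 = depth[tree$edge[, 2L]],
       seg_tip = seg_tip, seg_edge = seg_edge,
       tip_labels = tree$tip.label)
}

#' Phylogenetic covariance matrix of shared path lengths
#'
#' `C[i, j]` is the path length from the root to the most recent common
#' ancestor of tips i and j; the diagonal holds root-to-tip distances,
#' which differ across tips when fossils are present.
#'
#' @param tree A `phylo` object.
#' @return An n x n symmetric positive semidefinite matrix in tip order.
#' @export
phylo_covariance <- function(tree) {
  validate_timetree(tree)
  ape::vcv.phylo(tree)
}

#' Expected-optimum weight matrix of a multi-regime OU model
#'
#' Under an Ornstein-Uhlenbeck process with pull `alpha`, the expected
#' value at tip i is a convex combination of the regime optima, with the
#' weight of each painted segment of the root-to-tip path given by
#' exponential decay over the time since that segment. The root state
#' contributes `exp(-alpha * T_i)`: under the `"root-theta"` policy it is
#' folded into the root regime's column; under `"estimate"` it becomes an
#' extra column whose coefficient is a free ancestral state.
#'
#' @param tree A `phylo` object.
#' @param painting A [regime_painting()].
#' @param alpha Adaptation rate (1/Ma), > 0.
#' @param x0_policy `"root-theta"` (default) or `"estimate"`.
#' @param cache Optional precomputed [ou_cache] (internal use).
#' @return A tips x regimes matrix with rows summing to 1 (an extra
#'   ancestral-state column is appended under `"estimate"`).
#' @export
ou_weight_matrix <- function(tree, painting, alpha,
                             x0_policy = c("root-theta", "estimate"),
                             cache = NULL) {
  x0_policy <- match.arg(x0_policy)
  if (alpha == 0) {
    stop("alpha = 0 has no weight matrix: use the Brownian-motion limit ",
         "(bm_loglik)", call. = FALSE)
  }
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (is.null(cache)) cache <- ou_cache(tree)
  segw <- exp(-alpha * (cache$T[cache$seg_tip] - cache$t1[cache$seg_edge])) -
    exp(-alpha * (cache$T[cache$seg_tip] - cache$t0[cache$seg_edge]))
  n <- cache$n
  K <- painting$n_regimes
  grp <- (painting$regime_of_edge[cache$seg_edge] - 1L) * n + cache$seg_tip
  W <- numeric(n * K)
  agg <- rowsum(segw, grp)
  W[as.integer(rownames(agg))] <- agg
  W <- matrix(W, n, K)
  rootw <- exp(-alpha * cache$T)
  if (x0_policy == "root-theta") {
    W[, painting$root_regime] <- W[, painting$root_regime] + rootw
  } else {
    W <- cbind(W, rootw)
  }
  rownames(W) <- cache$tip_labels
  W
}

#' Tip covariance of an OU process on a tree
#'
#' `V[i, j] = (sigma2 / (2 alpha)) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_a))`
#' with `t_a` the shared time of tips i, j from the root and `d_ij` their
#' patristic distance; the Brownian limit `sigma2 * C` is returned for
#' vanishing `alpha`.
#'
#' @inheritParams ou_weight_matrix
#' @param sigma2 Brownian intensity (> 0).
#' @return An n x n covariance matrix in tip order.
#' @export
ou_covariance <- function(tree, alpha, sigma2 = 1, cache = NULL) {
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  stopifnot(sigma2 > 0)
  if (is.null(cache)) cache <- ou_cache(tree)
  if (alpha < 1e-12) return(sigma2 * cache$C)
  sigma2 * exp(-alpha * cache$D) * (-expm1(-2 * alpha * cache$C)) / (2 * alpha)
}

#' Brownian-motion log-likelihood on a tree
#'
#' Multivariate normal log-density of tip values with mean equal to the
#' GLS-estimated root state and covariance `sigma2 * C`; with
#' `sigma2 = "mle"` the rate is maximized in closed form.
#'
#' @param tree A `phylo` object with >= 2 tips.
#' @param x Numeric tip values, named by tip label or in tip order.
#' @param sigma2 Positive rate, or `"mle"`.
#' @return A list with `log_lik`, `sigma2` and `root_state`.
#' @export
bm_loglik <- function(tree, x, sigma2 = "mle") {
  cache <- ou_cache(tree)
  n <- cache$n
  stopifnot(n >= 2L)
  if (!is.null(names(x))) x <- x[cache$tip_labels]
  stopifnot(length(x) == n, !anyNA(x))
  U <- chol(cache$C)
  z <- backsolve(U, x, transpose = TRUE)
  one <- backsolve(U, rep(1, n), transpose = TRUE)
  ahat <- sum(one * z) / sum(one^2)
  r <- z - ahat * one
  logdet <- 2 * sum(log(diag(U)))
  if (identical(sigma2, "mle")) {
    s2 <- sum(r^2) / n
    ll <- -n / 2 * (log(2 * pi) + log(s2) + 1) - logdet / 2
  } else {
    stopifnot(is.numeric(sigma2), sigma2 > 0)
    s2 <- sigma2
    ll <- -n / 2 * (log(2 * pi) + log(s2)) - logdet / 2 - sum(r^2) / (2 * s2)
  }
  list(log_lik = ll, sigma2 = s2, root_state = ahat)
}

#' Finite-sample Akaike information criterion
#'
#' `AICc = -2 logL + 2p + 2p(p + 1) / (n - p - 1)`.
#'
#' @param log_lik Maximized log-likelihood.
#' @param p Number of free parameters.
#' @param n Number of observations (`n > p + 1`).
#' @return The AICc value.
#' @export
aicc <- function(log_lik, p, n) {
  if (n <= p + 1) {
    stop("AICc correction undefined: n must exceed p + 1 (n = ", n,
         ", p = ", p, ")", call. = FALSE)
  }
  -2 * log_lik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Phylogenetic half-life
#'
#' The expected time to traverse half the distance to a new optimum,
#' `t_1/2 = ln(2) / alpha`.
#'
#' @param alpha Adaptation rate(s), 1/Ma.
#' @return Half-life in Ma; `Inf` (with a warning) for `alpha <= 0`, the
#'   Brownian limit.
#' @export
half_life <- function(alpha) {
  out <- log(2) / alpha
  if (any(alpha <= 0)) {
    warning("alpha <= 0: half-life is infinite (Brownian limit)")
    out[alpha <= 0] <- Inf
  }
  out
}

# Profile log-likelihood machinery ------------------------------------------

# Log-likelihood of one trait under a painted OU model at fixed alpha, with
# sigma2 profiled out (ML) unless given, and theta estimated by GLS unless
# given. Returns logL plus the implied estimates.
ou_trait_loglik <- function(y, alpha, painting, cache,
                            sigma2 = "mle", theta = NULL,
                            x0_policy = "root-theta") {
  n <- cache$n
  V0 <- ou_covariance(NULL, alpha, 1, cache = cache)
  U <- chol(V0)
  logdet <- 2 * sum(log(diag(U)))
  Ty <- backsolve(U, y, transpose = TRUE)
  if (alpha < 1e-12) {
    # BM limit: all weight collapses onto the root state
    W <- matrix(0, n, painting$n_regimes)
    if (identical(x0_policy, "root-theta")) {
      W[, painting$root_regime] <- 1
    } else {
      W <- cbind(W, rep(1, n))
    }
  } else {
    W <- ou_weight_matrix(NULL, painting, alpha, x0_policy, cache = cache)
  }
  TW <- backsolve(U, W, transpose = TRUE)
  if (is.null(theta)) {
    fit <- stats::lm.fit(TW, Ty)
    theta <- fit$coefficients
    rss <- sum(fit$residuals^2)
  } else {
    rss <- sum((Ty - TW %*% theta)^2)
  }
  rss <- max(rss, .Machine$double.xmin) # guard exact fits on tiny trees
  if (identical(sigma2, "mle")) {
    s2 <- rss / n
    ll <- -n / 2 * (log(2 * pi) + log(s2) + 1) - logdet / 2
  } else {
    s2 <- sigma2
    ll <- -n / 2 * (log(2 * pi) + log(s2)) - logdet / 2 - rss / (2 * s2)
  }
  list(log_lik = ll, sigma2 = s2, theta = theta, rss = rss)
}

#' Log-likelihood of a painted Hansen model at fixed parameters
#'
#' Evaluates, for each trait, the Gaussian log-density implied by a regime
#' painting at a given adaptation rate `alpha`, with the Brownian intensity
#' profiled out (or fixed) and the optima estimated by GLS (or fixed).
#' Mostly useful for likelihood checks and profile exploration;
#' [hansen_fit()] maximizes over `alpha`.
#'
#' @param tree A `phylo` object.
#' @param painting A [regime_painting()].
#' @param traits A species x traits data frame (with a `species` column) or
#'   numeric matrix with species rownames; single traits may be a named
#'   vector.
#' @param alpha Fixed adaptation rate (>= 0; 0 is evaluated as the Brownian
#'   limit).
#' @param sigma2 `"mle"` or a fixed positive value (recycled over traits).
#' @param theta Optional fixed optima: a regimes x traits matrix (or vector
#'   for one trait).
#' @param x0_policy Root-state convention, see [ou_weight_matrix()].
#' @return A list with `log_lik` (summed over traits) and a per-trait
#'   tibble `traits`.
#' @export
hansen_loglik <- function(tree, painting, traits, alpha, sigma2 = "mle",
                          theta = NULL, x0_policy = "root-theta") {
  cache <- ou_cache(tree)
  Y <- as_trait_matrix(traits, tree)
  if (!is.null(theta)) theta <- matrix(theta, ncol = ncol(Y))
  rows <- lapply(seq_len(ncol(Y)), function(j) {
    r <- ou_trait_loglik(Y[, j], alpha, painting, cache,
                         sigma2 = sigma2,
                         theta = if (is.null(theta)) NULL else theta[, j],
                         x0_policy = x0_policy)
    tibble::tibble(trait = colnames(Y)[j], alpha = alpha,
                   sigma2 = r$sigma2, log_lik = r$log_lik)
  })
  tb <- dplyr::bind_rows(rows)
  list(log_lik = sum(tb$log_lik), traits = tb)
}

# Default profile grid for the adaptation rate (1/Ma). Spans half-lives
# from ~7000 Ma (effectively Brownian) to ~7000 years on Ma-scaled trees.
default_alpha_grid <- function() exp(seq(log(1e-4), log(100), length.out = 18))

#' Fit a multi-regime Hansen (OU) model with shared alpha and sigma per trait
#'
#' For each trait, a single adaptation rate and Brownian intensity are
#' shared across regimes while the optimum varies by regime: given `alpha`,
#' the optima are GLS estimates and `sigma2` has a closed-form ML value, so
#' `alpha` is found by profile likelihood over a log-spaced grid followed by
#' local continuous refinement. Trait likelihoods are summed (traits are
#' modelled independently under a shared painting).
#'
#' @inheritParams hansen_loglik
#' @param alpha_grid Profile grid for the adaptation rate (1/Ma).
#' @param refine Continuously refine the per-trait rate around the best
#'   grid point.
#' @param n_convention How AICc counts observations: `"tips_x_traits"`
#'   (default) or `"tips"`.
#' @param shift_cost Parameters charged per shift location in the AICc
#'   count (1 = naive count; stepwise searches pass the selection-adjusted
#'   cost `log(#candidate branches)`).
#' @return An object of class `hansen_fit`: per-trait tibble `traits`
#'   (`alpha`, `sigma2`, `log_lik`, `half_life`), `thetas` (regimes x
#'   traits), total `log_lik`, `n_params`, `n_obs`, `aicc`, and the
#'   painting.
#' @export
hansen_fit <- function(tree, painting, traits,
                       alpha_grid = default_alpha_grid(), refine = TRUE,
                       x0_policy = "root-theta",
                       n_convention = c("tips_x_traits", "tips"),
                       shift_cost = 1) {
  n_convention <- match.arg(n_convention)
  cache <- ou_cache(tree)
  Y <- as_trait_matrix(traits, tree)
  p_traits <- ncol(Y)
  K <- painting$n_regimes
  grid_ll <- matrix(NA_real_, length(alpha_grid), p_traits)
  for (a in seq_along(alpha_grid)) {
    for (j in seq_len(p_traits)) {
      grid_ll[a, j] <- ou_trait_loglik(Y[, j], alpha_grid[a], painting,
                                       cache, x0_policy = x0_policy)$log_lik
    }
  }
  per_trait <- lapply(seq_len(p_traits), function(j) {
    best <- which.max(grid_ll[, j])
    a_hat <- alpha_grid[best]
    if (refine) {
      lo <- log(alpha_grid[max(1L, best - 1L)])
      hi <- log(alpha_grid[min(length(alpha_grid), best + 1L)])
      if (best == 1L) lo <- log(1e-8)
      if (best == length(alpha_grid)) hi <- log(1e3)
      opt <- stats::optimize(function(la) {
        ou_trait_loglik(Y[, j], exp(la), painting, cache,
                        x0_policy = x0_policy)$log_lik
      }, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
      if (opt$objective >= grid_ll[best, j]) a_hat <- exp(opt$maximum)
    }
    r <- ou_trait_loglik(Y[, j], a_hat, painting, cache,
                         x0_policy = x0_policy)
    list(alpha = a_hat, fit = r)
  })
  # regimes carrying no tip weight at the fitted rates are unestimable
  thetas <- vapply(per_trait, function(z) {
    th <- z$fit$theta[seq_len(K)]
    as.numeric(th)
  }, numeric(K))
  thetas <- matrix(thetas, nrow = K, ncol = p_traits,
                   dimnames = list(paste0("regime_", seq_len(K)), colnames(Y)))
  for (j in seq_len(p_traits)) {
    W <- ou_weight_matrix(NULL, painting, max(per_trait[[j]]$alpha, 1e-12),
                          x0_policy, cache = cache)
    dead <- colSums(abs(W[, seq_len(K), drop = FALSE])) < 1e-10
    if (any(dead)) {
      thetas[dead, j] <- NA_real_
      warning("regime(s) ", paste(which(dead), collapse = ", "),
              " carry no tip weight for trait ", colnames(Y)[j],
              "; optimum flagged unestimable")
    }
  }
  tb <- tibble::tibble(
    trait = colnames(Y),
    alpha = vapply(per_trait, `[[`, 0, "alpha"),
    sigma2 = vapply(per_trait, function(z) z$fit$sigma2, 0),
    log_lik = vapply(per_trait, function(z) z$fit$log_lik, 0)
  )
  tb$half_life <- log(2) / tb$alpha
  n_params <- hansen_n_params(K, p_traits, length(painting$shift_edges),
                              x0_policy, shift_cost)
  n_obs <- if (n_convention == "tips_x_traits") cache$n * p_traits else cache$n
  structure(list(traits = tb, thetas = thetas, painting = painting,
                 log_lik = sum(tb$log_lik), n_params = n_params,
                 n_obs = n_obs, aicc = aicc(sum(tb$log_lik), n_params, n_obs),
                 n_tips = cache$n, x0_policy = x0_policy,
                 n_convention = n_convention),
            class = "hansen_fit")
}

# Parameter count: per trait alpha + sigma2 + one optimum per regime
# (plus a free root state under "estimate"), plus `shift_cost` parameters
# per shift location, counted once across traits. A cost of 1 is the naive
# count; stepwise searches default to log(#candidate branches), the
# risk-inflation-style price of selecting each shift location among all
# branches, which calibrates the detector against spurious shifts.
hansen_n_params <- function(n_regimes, n_traits, n_shifts,
                            x0_policy = "root-theta", shift_cost = 1) {
  per_trait <- 2 + n_regimes + if (x0_policy == "estimate") 1L else 0L
  n_traits * per_trait + shift_cost * n_shifts
}

#' @export
print.hansen_fit <- function(x, ...) {
  cat("Multi-regime OU (Hansen) fit:", nrow(x$traits), "trait(s),",
      x$painting$n_regimes, "regime(s)\n")
  cat(sprintf("log-likelihood %.4f | params %d | n %d | AICc %.4f\n",
              x$log_lik, x$n_params, x$n_obs, x$aicc))
  print(x$traits)
  invisible(x)
}
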