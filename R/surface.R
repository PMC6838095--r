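# Precomputation shared across every candidate painting evaluated during a
# stepwise search. For each grid value of the adaptation rate: the
# log-determinant of the unit-rate OU covariance, the transformed traits,
# the transformed per-edge weight columns TWE (column e holds, for every
# tip below edge e, the exponential weight its path segment on e would
# contribute to that tip's expected optimum), and the transformed
# root-weight vector. Any painting's GLS design is then a sum of TWE
# columns grouped by regime, so candidate shifts are evaluated
# incrementally instead of rebuilding the GLS from scratch.
surface_precompute <- function(tree, Y, alpha_grid, x0_policy) {
  cache <- ou_cache(tree)
  n <- cache$n
  E <- nrow(tree$edge)
  per_alpha <- lapply(alpha_grid, function(a) {
    V0 <- ou_covariance(NULL, a, 1, cache = cache)
    U <- chol(V0)
    segw <- exp(-a * (cache$T[cache$seg_tip] - cache$t1[cache$seg_edge])) -
      exp(-a * (cache$T[cache$seg_tip] - cache$t0[cache$seg_edge]))
    Wedge <- matrix(0, n, E)
    Wedge[cbind(cache$seg_tip, cache$seg_edge)] <- segw
    list(alpha = a,
         logdet = 2 * sum(log(diag(U))),
         TY = backsolve(U, Y, transpose = TRUE),
         TWE = backsolve(U, Wedge, transpose = TRUE),
         Troot = backsolve(U, exp(-a * cache$T), transpose = TRUE))
  })
  # edges in the subtree rooted at each edge's child (edge itself included)
  children <- tree$edge[, 2L]
  edges_of_parent <- split(seq_len(E), tree$edge[, 1L])
  subtree <- vector("list", E)
  post <- rev(match(stats::reorder(tree, "cladewise")$edge[, 2L], children))
  for (e in post) {
    kids <- edges_of_parent[[as.character(children[e])]]
    subtree[[e]] <- c(e, unlist(subtree[kids], use.names = FALSE))
  }
  list(cache = cache, per_alpha = per_alpha, Y = Y, n = n, E = E,
       p_traits = ncol(Y), x0_policy = x0_policy, subtree = subtree,
       paint = painting_builder(tree))
}

# Transformed GLS design (one column per regime) for a painting at grid
# point a; the ancestral-state weight is folded into the root regime's
# column or appended, per the x0 policy.
surface_TW <- function(pre, a, painting) {
  pa <- pre$per_alpha[[a]]
  K <- painting$n_regimes
  TW <- vapply(seq_len(K), function(r) {
    cols <- which(painting$regime_of_edge == r)
    if (length(cols)) {
      rowSums(pa$TWE[, cols, drop = FALSE])
    } else {
      numeric(pre$n)
    }
  }, numeric(pre$n))
  if (pre$x0_policy == "root-theta") {
    TW[, painting$root_regime] <- TW[, painting$root_regime] + pa$Troot
  } else {
    TW <- cbind(TW, pa$Troot)
  }
  TW
}

# Per-trait profile log-likelihoods at one grid point given the design.
surface_ll <- function(pre, a, TW) {
  pa <- pre$per_alpha[[a]]
  res <- .lm.fit(TW, pa$TY)$residuals
  rss <- colSums(matrix(res, nrow = pre$n)^2)
  rss <- pmax(rss, .Machine$double.xmin)
  -pre$n / 2 * (log(2 * pi) + log(rss / pre$n) + 1) - pa$logdet / 2
}

surface_aicc <- function(pre, best_ll, n_regimes, n_shifts, n_convention,
                         shift_cost) {
  p <- hansen_n_params(n_regimes, pre$p_traits, n_shifts, pre$x0_policy,
                       shift_cost)
  n_obs <- if (n_convention == "tips_x_traits") pre$n * pre$p_traits else pre$n
  aicc(sum(best_ll), p, n_obs)
}

# Summed AICc of an arbitrary painting (used at initialisation and in the
# backward phase), profiling each trait's rate over the grid.
surface_eval <- function(pre, painting, n_convention, shift_cost) {
  ll <- vapply(seq_along(pre$per_alpha), function(a) {
    surface_ll(pre, a, surface_TW(pre, a, painting))
  }, numeric(pre$p_traits))
  best <- apply(matrix(ll, nrow = pre$p_traits), 1L, max)
  list(aicc = surface_aicc(pre, best, painting$n_regimes,
                           length(painting$shift_edges), n_convention,
                           shift_cost),
       log_lik = sum(best), trait_log_lik = best)
}

#' Forward phase of the stepwise adaptive-peak search
#'
#' Starting from a single-regime OU model in which every lineage is
#' attracted to one optimum, regime shifts are added greedily: at each step
#' every branch not already carrying a shift is tried as a new shift origin
#' (the new regime flows tipward until overridden by existing shifts), and
#' the shift that most lowers the AICc summed across traits is accepted;
#' the search stops when no candidate lowers the AICc. Ties break to the
#' lowest AICc and then to the earliest branch in edge order, so the result
#' is deterministic given the inputs. Candidates whose fit fails are
#' skipped.
#'
#' By default each accepted shift's location is charged
#' `log(#candidate branches)` parameters in the AICc count (a
#' risk-inflation-style selection cost) so that the greedy search, which
#' picks the best of hundreds of candidate branches per step, stays
#' calibrated on shift-free data; `shift_cost = 1` restores the naive
#' count.
#'
#' @param tree A `phylo` object.
#' @param traits Species x traits data (at least 2 traits recommended).
#' @param alpha_grid Profile grid for the per-trait adaptation rate.
#' @param max_shifts Safety cap on the number of accepted shifts.
#' @param x0_policy Root-state convention, see [ou_weight_matrix()].
#' @param n_convention AICc observation count convention, see [hansen_fit()].
#' @param shift_cost Parameters charged per shift location (default
#'   `log(nrow(tree$edge))`).
#' @return An object of class `surface_result` (phase `"forward"`): the
#'   accepted `painting`, a `history` tibble of AICc after each step, the
#'   refined final [hansen_fit()] in `fit`, and `k` (number of regimes).
#' @export
surface_forward <- function(tree, traits,
                            alpha_grid = default_alpha_grid(),
                            max_shifts = NULL,
                            x0_policy = "root-theta",
                            n_convention = c("tips_x_traits", "tips"),
                            shift_cost = log(nrow(tree$edge))) {
  n_convention <- match.arg(n_convention)
  Y <- as_trait_matrix(traits, tree)
  pre <- surface_precompute(tree, Y, alpha_grid, x0_policy)
  E <- pre$E
  nA <- length(pre$per_alpha)
  if (is.null(max_shifts)) max_shifts <- min(pre$n - 2L, 40L)
  shifts <- integer(0)
  painting <- pre$paint(shifts)
  TWs <- lapply(seq_len(nA), function(a) surface_TW(pre, a, painting))
  cur <- surface_eval(pre, painting, n_convention, shift_cost)
  history <- tibble::tibble(step = 0L, action = "start", edge = NA_integer_,
                            k = 1L, aicc = cur$aicc)
  repeat {
    if (length(shifts) >= max_shifts) break
    K <- painting$n_regimes
    best <- NULL
    best_edge <- NA_integer_
    for (e in seq_len(E)) {
      if (e %in% shifts) next
      r_old <- painting$regime_of_edge[e]
      sub <- pre$subtree[[e]]
      cap <- sub[painting$regime_of_edge[sub] == r_old]
      ll <- matrix(NA_real_, nA, pre$p_traits)
      ok <- TRUE
      for (a in seq_len(nA)) {
        newcol <- rowSums(pre$per_alpha[[a]]$TWE[, cap, drop = FALSE])
        TWc <- cbind(TWs[[a]], newcol, deparse.level = 0)
        TWc[, r_old] <- TWc[, r_old] - newcol
        la <- tryCatch(surface_ll(pre, a, TWc), error = function(err) NULL)
        if (is.null(la)) { ok <- FALSE; break }
        ll[a, ] <- la
      }
      if (!ok) next
      best_ll <- apply(ll, 2L, max)
      cand_aicc <- surface_aicc(pre, best_ll, K + 1L, length(shifts) + 1L,
                                n_convention, shift_cost)
      if (is.null(best) || cand_aicc < best$aicc) {
        best <- list(aicc = cand_aicc, log_lik = sum(best_ll))
        best_edge <- e
      }
    }
    if (is.null(best) || best$aicc >= cur$aicc) break
    shifts <- c(shifts, best_edge)
    painting <- pre$paint(shifts)
    TWs <- lapply(seq_len(nA), function(a) surface_TW(pre, a, painting))
    cur <- best
    history <- dplyr::bind_rows(history, tibble::tibble(
      step = length(shifts), action = "add_shift", edge = best_edge,
      k = painting$n_regimes, aicc = cur$aicc))
  }
  fit <- hansen_fit(tree, painting, Y, alpha_grid = alpha_grid,
                    x0_policy = x0_policy, n_convention = n_convention,
                    shift_cost = shift_cost)
  structure(list(phase = "forward", tree = tree, painting = painting,
                 history = history, fit = fit, k = painting$n_regimes,
                 grid_aicc = cur$aicc, alpha_grid = alpha_grid,
                 x0_policy = x0_policy, n_convention = n_convention,
                 shift_cost = shift_cost),
            class = "surface_result")
}

#' Backward (convergence-collapse) phase of the stepwise search
#'
#' Tests whether the AICc improves when different shifts lead to shared
#' adaptive regimes rather than each occupying its own peak: pairs of
#' regimes are merged greedily while the summed AICc keeps decreasing
#' (merging drops one optimum per trait; shift locations are retained).
#' Regimes reached from more than one origin in the collapsed painting are
#' reported as convergent.
#'
#' @param tree,traits As in [surface_forward()].
#' @param forward A forward-phase `surface_result`.
#' @return An object of class `surface_result` (phase `"backward"`), with
#'   `k` (regimes before collapse), `k_prime` (distinct regimes after),
#'   `convergent` (ids of convergent regimes), combined `history`, and the
#'   refined final fit.
#' @export
surface_backward <- function(tree, traits, forward) {
  stopifnot(inherits(forward, "surface_result"))
  Y <- as_trait_matrix(traits, tree)
  pre <- surface_precompute(tree, Y, forward$alpha_grid, forward$x0_policy)
  n_convention <- forward$n_convention
  shift_cost <- forward$shift_cost
  painting <- forward$painting
  n_shifts <- length(painting$shift_edges)
  cur <- surface_eval(pre, painting, n_convention, shift_cost)
  history <- forward$history
  step <- max(history$step)
  repeat {
    K <- painting$n_regimes
    if (K < 2L) break
    pairs <- combn(K, 2L)
    best <- NULL
    best_pair <- NULL
    for (j in seq_len(ncol(pairs))) {
      cand_paint <- merge_regimes(painting, pairs[1L, j], pairs[2L, j])
      cand <- tryCatch(
        surface_eval(pre, cand_paint, n_convention, shift_cost),
        error = function(err) NULL
      )
      if (is.null(cand)) next
      if (is.null(best) || cand$aicc < best$aicc) {
        best <- cand
        best_pair <- pairs[, j]
      }
    }
    if (is.null(best) || best$aicc >= cur$aicc) break
    painting <- merge_regimes(painting, best_pair[1L], best_pair[2L])
    cur <- best
    step <- step + 1L
    history <- dplyr::bind_rows(history, tibble::tibble(
      step = step, action = "collapse", edge = NA_integer_,
      k = painting$n_regimes, aicc = cur$aicc))
  }
  fit <- hansen_fit(tree, painting, Y, alpha_grid = forward$alpha_grid,
                    x0_policy = forward$x0_policy,
                    n_convention = n_convention, shift_cost = shift_cost)
  structure(list(phase = "backward", tree = tree, painting = painting,
                 history = history, fit = fit,
                 k = forward$painting$n_regimes,
                 k_prime = painting$n_regimes,
                 convergent = convergent_regimes(painting),
                 grid_aicc = cur$aicc,
                 alpha_grid = forward$alpha_grid,
                 x0_policy = forward$x0_policy,
                 n_convention = n_convention,
                 shift_cost = shift_cost),
            class = "surface_result")
}

#' Full stepwise adaptive-peak analysis (forward + collapse)
#'
#' @inheritParams surface_forward
#' @return The backward-phase `surface_result` (which carries the full
#'   history of both phases).
#' @export
surface_fit <- function(tree, traits, alpha_grid = default_alpha_grid(),
                        max_shifts = NULL, x0_policy = "root-theta",
                        n_convention = c("tips_x_traits", "tips"),
                        shift_cost = log(nrow(tree$edge))) {
  fw <- surface_forward(tree, traits, alpha_grid = alpha_grid,
                        max_shifts = max_shifts, x0_policy = x0_policy,
                        n_convention = n_convention, shift_cost = shift_cost)
  surface_backward(tree, traits, fw)
}

#' @export
print.surface_result <- function(x, ...) {
  cat("Stepwise adaptive-peak search (", x$phase, " phase)\n", sep = "")
  if (!is.null(x$k_prime)) {
    cat(sprintf("k = %d regimes before collapse, k' = %d after; %d convergent\n",
                x$k, x$k_prime, length(x$convergent)))
  } else {
    cat(sprintf("k = %d regimes (%d shifts)\n", x$k,
                length(x$painting$shift_edges)))
  }
  cat(sprintf("grid-profile AICc %.4f | refined AICc %.4f\n",
              x$grid_aicc, x$fit$aicc))
  invisible(x)
}

#' Compare Brownian motion, single-optimum OU and the stepwise model
#'
#' Fits Brownian motion (2 parameters per trait) and a single-regime OU
#' model (3 per trait) to the same traits and tabulates their AICc against
#' the final stepwise multi-regime model.
#'
#' @inheritParams surface_forward
#' @param surface Optionally, an already-computed `surface_result`
#'   (otherwise [surface_fit()] is run).
#' @return A tibble with one row per model: `model`, `log_lik`, `n_params`,
#'   `aicc`, `delta_aicc` (relative to the best model, 0 by construction).
#' @export
compare_models <- function(tree, traits, surface = NULL,
                           alpha_grid = default_alpha_grid(),
                           x0_policy = "root-theta",
                           n_convention = c("tips_x_traits", "tips"),
                           shift_cost = log(nrow(tree$edge))) {
  n_convention <- match.arg(n_convention)
  Y <- as_trait_matrix(traits, tree)
  n <- nrow(Y)
  p_traits <- ncol(Y)
  n_obs <- if (n_convention == "tips_x_traits") n * p_traits else n
  bm_ll <- sum(vapply(seq_len(p_traits),
                      function(j) bm_loglik(tree, Y[, j])$log_lik, 0))
  bm_p <- 2L * p_traits
  ou1 <- hansen_fit(tree, regime_painting(tree), Y, alpha_grid = alpha_grid,
                    x0_policy = x0_policy, n_convention = n_convention)
  if (is.null(surface)) {
    surface <- surface_fit(tree, Y, alpha_grid = alpha_grid,
                           x0_policy = x0_policy,
                           n_convention = n_convention,
                           shift_cost = shift_cost)
  }
  out <- tibble::tibble(
    model = c("BM", "OU1", "surface"),
    log_lik = c(bm_ll, ou1$log_lik, surface$fit$log_lik),
    n_params = c(bm_p, ou1$n_params, surface$fit$n_params),
    aicc = c(aicc(bm_ll, bm_p, n_obs), ou1$aicc, surface$fit$aicc)
  )
  out$delta_aicc <- out$aicc - min(out$aicc)
  attr(out, "surface") <- surface
  out
}
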