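#' Tidy a Hansen fit
#'
#' @param x A [hansen_fit()].
#' @param what `"rates"` (per-trait alpha, sigma2, log-likelihood,
#'   half-life) or `"optima"` (long tibble of regime optima).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hansen_fit <- function(x, what = c("rates", "optima"), ...) {
  what <- match.arg(what)
  if (what == "rates") return(x$traits)
  tibble::as_tibble(x$thetas, rownames = "regime") |>
    tidyr::pivot_longer(-"regime", names_to = "trait", values_to = "theta")
}

#' @export
glance.hansen_fit <- function(x, ...) {
  tibble::tibble(log_lik = x$log_lik, n_params = x$n_params,
                 n_obs = x$n_obs, aicc = x$aicc,
                 n_regimes = x$painting$n_regimes,
                 n_shifts = length(x$painting$shift_edges))
}

#' Tidy a stepwise search result (AICc history)
#'
#' @param x A `surface_result`.
#' @param ... Unused.
#' @return The step-by-step history tibble (`step`, `action`, `edge`, `k`,
#'   `aicc`).
#' @export
tidy.surface_result <- function(x, ...) x$history

#' @export
glance.surface_result <- function(x, ...) {
  tibble::tibble(phase = x$phase, k = x$k,
                 k_prime = x$k_prime %||% NA_integer_,
                 n_convergent = length(x$convergent %||% integer(0)),
                 aicc = x$fit$aicc, log_lik = x$fit$log_lik)
}

#' @export
tidy.kmult_result <- function(x, ...) {
  tibble::tibble(statistic = x$K, p_value = x$p_value,
                 n_permutations = x$n_permutations,
                 n = x$n, n_traits = x$p_traits)
}

#' @export
tidy.dpgls_result <- function(x, ...) {
  tibble::tibble(r2 = x$r2, p_value = x$p_value,
                 n_permutations = x$n_permutations, n = x$n)
}

#' Morphospace plot of a between-group PCA
#'
#' Individual specimens as points, group means as larger labelled points.
#'
#' @param object A `shape_space`.
#' @param axes Which two axes to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_space <- function(object, axes = c(1L, 2L), ...) {
  ax <- paste0("PC", axes)
  if (!all(ax %in% names(object$group_scores))) {
    stop("requested axes beyond the rank of the shape space", call. = FALSE)
  }
  sp <- object$specimen_scores
  gm <- object$group_scores
  ggplot2::ggplot(sp, ggplot2::aes(x = .data[[ax[1L]]], y = .data[[ax[2L]]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.6,
                        size = 1.5) +
    ggplot2::geom_point(data = gm,
                        ggplot2::aes(fill = .data$group,
                                     shape = .data$in_eigenanalysis),
                        size = 3, colour = "black") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 21, `FALSE` = 24)) +
    ggplot2::labs(x = ax[1L], y = ax[2L], shape = "in eigenanalysis") +
    ggplot2::theme_minimal()
}

#' AICc trajectory of a stepwise search
#'
#' @param object A `surface_result`.
#' @param ... Unused.
#' @return A ggplot object showing the AICc after each accepted step.
#' @export
autoplot.surface_result <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$aicc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$action), size = 2) +
    ggplot2::labs(x = "step", y = "summed AICc") +
    ggplot2::theme_minimal()
}
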