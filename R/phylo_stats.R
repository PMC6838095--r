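#' Coerce traits to a species-by-trait matrix matched to a tree
#'
#' Accepts a data frame with a `species` column and numeric trait columns,
#' a numeric matrix with species rownames, or a named numeric vector, and
#' returns a matrix with one row per tip in the tree's tip order. The
#' species set must equal the tree's tip set and no cell may be missing.
#'
#' @param traits Trait data in any of the accepted forms.
#' @param tree A `phylo` object.
#' @return A numeric matrix (n tips x p traits) with tip-label rownames.
#' @export
as_trait_matrix <- function(traits, tree) {
  if (is.data.frame(traits)) {
    stopifnot("species" %in% names(traits))
    sp <- as.character(traits$species)
    M <- as.matrix(traits[setdiff(names(traits), "species")])
    rownames(M) <- sp
  } else if (is.matrix(traits)) {
    M <- traits
  } else {
    M <- matrix(traits, ncol = 1L, dimnames = list(names(traits), "trait"))
  }
  if (is.null(rownames(M))) {
    if (nrow(M) != ape::Ntip(tree)) stop("unnamed traits of wrong length", call. = FALSE)
    rownames(M) <- tree$tip.label
  }
  extra <- setdiff(rownames(M), tree$tip.label)
  miss <- setdiff(tree$tip.label, rownames(M))
  if (length(extra) || length(miss)) {
    stop("species/tip mismatch; missing from traits: ",
         paste(miss, collapse = ", "), "; absent from tree: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  M <- M[tree$tip.label, , drop = FALSE]
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("missing trait values", call. = FALSE)
  if (is.null(colnames(M))) colnames(M) <- paste0("trait", seq_len(ncol(M)))
  M
}

#' Multivariate phylogenetic signal (generalized Blomberg's K)
#'
#' The high-dimensional generalization of Blomberg's K: the ratio of the
#' summed squared distances of tip values from the GLS-estimated root
#' state in the raw versus the phylogenetically transformed space, scaled
#' by its expectation under Brownian motion, so K has expectation 1 under
#' Brownian evolution, < 1 for less phylogenetic signal and > 1 for more.
#' Significance comes from permuting trait values across the tips of the
#' phylogeny. Reduces to the classic univariate K for a single trait, and
#' handles non-contemporaneous (fossil) tips through the unequal diagonal
#' of the phylogenetic covariance matrix.
#'
#' @param tree A `phylo` object with >= 4 tips.
#' @param traits Species x traits data (see [as_trait_matrix()]).
#' @param n_perm Number of permutation rounds (0 skips the test).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `kmult_result` with `K`, `p_value`
#'   (`(count(K_perm >= K_obs) + 1) / (n_perm + 1)`), `n_permutations`,
#'   and the permuted statistics.
#' @export
kmult <- function(tree, traits, n_perm = 999L, seed = NULL) {
  Y <- as_trait_matrix(traits, tree)
  n <- nrow(Y)
  stopifnot(n >= 4L)
  C <- phylo_covariance(tree)
  U <- chol(C)
  Cinv1 <- backsolve(U, backsolve(U, rep(1, n), transpose = TRUE))
  sum_cinv <- sum(Cinv1)
  w <- Cinv1 / sum_cinv                 # GLS root-state weights
  expected <- (sum(diag(C)) - n / sum_cinv) / (n - 1)
  k_stat <- function(Ym) {
    a <- crossprod(w, Ym)               # 1 x p generalized mean
    R <- sweep(Ym, 2L, as.numeric(a))
    ss0 <- sum(R^2)
    ssc <- sum(backsolve(U, R, transpose = TRUE)^2)
    if (ss0 < .Machine$double.eps * n) {
      stop("degenerate data: traits are constant across tips", call. = FALSE)
    }
    (ss0 / ssc) / expected
  }
  K <- k_stat(Y)
  perm_K <- numeric(0)
  p_value <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    perm_K <- vapply(seq_len(n_perm), function(i) {
      k_stat(Y[sample.int(n), , drop = FALSE])
    }, 0)
    p_value <- (sum(perm_K >= K) + 1) / (n_perm + 1)
  }
  structure(list(K = K, p_value = p_value, n_permutations = n_perm,
                 perm_K = perm_K, n = n, p_traits = ncol(Y), seed = seed),
            class = "kmult_result")
}

#' @export
print.kmult_result <- function(x, ...) {
  cat(sprintf("Generalized Blomberg's K: K = %.4f (n = %d, traits = %d)\n",
              x$K, x$n, x$p_traits))
  if (x$n_permutations > 0) {
    cat(sprintf("permutation p = %.4g (%d rounds)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Phylogenetic multivariate regression of shape on size (D-PGLS)
#'
#' Regresses a multivariate response (e.g. all Procrustes coordinates) on
#' one or more predictors (e.g. centroid size) in the phylogenetically
#' transformed space: both sides are premultiplied by the inverse Cholesky
#' factor of the phylogenetic covariance matrix and fitted by least
#' squares. The effect size is `r2 = 1 - RSS_full / RSS_intercept`, the
#' explained fraction of the total transformed sum of squares, and the
#' p-value comes from permuting the predictor values across tips.
#'
#' @param tree A `phylo` object.
#' @param shape Species x p response data (see [as_trait_matrix()]).
#' @param size Species x q predictor data (vector, matrix or data frame).
#' @param n_perm Permutation rounds (0 skips the test).
#' @param seed Optional integer seed.
#' @return An object of class `dpgls_result` with `r2`, `p_value`,
#'   `n_permutations` and the permuted statistics.
#' @export
dpgls_shape_size <- function(tree, shape, size, n_perm = 999L, seed = NULL) {
  Y <- as_trait_matrix(shape, tree)
  X <- as_trait_matrix(size, tree)
  n <- nrow(Y)
  C <- phylo_covariance(tree)
  U <- tryCatch(chol(C), error = function(e) {
    stop("singular phylogenetic covariance; consider jittering zero ",
         "branch lengths", call. = FALSE)
  })
  TY <- backsolve(U, Y, transpose = TRUE)
  Tone <- backsolve(U, rep(1, n), transpose = TRUE)
  rss_reduced <- sum(stats::lm.fit(cbind(Tone), TY)$residuals^2)
  r2_of <- function(Xm) {
    TX <- backsolve(U, Xm, transpose = TRUE)
    rss_full <- sum(stats::lm.fit(cbind(Tone, TX), TY)$residuals^2)
    1 - rss_full / rss_reduced
  }
  r2 <- r2_of(X)
  perm_r2 <- numeric(0)
  p_value <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    perm_r2 <- vapply(seq_len(n_perm), function(i) {
      r2_of(X[sample.int(n), , drop = FALSE])
    }, 0)
    p_value <- (sum(perm_r2 >= r2) + 1) / (n_perm + 1)
  }
  structure(list(r2 = r2, p_value = p_value, n_permutations = n_perm,
                 perm_r2 = perm_r2, n = n, seed = seed),
            class = "dpgls_result")
}

#' @export
print.dpgls_result <- function(x, ...) {
  cat(sprintf("Phylogenetic multivariate regression: r2 = %.4f\n", x$r2))
  if (x$n_permutations > 0) {
    cat(sprintf("permutation p = %.4g (%d rounds)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}
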