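#' Build a landmark set from a long-format table
#'
#' @param df A data frame with one row per specimen-landmark: columns
#'   `specimen`, `species`, `landmark` (1..k), `x`, `y`, `z` (mm), and
#'   optionally `group` (defaults to `species`) and `is_fossil` (defaults to
#'   `FALSE`). Every specimen must carry the same complete set of landmarks.
#' @return An object of class `landmark_set`: `coords` (k x 3 x n array) and
#'   `specimens` (tibble with one row per specimen).
#' @export
landmark_set <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("specimen", "species", "landmark", "x", "y", "z") %in% names(df)))
  df <- dplyr::arrange(dplyr::as_tibble(df), .data$specimen, .data$landmark)
  ids <- unique(df$specimen)
  ks <- table(df$specimen)
  if (length(unique(ks)) != 1L) {
    stop("specimens differ in landmark count: ",
         paste(names(ks)[ks != ks[1L]][1L]), call. = FALSE)
  }
  k <- unname(ks[1L])
  if (anyNA(df[c("x", "y", "z")])) stop("missing landmark coordinates", call. = FALSE)
  n <- length(ids)
  coords <- array(NA_real_, c(k, 3L, n),
                  dimnames = list(NULL, c("x", "y", "z"), ids))
  for (i in seq_len(n)) {
    sub <- df[df$specimen == ids[i], ]
    if (!identical(sort(sub$landmark), sort(unique(df$landmark)))) {
      stop("specimen ", ids[i], " is missing landmarks", call. = FALSE)
    }
    coords[, , i] <- as.matrix(sub[order(sub$landmark), c("x", "y", "z")])
  }
  info <- dplyr::distinct(df, .data$specimen, .keep_all = TRUE)
  specimens <- tibble::tibble(
    specimen = as.character(info$specimen),
    species = as.character(info$species),
    group = if ("group" %in% names(info)) as.character(info$group) else as.character(info$species),
    is_fossil = if ("is_fossil" %in% names(info)) as.logical(info$is_fossil) else FALSE
  )
  structure(list(coords = coords, specimens = specimens), class = "landmark_set")
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid; invariant to rotation and translation, homogeneous of
#' degree 1 under scaling.
#'
#' @param config A k x 3 (or k x d) coordinate matrix.
#' @return Centroid size in the units of the coordinates (mm).
#' @examples
#' centroid_size(rbind(c(0, 0, 0), c(3, 4, 0))) # sqrt(12.5)
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  stopifnot(nrow(config) >= 2L)
  cen <- sweep(config, 2L, colMeans(config))
  sqrt(sum(cen^2))
}

# Rotation (no reflection) carrying centred X onto centred Y.
opa_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes alignment with tangent projection
#'
#' Iteratively centres each configuration, scales it to unit centroid size,
#' and rotates it onto the running consensus (orthogonal Procrustes via SVD,
#' reflections excluded) until the consensus stabilises, then orthogonally
#' projects the aligned shapes onto the tangent plane at the consensus.
#' Centroid sizes are retained (with natural logs) as size traits.
#'
#' @param lms A [landmark_set()].
#' @param tol Convergence tolerance on the consensus displacement.
#' @param max_iter Maximum superimposition iterations.
#' @return An object of class `aligned_shapes`: `coords` (k x 3 x n tangent
#'   coordinates), `consensus` (k x 3, unit centroid size), and `specimens`
#'   with `centroid_size` and `ln_cs` columns appended.
#' @export
gpa <- function(lms, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(lms, "landmark_set"))
  coords <- lms$coords
  k <- dim(coords)[1L]
  n <- dim(coords)[3L]
  if (k < 4L) stop("need at least 4 landmarks", call. = FALSE)
  cs <- numeric(n)
  X <- coords
  for (i in seq_len(n)) {
    cen <- sweep(coords[, , i], 2L, colMeans(coords[, , i]))
    cs[i] <- sqrt(sum(cen^2))
    if (cs[i] <= .Machine$double.eps) {
      stop("specimen ", dimnames(coords)[[3L]][i],
           " has zero centroid size", call. = FALSE)
    }
    if (qr(cen)$rank < 3L) {
      stop("degenerate (rank < 3) configuration for specimen ",
           dimnames(coords)[[3L]][i], call. = FALSE)
    }
    X[, , i] <- cen / cs[i]
  }
  consensus <- X[, , 1L]
  delta <- Inf
  iter <- 0L
  while (delta >= tol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("Procrustes superimposition did not converge after ", max_iter,
           " iterations (last consensus change ", format(delta), ")",
           call. = FALSE)
    }
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% opa_rotation(X[, , i], consensus)
    new_consensus <- apply(X, c(1L, 2L), mean)
    new_consensus <- sweep(new_consensus, 2L, colMeans(new_consensus))
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  # canonical orientation: principal axes of the consensus, signs fixed by
  # the largest-magnitude coordinate, so the alignment does not depend on
  # the original orientation of any input specimen
  R <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  rot <- consensus %*% R
  for (j in 1:3) {
    if (rot[which.max(abs(rot[, j])), j] < 0) R[, j] <- -R[, j]
  }
  if (det(R) < 0) R[, 3L] <- -R[, 3L]
  consensus <- consensus %*% R
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% R

  # orthogonal projection onto the tangent plane at the consensus
  cvec <- as.vector(consensus)
  for (i in seq_len(n)) {
    x <- as.vector(X[, , i])
    X[, , i] <- X[, , i] + consensus * (1 - sum(x * cvec))
  }
  specimens <- dplyr::mutate(lms$specimens,
                             centroid_size = cs, ln_cs = log(cs))
  structure(list(coords = X, consensus = consensus, specimens = specimens,
                 iterations = iter, tol = tol),
            class = "aligned_shapes")
}

# flatten k x 3 x n -> n x 3k
flatten_shapes <- function(coords) {
  n <- dim(coords)[3L]
  t(matrix(coords, ncol = n))
}

#' Between-group principal component analysis of aligned shapes
#'
#' Eigenanalysis of the covariance matrix of group-mean tangent
#' coordinates (groups are typically species means, optionally including
#' fossil individuals), with all individual specimens projected onto the
#' resulting axes a posteriori. The number of non-null axes is at most
#' one less than the number of groups in the eigenanalysis. Supports the
#' variant where fossils are excluded from the eigenanalysis and projected
#' afterwards via `include`.
#'
#' @param aligned An [gpa()] result.
#' @param groups Name of the column of `aligned$specimens` defining groups
#'   (default `"species"`), or a character vector with one label per
#'   specimen.
#' @param include Optional character vector of group labels entering the
#'   eigenanalysis (default: all groups). Specimens in other groups still
#'   receive scores by projection.
#' @return An object of class `shape_space`: orthonormal `eigenvectors`
#'   (3k x m), `eigenvalues` (descending), `center` (grand mean of the
#'   eigenanalysis set), `group_scores` and `specimen_scores` tibbles.
#' @export
bgpca <- function(aligned, groups = "species", include = NULL) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  spec <- aligned$specimens
  glab <- if (length(groups) == 1L && groups %in% names(spec)) {
    as.character(spec[[groups]])
  } else {
    stopifnot(length(groups) == nrow(spec))
    as.character(groups)
  }
  X <- flatten_shapes(aligned$coords)
  all_groups <- unique(glab)
  if (is.null(include)) include <- all_groups
  missing_groups <- setdiff(include, all_groups)
  if (length(missing_groups)) {
    stop("group label(s) absent from data: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  if (length(include) < 2L) stop("need >= 2 groups in the eigenanalysis", call. = FALSE)
  gm <- do.call(rbind, lapply(all_groups, function(g) {
    colMeans(X[glab == g, , drop = FALSE])
  }))
  rownames(gm) <- all_groups
  E <- gm[include, , drop = FALSE]
  center <- colMeans(E)
  S <- crossprod(sweep(E, 2L, center)) / (length(include) - 1)
  eig <- eigen(S, symmetric = TRUE)
  keep <- which(eig$values > max(eig$values) * 1e-10)
  keep <- head(keep, length(include) - 1L)
  vec <- eig$vectors[, keep, drop = FALSE]
  val <- eig$values[keep]
  # reproducible axis orientation: largest-magnitude loading positive
  for (j in seq_len(ncol(vec))) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  axis_names <- paste0("PC", seq_along(val))
  score_tbl <- function(M) {
    s <- sweep(M, 2L, center) %*% vec
    colnames(s) <- axis_names
    tibble::as_tibble(s)
  }
  group_scores <- dplyr::bind_cols(
    tibble::tibble(group = all_groups,
                   in_eigenanalysis = all_groups %in% include),
    score_tbl(gm)
  )
  specimen_scores <- dplyr::bind_cols(spec, score_tbl(X))
  structure(list(eigenvectors = vec, eigenvalues = val, center = center,
                 consensus = aligned$consensus,
                 groups_in_eigenanalysis = include,
                 group_means = gm,
                 group_scores = group_scores,
                 specimen_scores = specimen_scores,
                 k = dim(aligned$coords)[1L]),
            class = "shape_space")
}

#' Project aligned configurations into an existing shape space
#'
#' Scores are computed relative to the grand mean of the eigenanalysis set;
#' appending projected points never alters the eigenbasis.
#'
#' @param space A [bgpca()] result.
#' @param configs A k x 3 matrix, a k x 3 x m array of configurations
#'   aligned in the same Procrustes frame, or an m x 3k matrix of flattened
#'   tangent coordinates.
#' @return A tibble of scores (one row per configuration).
#' @export
project_shapes <- function(space, configs) {
  stopifnot(inherits(space, "shape_space"))
  p <- nrow(space$eigenvectors)
  M <- if (is.array(configs) && length(dim(configs)) == 3L) {
    flatten_shapes(configs)
  } else if (is.matrix(configs) && ncol(configs) == 3L && nrow(configs) == space$k) {
    matrix(as.vector(configs), nrow = 1L)
  } else if (is.matrix(configs)) {
    configs
  } else {
    matrix(as.vector(configs), nrow = 1L)
  }
  if (ncol(M) != p) {
    stop("dimension mismatch: configurations have ", ncol(M),
         " coordinates, shape space expects ", p, call. = FALSE)
  }
  s <- sweep(M, 2L, space$center) %*% space$eigenvectors
  colnames(s) <- paste0("PC", seq_len(ncol(s)))
  tibble::as_tibble(s)
}

#' Align a raw configuration onto a Procrustes consensus (OPA)
#'
#' Centres and unit-scales a single configuration, rotates it onto the
#' consensus of an existing alignment, and applies the same tangent
#' projection -- the path used to place fossils in a morphospace they did
#' not help build.
#'
#' @param aligned An [gpa()] result (or a `shape_space`).
#' @param config A k x 3 raw coordinate matrix.
#' @return A k x 3 matrix of tangent coordinates in the consensus frame.
#' @export
opa_align <- function(aligned, config) {
  consensus <- aligned$consensus
  stopifnot(!is.null(consensus), nrow(config) == nrow(consensus))
  cen <- sweep(as.matrix(config), 2L, colMeans(config))
  cs <- sqrt(sum(cen^2))
  if (cs <= .Machine$double.eps) stop("zero centroid size", call. = FALSE)
  Xi <- cen / cs
  Xi <- Xi %*% opa_rotation(Xi, consensus)
  cvec <- as.vector(consensus)
  Xi + consensus * (1 - sum(as.vector(Xi) * cvec))
}

#' Species mean shapes and sizes
#'
#' @param aligned An [gpa()] result.
#' @param fossil_as_is If `TRUE` (default) fossil specimens are averaged per
#'   species like any other.
#' @return A list with `coords` (k x 3 x n_species mean tangent shapes),
#'   `species`, and a tibble `sizes` (species, mean `ln_cs`, mean
#'   `centroid_size`, `is_fossil`).
#' @export
species_means <- function(aligned, fossil_as_is = TRUE) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  spp <- unique(aligned$specimens$species)
  k <- dim(aligned$coords)[1L]
  out <- array(NA_real_, c(k, 3L, length(spp)),
               dimnames = list(NULL, c("x", "y", "z"), spp))
  for (i in seq_along(spp)) {
    idx <- which(aligned$specimens$species == spp[i])
    out[, , i] <- apply(aligned$coords[, , idx, drop = FALSE], c(1L, 2L), mean)
  }
  sizes <- aligned$specimens |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(ln_cs = mean(.data$ln_cs),
                     centroid_size = mean(.data$centroid_size),
                     is_fossil = any(.data$is_fossil), .groups = "drop")
  list(coords = out, species = spp, sizes = sizes)
}
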