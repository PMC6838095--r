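# Independent oracles used to freeze expected values. These deliberately
# avoid the package's computational paths (weight matrices, Cholesky
# profiling): moments come from a node-by-node recursion over the tree and
# densities from mvtnorm.

# Tip means and covariance of a painted OU process by recursion over nodes:
# E[child] = theta_r + (E[parent] - theta_r) e^{-a t},
# V[child] = V[parent] e^{-2 a t} + s2 (1 - e^{-2 a t}) / (2 a),
# Cov(i, j) = V[mrca] e^{-a (d_i + d_j)} with d_* the path from the mrca.
oracle_ou_moments <- function(tree, painting, alpha, sigma2, theta, x0) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  m <- v <- rep(NA_real_, nn)
  m[root] <- x0
  v[root] <- 0
  ord <- stats::reorder(tree, "cladewise")$edge
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  for (r in seq_len(nrow(ord))) {
    e <- match(paste(ord[r, 1], ord[r, 2]), key)
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    th <- theta[painting$regime_of_edge[e]]
    m[ch] <- th + (m[p] - th) * exp(-alpha * t)
    v[ch] <- v[p] * exp(-2 * alpha * t) +
      sigma2 * (1 - exp(-2 * alpha * t)) / (2 * alpha)
  }
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree)
  V <- matrix(NA_real_, ntip, ntip)
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      a <- if (i == j) i else mr[i, j]
      V[i, j] <- v[a] * exp(-alpha * (depth[i] + depth[j] - 2 * depth[a]))
    }
  }
  list(mean = m[seq_len(ntip)], cov = V)
}

# Classic univariate Blomberg's K written out with explicit solve()
# arithmetic (no Cholesky shortcuts).
oracle_classic_K <- function(tree, x) {
  C <- ape::vcv.phylo(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Cinv <- solve(C)
  one <- rep(1, n)
  a <- as.numeric((t(one) %*% Cinv %*% x) / (t(one) %*% Cinv %*% one))
  r <- x - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% Cinv %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  (mse0 / mse) / expected
}

# Whether a recovered shift edge matches a true one exactly or on an
# adjacent branch (parent edge or either child edge of the shifted node).
edge_neighbourhood <- function(tree, e) {
  child <- tree$edge[e, 2]
  parent <- tree$edge[e, 1]
  c(e,
    which(tree$edge[, 2] == parent),
    which(tree$edge[, 1] == child))
}
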