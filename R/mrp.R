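#' Matrix representation of source trees (Baum/Ragan encoding)
#'
#' Encodes every non-trivial clade of every source tree as a binary
#' character: members of the clade score 1, other taxa present in the same
#' source score 0, and taxa absent from that source are missing. Columns are
#' equally weighted; polytomies contribute one column per (multifurcating)
#' internal node, the soft-polytomy convention.
#'
#' @param source_trees A `phylo` object or list/`multiPhylo` of them, each
#'   with at least 3 tips.
#' @return An object of class `mrp_matrix`: a list with `taxa` (union of
#'   tip labels), `mat` (taxa x characters, values 0/1/`NA`), and `source`
#'   (source-tree index of each column).
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),C);")
#' t2 <- ape::read.tree(text = "((B,D),E);")
#' m <- mrp_encode(list(t1, t2))
#' m$mat
#' @export
mrp_encode <- function(source_trees) {
  if (inherits(source_trees, "phylo")) source_trees <- list(source_trees)
  stopifnot(length(source_trees) >= 1L)
  for (i in seq_along(source_trees)) {
    tr <- source_trees[[i]]
    if (!inherits(tr, "phylo") || ape::Ntip(tr) < 3L) {
      stop("source tree ", i, " is not a phylo with >= 3 tips", call. = FALSE)
    }
    if (anyDuplicated(tr$tip.label)) {
      stop("duplicate tip labels within source tree ", i, call. = FALSE)
    }
  }
  taxa <- sort(unique(unlist(lapply(source_trees, `[[`, "tip.label"))))
  cols <- list()
  src <- integer()
  for (i in seq_along(source_trees)) {
    tr <- source_trees[[i]]
    ntip <- ape::Ntip(tr)
    root <- setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
    internals <- setdiff(unique(tr$edge[, 1L]), root)
    for (nd in internals) {
      clade <- tr$tip.label[phangorn::Descendants(tr, nd, "tips")[[1L]]]
      if (length(clade) < 2L || length(clade) >= ntip) next
      col <- rep(NA_integer_, length(taxa))
      col[taxa %in% tr$tip.label] <- 0L
      col[taxa %in% clade] <- 1L
      cols[[length(cols) + 1L]] <- col
      src <- c(src, i)
    }
  }
  mat <- do.call(cbind, cols)
  if (is.null(mat)) mat <- matrix(integer(), nrow = length(taxa), ncol = 0L)
  rownames(mat) <- taxa
  structure(list(taxa = taxa, mat = mat, source = src), class = "mrp_matrix")
}

# Fitch state masks: 1 = {0}, 2 = {1}, 3 = {0,1} (missing / ambiguous)
fitch_masks <- function(mat) {
  m <- matrix(3L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  m[which(mat == 0L)] <- 1L
  m[which(mat == 1L)] <- 2L
  m
}

#' Fitch parsimony length of a tree on an MRP matrix
#'
#' Bottom-up Fitch counting summed over characters; missing entries act as
#' fully ambiguous states and an all-missing column contributes 0 steps.
#' Exact for binary trees (polytomies are folded pairwise).
#'
#' @param tree A `phylo` topology whose tips are a subset of `mrp$taxa`.
#' @param mrp An [mrp_encode()] result (or a compatible list with `taxa`
#'   and 0/1/`NA` matrix `mat`).
#' @return Integer total number of steps.
#' @export
parsimony_score <- function(tree, mrp) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, mrp$taxa)
  if (length(miss)) {
    stop("tree tips absent from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nc <- ncol(mrp$mat)
  if (nc == 0L) return(0L)
  ntip <- ape::Ntip(tree)
  masks <- fitch_masks(mrp$mat)[tree$tip.label, , drop = FALSE]
  tr <- stats::reorder(tree, "postorder")
  M <- matrix(0L, ntip + tr$Nnode, nc)
  M[seq_len(ntip), ] <- masks
  steps <- integer(nc)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]
    ch <- tr$edge[i, 2L]
    cm <- M[ch, ]
    pm <- M[p, ]
    if (all(pm == 0L)) {
      M[p, ] <- cm
    } else {
      inter <- bitwAnd(pm, cm)
      empty <- inter == 0L
      steps[empty] <- steps[empty] + 1L
      inter[empty] <- bitwOr(pm, cm)[empty]
      M[p, ] <- inter
    }
  }
  sum(steps)
}

#' MRP supertree by parsimony search
#'
#' Finds a minimum-length topology for an MRP matrix. A hypothetical
#' all-zero outgroup roots the search (standard MRP practice): taxon sets of
#' up to `exhaustive_max` are scored exhaustively over all unrooted
#' topologies; larger sets use a seeded parsimony-ratchet heuristic and the
#' best tree found is returned with a `heuristic` attribute.
#'
#' @param mrp An [mrp_encode()] result over at least 4 taxa.
#' @param seed Integer seed for the heuristic search (tie-breaking and
#'   restarts).
#' @param exhaustive_max Largest taxon count searched exhaustively.
#' @return A rooted `phylo` topology over `mrp$taxa` (no branch lengths),
#'   with attribute `score` (parsimony length) and `heuristic` (logical).
#' @export
mrp_supertree <- function(mrp, seed = 42L, exhaustive_max = 8L) {
  taxa <- mrp$taxa
  n <- length(taxa)
  if (n < 4L) stop("need >= 4 taxa for a supertree search", call. = FALSE)
  og <- "MRP_outgroup_"
  chars <- rbind(mrp$mat, matrix(0L, 1L, ncol(mrp$mat),
                                 dimnames = list(og, NULL)))
  cm <- matrix(as.character(chars), nrow(chars), ncol(chars),
               dimnames = dimnames(chars))
  cm[is.na(chars)] <- "?"
  dat <- phangorn::phyDat(cm, type = "USER", levels = c("0", "1"),
                          ambiguity = "?")
  heuristic <- n > exhaustive_max
  if (!heuristic) {
    cand <- phangorn::allTrees(n + 1L, rooted = FALSE,
                               tip.label = c(taxa, og))
    scores <- phangorn::parsimony(cand, dat)
    best <- cand[[which.min(scores)]]
    score <- min(scores)
  } else {
    set.seed(seed)
    best <- phangorn::pratchet(dat, trace = 0, all = FALSE)
    if (inherits(best, "multiPhylo")) best <- best[[1L]]
    score <- phangorn::parsimony(best, dat)
  }
  rooted <- ape::root(best, outgroup = og, resolve.root = TRUE)
  out <- ape::drop.tip(rooted, og)
  out$edge.length <- NULL
  attr(out, "score") <- as.integer(score)
  attr(out, "heuristic") <- heuristic
  out
}
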