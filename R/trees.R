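#' Read a time-calibrated phylogeny from Newick or Nexus
#'
#' Parses a tree from a file path or a literal Newick/Nexus string and
#' validates it as a time tree: numeric non-negative branch lengths in
#' millions of years (Ma), unique tip labels and a single root. Trees are
#' not required to be ultrametric -- fossil tips sit at positive ages.
#'
#' @param x A file path, or a character string containing a Newick tree
#'   (terminated by `;`) or a Nexus `TREES` block (starting with `#NEXUS`).
#' @return An object of class `phylo` (see [ape::read.tree()]).
#' @examples
#' tr <- read_timetree("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
read_timetree <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("[(;]", x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    x
  }
  # branch annotations ([&regime=k] and friends) are metadata, not topology
  txt_clean <- gsub("\\[&[^]]*\\]", "", txt)
  tr <- if (grepl("^\\s*#NEXUS", txt_clean, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".nex")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(txt_clean, tmp)
    out <- ape::read.nexus(tmp)
    if (inherits(out, "multiPhylo")) out[[1L]] else out
  } else {
    suppressWarnings(tryCatch(
      ape::read.tree(text = txt_clean),
      error = function(e) NULL
    ))
  }
  if (is.null(tr) || !inherits(tr, "phylo")) {
    bad <- sub("^[^(]*", "", substr(txt_clean, 1, 40))
    stop("failed to parse tree text near: '", bad, "'", call. = FALSE)
  }
  validate_timetree(tr)
  tr
}

#' Write a time tree to Newick or Nexus
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the serialized tree is returned as a
#'   character string.
#' @param format `"newick"` or `"nexus"`.
#' @return The file path (invisibly) or the serialized string.
#' @export
write_timetree <- function(tree, file = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  validate_timetree(tree)
  if (format == "newick") {
    if (is.null(file)) return(ape::write.tree(tree, digits = 15))
    ape::write.tree(tree, file = file, digits = 15)
  } else {
    if (is.null(file)) {
      tmp <- tempfile(fileext = ".nex")
      on.exit(unlink(tmp), add = TRUE)
      ape::write.nexus(tree, file = tmp)
      return(paste(readLines(tmp, warn = FALSE), collapse = "\n"))
    }
    ape::write.nexus(tree, file = file)
  }
  invisible(file)
}

#' Validate time-tree invariants
#'
#' Checks branch lengths (present, numeric, non-negative), unique tip
#' labels, and a single root. Errors describe the offending element.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly.
#' @export
validate_timetree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a time tree requires lengths in Ma",
         call. = FALSE)
  }
  if (anyNA(tree$edge.length) || !is.numeric(tree$edge.length)) {
    stop("non-numeric branch length", call. = FALSE)
  }
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    stop("negative branch length on edge ", neg[1L], " (",
         format(tree$edge.length[neg[1L]]), " Ma)", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ",
         tree$tip.label[anyDuplicated(tree$tip.label)], call. = FALSE)
  }
  # in ape's representation every node except the root has exactly one parent
  kids <- tabulate(tree$edge[, 2L], nbins = ape::Ntip(tree) + tree$Nnode)
  if (any(kids > 1L)) stop("node with more than one parent", call. = FALSE)
  invisible(tree)
}

#' Node ages in Ma before present
#'
#' The root age is taken as the maximum root-to-tip path length, so the
#' deepest tip sits at age 0 and fossil tips at positive ages.
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector over tips then internal nodes
#'   (ape node numbering), ages in Ma.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  ages <- max(depth[seq_len(ntip)]) - depth
  names(ages) <- c(tree$tip.label,
                   if (is.null(tree$node.label)) {
                     as.character(ntip + seq_len(tree$Nnode))
                   } else tree$node.label)
  ages
}

#' Midpoint of a geological age range
#'
#' Collapses a stratigraphic age bracket to a point estimate for use as a
#' fossil tip age, e.g. `midpoint_age(29.5, 30.2)` gives 29.85 Ma.
#'
#' @param lower,upper Bounds of the range in Ma, `lower <= upper`.
#' @return `(lower + upper) / 2` in Ma.
#' @export
midpoint_age <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (any(lower > upper)) {
    stop("reversed age range: lower bound exceeds upper bound", call. = FALSE)
  }
  (lower + upper) / 2
}

#' Graft a fossil tip onto a dated backbone tree
#'
#' Attaches an extinct taxon as sister to `attachment` (a tip label or the
#' clade spanned by several tip labels). The new attachment node is placed
#' 1 Ma older than the adjacent crown node when the fossil is younger than
#' that node, and 1 Ma older than the fossil's own geological age when the
#' fossil is older -- i.e. at `max(age(crown node), tip_age) + 1` Ma. The
#' fossil's pendant branch then spans from the attachment node down to its
#' geological age.
#'
#' @param backbone A dated `phylo` tree.
#' @param taxon Name of the fossil tip to add.
#' @param tip_age Geological age of the fossil in Ma (> 0 typically).
#' @param attachment Character vector of backbone tip labels: length 1
#'   attaches the fossil as sister to that tip; length > 1 as sister to the
#'   clade spanned by their MRCA.
#' @return The enlarged `phylo` tree.
#' @examples
#' bb <- read_timetree("((A:10,B:10):15,C:25);")
#' tr <- graft_fossil(bb, "Fossil_x", tip_age = 12, attachment = c("A", "B"))
#' node_ages(tr)[["Fossil_x"]]
#' @export
graft_fossil <- function(backbone, taxon, tip_age, attachment) {
  validate_timetree(backbone)
  stopifnot(is.character(taxon), length(taxon) == 1L, tip_age >= 0)
  miss <- setdiff(attachment, backbone$tip.label)
  if (length(miss)) {
    stop("attachment taxa not in backbone: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ages <- node_ages(backbone)
  node <- if (length(attachment) == 1L) {
    match(attachment, backbone$tip.label)
  } else {
    ape::getMRCA(backbone, attachment)
  }
  crown_age <- ages[[node]]
  attach_age <- max(crown_age, tip_age) + 1.0
  ntip <- ape::Ntip(backbone)
  root <- ntip + 1L
  if (node == root) {
    stop("re-grafting conflict: attachment node is the root; the new node ",
         "at ", format(attach_age), " Ma would predate the tree", call. = FALSE)
  }
  parent <- backbone$edge[backbone$edge[, 2L] == node, 1L]
  parent_age <- ages[[parent]]
  if (attach_age >= parent_age) {
    stop("re-grafting conflict: new node at ", format(attach_age),
         " Ma is not younger than the parent node (",
         format(parent_age), " Ma)", call. = FALSE)
  }
  out <- phytools::bind.tip(
    backbone, taxon,
    edge.length = attach_age - tip_age,
    where = node,
    position = attach_age - crown_age
  )
  validate_timetree(out)
  out
}

#' Graft several fossil calibrations
#'
#' @param backbone A dated `phylo` tree.
#' @param calibrations A data frame with columns `taxon` (character),
#'   `tip_age` (Ma) and `attachment` (list-column of character vectors, or a
#'   character column of `;`-separated tip labels).
#' @return The tree with all fossils attached. The result does not depend on
#'   the grafting order when attachments are distinct backbone clades.
#' @export
graft_fossils <- function(backbone, calibrations) {
  stopifnot(is.data.frame(calibrations),
            all(c("taxon", "tip_age", "attachment") %in% names(calibrations)))
  att <- calibrations$attachment
  if (!is.list(att)) att <- strsplit(as.character(att), ";\\s*")
  tr <- backbone
  for (i in seq_len(nrow(calibrations))) {
    tr <- graft_fossil(tr, calibrations$taxon[[i]],
                       calibrations$tip_age[[i]], att[[i]])
  }
  tr
}

#' Serialize a tree with regime annotations
#'
#' Writes Newick with `[&regime=k]` comments on every branch, recording a
#' regime painting alongside the topology.
#'
#' @param tree A `phylo` object.
#' @param painting A [regime_painting] for `tree`.
#' @param file Optional output path.
#' @return The annotated Newick string (invisibly if written to `file`).
#' @export
write_regime_newick <- function(tree, painting, file = NULL) {
  stopifnot(inherits(painting, "regime_painting"))
  ntip <- ape::Ntip(tree)
  edge_of_node <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2L])
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(node) {
    lab <- if (node <= ntip) tree$tip.label[node] else ""
    inner <- if (node > ntip) {
      paste0("(", paste(vapply(kids[[as.character(node)]], rec, ""),
                        collapse = ","), ")")
    } else ""
    e <- edge_of_node[node]
    suff <- if (!is.na(e)) {
      sprintf("[&regime=%d]:%s", painting$regime_of_edge[e],
              format(tree$edge.length[e], digits = 12))
    } else ""
    paste0(inner, lab, suff)
  }
  out <- paste0(rec(ntip + 1L), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
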