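#' Run the full landmark-to-regimes analysis pipeline
#'
#' Orchestrates the end-to-end workflow: generalized Procrustes alignment,
#' species means and log centroid sizes, between-group PCA (fossils either
#' inside the eigenanalysis or projected a posteriori), multivariate
#' phylogenetic signal and shape-on-size regression, stepwise
#' adaptive-peak detection with convergence collapse on each candidate
#' tree, and model comparison against Brownian motion and single-optimum
#' OU.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{landmarks}{a [landmark_set()], a long-format data frame, or a
#'       CSV path with columns specimen, species, landmark, x, y, z
#'       (optionally group, is_fossil).}
#'     \item{trees}{a named list of `phylo` objects or tree-file paths (a
#'       single `tree` entry is also accepted).}
#'     \item{bgpca_fossils}{`"eigen"` (fossil species enter the
#'       eigenanalysis, default) or `"project"` (projected a posteriori).}
#'     \item{traits}{trait columns for evolutionary modelling, default
#'       `c("PC1", "PC2", "PC3", "ln_cs")`.}
#'     \item{n_perm}{permutation rounds for the signal tests (default 999).}
#'     \item{seed}{integer seed used for every stochastic stage.}
#'     \item{out_dir}{optional directory for stage artifacts (scores CSV,
#'       summary JSON, annotated Newick).}
#'   }
#' @return An object of class `pipeline_report`: stage results
#'   (`aligned`, `space`, `traits`, `kmult`, `kmult_size`, `dpgls`,
#'   `surface` and `comparison` per tree) and a machine-readable `summary`
#'   list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  n_perm <- config$n_perm %||% 999L
  variant <- config$bgpca_fossils %||% "eigen"
  trait_names <- config$traits %||% c("PC1", "PC2", "PC3", "ln_cs")
  stopifnot(length(trait_names) >= 1L)

  lms <- config$landmarks
  if (is.character(lms)) {
    lms <- utils::read.csv(lms, stringsAsFactors = FALSE)
  }
  if (is.data.frame(lms)) lms <- landmark_set(lms)
  stopifnot(inherits(lms, "landmark_set"))

  trees <- config$trees %||% list(tree = config$tree)
  if (inherits(trees, "phylo")) trees <- list(tree = trees)
  trees <- lapply(trees, function(t) if (is.character(t)) read_timetree(t) else t)
  if (is.null(names(trees)) || any(names(trees) == "")) {
    names(trees) <- paste0("tree", seq_along(trees))
  }

  aligned <- gpa(lms)
  sm <- species_means(aligned)
  fossil_species <- sm$sizes$species[sm$sizes$is_fossil]
  include <- if (identical(variant, "project")) {
    setdiff(sm$species, fossil_species)
  } else {
    sm$species
  }
  space <- bgpca(aligned, groups = "species", include = include)

  # reconcile species between morphometric data and every tree
  for (nm in names(trees)) {
    tips <- trees[[nm]]$tip.label
    miss <- setdiff(sm$species, tips)
    extra <- setdiff(tips, sm$species)
    if (length(miss) || length(extra)) {
      stop("species mismatch for ", nm, "; in landmarks but not tree: ",
           paste(miss, collapse = ", "), "; in tree but not landmarks: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }

  pc_cols <- grep("^PC", trait_names, value = TRUE)
  gs <- space$group_scores
  traits_tbl <- tibble::tibble(species = gs$group)
  for (pc in pc_cols) traits_tbl[[pc]] <- gs[[pc]]
  if ("ln_cs" %in% trait_names) {
    traits_tbl$ln_cs <- sm$sizes$ln_cs[match(traits_tbl$species,
                                             sm$sizes$species)]
  }

  first_tree <- trees[[1L]]
  k_shape <- kmult(first_tree, traits_tbl[c("species", pc_cols)],
                   n_perm = n_perm, seed = seed)
  k_size <- if ("ln_cs" %in% names(traits_tbl)) {
    kmult(first_tree, traits_tbl[c("species", "ln_cs")],
          n_perm = n_perm, seed = seed)
  } else NULL
  k_all <- kmult(first_tree, traits_tbl, n_perm = n_perm, seed = seed)

  shape_mat <- flatten_shapes(sm$coords)
  rownames(shape_mat) <- sm$species
  size_mat <- matrix(sm$sizes$ln_cs, dimnames = list(sm$sizes$species, "ln_cs"))
  dp <- dpgls_shape_size(first_tree, shape_mat, size_mat,
                         n_perm = n_perm, seed = seed)

  per_tree <- lapply(names(trees), function(nm) {
    tr <- trees[[nm]]
    surf <- surface_fit(tr, traits_tbl)
    cmp <- compare_models(tr, traits_tbl, surface = surf)
    list(name = nm, surface = surf, comparison = cmp)
  })
  names(per_tree) <- names(trees)

  main <- per_tree[[1L]]
  hl <- setNames(main$surface$fit$traits$half_life,
                 main$surface$fit$traits$trait)
  cmp <- main$comparison
  summary <- list(
    seed = seed,
    n_species = length(sm$species),
    n_fossil_species = length(fossil_species),
    bgpca_variant = variant,
    traits = trait_names,
    regime_count = main$surface$k_prime,
    regimes_before_collapse = main$surface$k,
    convergent_regimes = length(main$surface$convergent),
    half_lives = as.list(hl),
    delta_aicc_bm = cmp$delta_aicc[cmp$model == "BM"],
    delta_aicc_ou1 = cmp$delta_aicc[cmp$model == "OU1"],
    K_shape = k_shape$K, K_shape_p = k_shape$p_value,
    K_size = if (is.null(k_size)) NULL else k_size$K,
    K_all = k_all$K,
    dpgls_r2 = dp$r2, dpgls_p = dp$p_value,
    regime_count_per_tree = lapply(per_tree, function(z) z$surface$k_prime)
  )

  report <- structure(list(aligned = aligned, space = space,
                           traits = traits_tbl, kmult = k_shape,
                           kmult_size = k_size, kmult_all = k_all,
                           dpgls = dp, trees = trees, per_tree = per_tree,
                           summary = summary),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$space$specimen_scores,
                   file.path(out_dir, "specimen_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$traits, file.path(out_dir, "species_traits.csv"),
                   row.names = FALSE)
  for (nm in names(report$per_tree)) {
    z <- report$per_tree[[nm]]
    utils::write.csv(z$comparison,
                     file.path(out_dir, paste0("model_comparison_", nm, ".csv")),
                     row.names = FALSE)
    write_regime_newick(report$trees[[nm]], z$surface$painting,
                        file.path(out_dir, paste0("regimes_", nm, ".nwk")))
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Pipeline report:", s$n_species, "species (",
      s$n_fossil_species, "fossil )\n")
  cat(sprintf("regimes: %d (from %d before collapse; %d convergent)\n",
              s$regime_count, s$regimes_before_collapse,
              s$convergent_regimes))
  cat(sprintf("dAICc: BM %.2f, OU1 %.2f\n", s$delta_aicc_bm, s$delta_aicc_ou1))
  cat(sprintf("K(shape PCs) = %.3f, K(all traits) = %.3f, dpgls r2 = %.4f\n",
              s$K_shape, s$K_all, s$dpgls_r2))
  invisible(x)
}

# tip-set signature of each shift for cross-tree comparison
shift_signatures <- function(tree, painting) {
  ntip <- ape::Ntip(tree)
  sort(vapply(painting$shift_edges, function(e) {
    nd <- tree$edge[e, 2L]
    tips <- if (nd <= ntip) nd else phangorn::Descendants(tree, nd, "tips")[[1L]]
    paste(sort(tree$tip.label[tips]), collapse = "|")
  }, ""))
}

#' Repeat the stepwise analysis over alternative trees
#'
#' Runs the full stepwise search on each candidate phylogeny (all sharing
#' the same tip set) with identical trait data and summarises agreement of
#' the inferred shift placements, identified by the tip sets of the shifted
#' clades.
#'
#' @param traits Species x traits data (see [as_trait_matrix()]).
#' @param trees A named list of `phylo` objects over the same tip set.
#' @param ... Passed to [surface_fit()].
#' @return A tibble with one row per tree: `tree`, `k`, `k_prime`,
#'   `n_convergent`, `shifts` (list of clade signatures), and `agrees`
#'   (identical shift placements to the first tree). The per-tree
#'   `surface_result`s are attached as attribute `"surface"`.
#' @export
sensitivity_over_trees <- function(traits, trees, ...) {
  stopifnot(length(trees) >= 2L)
  if (is.null(names(trees)) || any(names(trees) == "")) {
    names(trees) <- paste0("tree", seq_along(trees))
  }
  tips <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tips, identical, TRUE, tips[[1L]]))) {
    stop("trees do not share a common tip set", call. = FALSE)
  }
  fits <- lapply(trees, function(tr) surface_fit(tr, traits, ...))
  sigs <- lapply(names(trees), function(nm) {
    shift_signatures(trees[[nm]], fits[[nm]]$painting)
  })
  out <- tibble::tibble(
    tree = names(trees),
    k = unname(vapply(fits, `[[`, 0L, "k")),
    k_prime = unname(vapply(fits, `[[`, 0L, "k_prime")),
    n_convergent = unname(vapply(fits, function(z) length(z$convergent), 0L)),
    shifts = sigs,
    agrees = vapply(sigs, identical, TRUE, sigs[[1L]])
  )
  attr(out, "surface") <- fits
  out
}
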