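# Shared simulation scenarios. The study conditions (tree size, adaptation
# rate, optimum separation in stationary-SD units) are the package's
# documented defaults for recovery experiments.

# Three regimes on a 128-tip chronogram: two disjoint clades near a quarter
# of the tips each, optima 5 stationary SDs from the ancestral optimum
# along different trait axes, alpha = 3 / Ma, sigma2 = 1.
three_regime_scenario <- function(seed, n_tips = 128) {
  tree <- simulate_tree(n_tips, 0, seed = seed)
  true_edges <- pick_shift_edges(tree, 2, 0.25)
  painting <- regime_painting(tree, true_edges)
  sd_stat <- sqrt(1 / (2 * 3))
  theta <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)) * sd_stat
  traits <- simulate_mvou(tree, painting, alpha = 3, sigma2 = 1,
                          theta = theta, seed = seed + 10000)
  list(tree = tree, painting = painting, traits = traits,
       true_edges = true_edges)
}

# Convergent pair: two small, shallow, non-sister clades (about 8% of the
# tips each) shifting to the same optimum 5 stationary SDs away.
convergent_scenario <- function(seed, n_tips = 64) {
  tree <- simulate_tree(n_tips, 0, seed = seed)
  cand <- pick_shift_edges(tree, 4, 0.08, non_sister = TRUE)
  true_edges <- cand[1:2]
  painting <- regime_painting(tree, true_edges)
  sd_stat <- sqrt(1 / (2 * 3))
  theta <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 0, 0)) * sd_stat
  traits <- simulate_mvou(tree, painting, alpha = 3, sigma2 = 1,
                          theta = theta, seed = seed + 20000)
  list(tree = tree, painting = painting, traits = traits,
       true_edges = true_edges)
}

# A small landmark scenario for the pipeline: extant + fossil tips, two
# shifted clades, modest landmark noise.
landmark_scenario <- function(seed, n_tips = 16, k = 10) {
  tree <- simulate_tree(n_tips, fossil_fraction = 0.125, seed = seed)
  true_edges <- pick_shift_edges(tree, 2, 0.25)
  painting <- regime_painting(tree, true_edges)
  theta <- rbind(c(0, 0), c(0.08, 0), c(0, 0.08))
  sim <- simulate_landmarks(tree, painting, alpha = 3, sigma2 = 2e-4,
                            theta = theta, k = k, n_specimens = 3,
                            noise_sd = 0.004, size_sigma2 = 0.01,
                            seed = seed + 30000)
  # mark fossil species
  ages <- node_ages(tree)[seq_len(n_tips)]
  fossil <- names(ages)[ages > 1e-6]
  sim$landmarks$specimens$is_fossil <-
    sim$landmarks$specimens$species %in% fossil
  c(sim, list(tree = tree, painting = painting, true_edges = true_edges,
              fossil_species = fossil))
}
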