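# peakshift

Adaptive-peak inference for geometric morphometric data on
time-calibrated phylogenies.

## The problem

Comparative morphologists routinely ask how the shape of a structure —
the proximal femur across living and fossil anthropoid primates, say —
evolved: did lineages drift, or were they pulled towards clade-specific
adaptive optima, and did distant clades converge on the same optimum?
Answering that requires a chain of methods that usually live in separate
packages: Procrustes superimposition of 3D landmarks, ordination that
respects species structure, phylogenetic signal and allometry tests that
tolerate fossil (non-contemporaneous) tips, and multi-regime
Ornstein–Uhlenbeck model selection. `peakshift` implements the whole
chain, plus the tree-side plumbing (fossil-tip grafting by stratigraphic
age, MRP supertrees) and simulators with known ground truth for every
stage.

## The models at the core

Brownian motion, dX(t) = σ dB(t), is the neutral baseline. The
Hansen (OU) model adds stabilizing selection towards an optimum θ with
pull α (1/Ma):

> dX(t) = α[θ − X(t)] dt + σ dB(t)

with α = 0 recovering Brownian motion, and the *phylogenetic half-life*
t½ = ln(2)/α measuring how fast lineages adapt after a regime shift. In
the multi-regime version the phylogeny is painted with regimes; the
expected tip values are regime-weighted combinations of the optima and
the tip covariance is (σ²/2α)·e^(−α·d_ij)·(1 − e^(−2α·t_a)). A stepwise
AICc search adds shifts where they most improve fit across all traits,
then collapses regimes that converge on shared optima. Model support is
summarised against Brownian motion and single-optimum OU.

## Worked example

Simulate a 40-species radiation (4 fossil tips) in which two clades shift
to their own shape optima, then run the full pipeline — alignment, bgPCA,
signal and allometry tests, stepwise peak detection, model comparison:

```r
library(peakshift)

tree <- simulate_tree(40, fossil_fraction = 0.1, seed = 42)
shifts <- pick_shift_edges(tree, 2, target_frac = 0.2)
painting <- regime_painting(tree, shifts)
theta <- rbind(c(0, 0), c(0.06, 0), c(0, 0.06))   # optima on two shape axes
sim <- simulate_landmarks(tree, painting, alpha = 3, sigma2 = 2e-4,
                          theta = theta, k = 14, n_specimens = 3,
                          noise_sd = 0.004, size_sigma2 = 0.01, seed = 43)
ages <- node_ages(tree)[1:40]
sim$landmarks$specimens$is_fossil <-
  sim$landmarks$specimens$species %in% names(ages)[ages > 1e-6]

report <- run_pipeline(list(landmarks = sim$landmarks, tree = tree,
                            traits = c("PC1", "PC2", "ln_cs"),
                            n_perm = 999, seed = 1))
report
#> Pipeline report: 40 species ( 4 fossil )
#> regimes: 3 (from 3 before collapse; 0 convergent)
#> dAICc: BM 92.47, OU1 91.79
#> K(shape PCs) = 0.921, K(all traits) = 0.674, dpgls r2 = 0.0063
```

The search recovered the three simulated regimes; the multi-regime model
beats Brownian motion and single-optimum OU by ~92 AICc units; shape PCs
carry Brownian-like phylogenetic signal (K = 0.92, expectation 1 under
Brownian motion); and shape is not predicted by size (r² = 0.006). The
per-trait adaptation rates convert to half-lives:

```r
tidy(report$per_tree$tree$surface$fit)
#> # A tibble: 3 × 5
#>   trait  alpha   sigma2 log_lik half_life
#>   <chr>  <dbl>    <dbl>   <dbl>     <dbl>
#> 1 PC1   2.23   0.000139  152.       0.311
#> 2 PC2   1.23   0.000104  147.       0.562
#> 3 ln_cs 0.0265 0.0130     -3.95    26.2
```

Shape axes adapt fast (half-lives well under 1 Ma, as simulated with
α = 3); size, simulated as Brownian, is fitted with a tiny α — an
effectively infinite half-life. `compare_models()` tabulates the AICc
of BM, OU1 and the stepwise model; `autoplot()` draws the morphospace
(`bgpca` result) and the AICc trajectory (`surface` result), and
`write_regime_newick()` exports the painted tree.

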