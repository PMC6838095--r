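---
title: "Adaptive-peak inference for shape data on time-calibrated phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-peak inference for shape data on time-calibrated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakshift)
```

## The analysis chain

`peakshift` implements an inference chain that starts from raw 3D landmark
coordinates of museum specimens (extant and fossil) and a time-calibrated
phylogeny, and ends with a reconstruction of the adaptive regimes under
which a structure — think of the primate proximal femur — evolved:

1. **Generalized Procrustes analysis (GPA).** Every configuration of k
   landmarks is centred, scaled to unit centroid size
   (CS = sqrt of the summed squared distances of landmarks from their
   centroid, in mm), and rotated onto an iteratively refined consensus;
   the aligned shapes are then orthogonally projected onto the tangent
   plane at the consensus so that ordinary linear multivariate statistics
   apply. CS is retained and its natural log (lnCS) re-enters the analysis
   as a size trait.
2. **Between-group PCA (bgPCA).** An eigenanalysis of the covariance
   matrix of *group-mean* shapes (species means, optionally including
   fossil individuals), with every individual specimen projected onto the
   resulting axes afterwards. With g groups there are at most g − 1
   non-null axes; the leading axes summarise among-species shape
   variation while intraspecific scatter stays in the projections.
3. **Phylogenetic signal and allometry.** A high-dimensional
   generalization of Blomberg's K (expectation 1 under Brownian motion)
   with a tip-permutation test, and a phylogenetic multivariate
   regression of shape on size (D-PGLS) whose p-value comes from
   permuting the predictor across tips.
4. **Multi-regime Ornstein–Uhlenbeck modelling.** A stepwise search
   locates adaptive-peak shifts on the tree, then tests whether separate
   shifts converge on shared optima; the final model is compared with
   Brownian motion and a single-optimum OU model by AICc.

## Evolutionary models

Brownian motion: dX(t) = σ dB(t), with rate parameter σ². The
Ornstein–Uhlenbeck (Hansen) model adds stabilizing selection towards an
optimum θ with pull α (units 1/Ma):

dX(t) = α[θ − X(t)] dt + σ dB(t),

reducing to Brownian motion at α = 0. The *phylogenetic half-life*
t½ = ln(2)/α is the expected time to evolve half-way to a new optimum
after a regime shift and is the package's preferred summary of the rate
of adaptation.

In the multi-regime version, the phylogeny is *painted*: the root regime
flows tipward and changes wherever a shift edge begins. Given a painting,
the expected value at tip i is a convex combination of the regime optima,

E[X_i] = Σ_r W[i, r] θ_r,

where W integrates exponential decay e^(−α·(elapsed time)) along the
painted segments of the root-to-tip path (`ou_weight_matrix()`), and the
tip covariance is

V[i, j] = (σ²/2α) · e^(−α·d_ij) · (1 − e^(−2α·t_a)),

with t_a the shared time of tips i and j and d_ij their patristic
distance (`ou_covariance()`). Fossil tips simply have shorter root-to-tip
depths; both W and V use the actual depths, so no contemporaneity is
assumed anywhere.

Following the stepwise-search convention, α and σ² are shared across
regimes (per trait) and only θ varies; traits are modelled independently
under the shared painting, and their log-likelihoods are summed.
The optional cross-trait D-PGLS report (`dpgls_shape_size()` between PC
scores) lets users check the independence assumption on their own data.

**Root state.** The root is assigned the root regime's optimum
(`x0_policy = "root-theta"`), the convention of the reference stepwise
method; `"estimate"` instead adds one free ancestral state per trait.
The policy materially affects W at small α, which is why it is exposed.

## Fitting and the stepwise search

Given α, the optima are generalized-least-squares estimates and σ² has a
closed-form maximum-likelihood value, so each trait's α is found by
profile likelihood. The search grid spans α ∈ [1e−4, 100] per Ma
(18 log-spaced points — half-lives from roughly 7000 Ma, effectively
Brownian, down to 0.007 Ma), and the accepted model is refined by
continuous optimization on the log scale, bounded to [1e−8, 1e3]. Grid
values are used for *ranking* candidate shifts (the Cholesky factor of
the unit-rate covariance and the transformed per-edge weight columns are
cached per grid point, so thousands of candidate paintings are evaluated
incrementally); the continuous refinement only polishes the reported
estimates, so search decisions stay deterministic and cheap.

The forward phase starts from a single-optimum OU model and greedily adds
the shift (on any branch, shifts placed at the branch origin) that most
lowers the AICc summed across traits, stopping when no candidate lowers
it. Ties break to the lowest AICc and then to the earliest branch in edge
order. The backward phase greedily merges pairs of regimes while the AICc
keeps improving; a regime reached from more than one origin after merging
is *convergent*.

### AICc accounting

AICc = −2 logL + 2p + 2p(p + 1)/(n − p − 1). Per trait the parameter
count is 2 + K (α, σ², K optima); n counts tips × traits by default
(`n_convention = "tips"` counts species alone — the literature is not
consistent, so it is a flag).

Each shift's *location* is additionally charged `shift_cost` parameters,
and this is the one place the package deliberately departs from the naive
count. A greedy step selects the best of E candidate branches (E ≈ 2 ×
tips), and the expected maximum of that many correlated likelihood gains
is far above the 2(m + 1) penalty of a single added shift: in null
calibrations (single-regime OU data, 128 tips, 3 traits) the naive count
accepted 7–10 spurious shifts per run. Charging log(E) parameters per
shift — the risk-inflation price of selecting one location among E
candidates, in the spirit of Foster & George's criterion and of the
modified information criteria used by penalized shift-detection methods —
restores calibration: under the same null the search now accepts zero
spurious shifts in the large majority of runs, while shifts separated by
≥5 stationary SDs are still found essentially always. `shift_cost = 1`
recovers the naive count for users who want strict comparability with the
reference stepwise software.

### Numerical safeguards

* Residual sums of squares are floored at the smallest positive double so
  exact fits on tiny trees yield finite log-likelihoods.
* A regime whose weight column is numerically zero (e.g. painted only on
  a zero-length branch) is flagged and its optimum reported as `NA`.
* `ou_covariance()` switches to the exact Brownian limit σ²C below
  α = 1e−12 and uses `expm1` to keep 1 − e^(−2αt) accurate at small α.
* All GLS solves go through Cholesky factors; a singular phylogenetic
  covariance raises an error suggesting branch-length jitter.

## Morphometric conventions

* **Reflections are excluded** from Procrustes rotations (the SVD sign is
  corrected so det(R) = +1): left and right structures must not be
  superimposed by mirroring.
* **Tangent projection** is the orthogonal projection onto the plane
  normal to the consensus (not the stereographic alternative).
* GPA converges when the consensus moves by less than `tol = 1e-8`
  (at most 100 iterations, then an error reporting the last change), and
  the final alignment is rotated to the principal axes of the consensus
  with a deterministic sign rule, so the output does not depend on the
  original orientation of any input specimen.
* The covariance of group means divides by g − 1; this scales the
  eigenvalues but not the directions.
* Each eigenvector's sign is fixed by making its largest-magnitude
  loading positive, so axis orientation is reproducible across runs and
  machines.
* Species means are arithmetic means of aligned coordinates; species
  lnCS is the mean of specimen lnCS values.
* Fossils can either join the eigenanalysis (`bgpca_fossils = "eigen"`)
  or be projected a posteriori (`"project"`); whether fossils should be
  aligned inside the common GPA or OPA-fitted to the consensus afterwards
  is genuinely ambiguous in practice, so both paths exist (`gpa()` on the
  full sample vs `opa_align()` + `project_shapes()`).

## Trees, fossil grafting and supertrees

Time trees are `ape::phylo` objects with branch lengths in Ma; node ages
are derived as root height minus path length (ultrametricity checks use a
1e−6 Ma tolerance because fossil tips make exact zero-age checks wrong).
`graft_fossil()` implements the rule that the attachment node sits 1 Ma
older than the adjacent crown node when the fossil is younger than that
node, and 1 Ma older than the fossil's own age otherwise; the attachment
clade is always explicit, because "adjacent" is ambiguous when a fossil's
assignment spans nested nodes. Stratigraphic ranges collapse to tip ages
via `midpoint_age()`.

MRP supertrees use the standard Baum/Ragan encoding with equal column
weights and soft polytomies; `parsimony_score()` is a bottom-up Fitch
count with missing entries as full ambiguity. The search roots on an
all-zero hypothetical outgroup, enumerating all topologies exhaustively
for up to 8 taxa (2,027,025 rooted topologies at 9 taxa is past what a
single-CPU exhaustive scan should spend) and switching to a seeded
parsimony ratchet above that (`seed = 42` by default, exposed).

## What the synthetic generator emulates — and what it does not

`simulate_tree()` draws pure-birth chronograms scaled to a 40 Ma root
(an anthropoid-scale radiation) and truncates a chosen fraction of
terminal branches so those tips end at positive ages, like fossils.
`simulate_mvou()` uses *exact* OU transition sampling per branch (no
Euler discretization, hence no discretization bias in recovery tests);
`simulate_landmarks()` builds species mean shapes as a fixed template
plus orthonormal shape-basis deflections whose coefficients evolve under
the painted OU process, adds isotropic Gaussian landmark noise per
specimen, and scales configurations by a Brownian log-size factor so
lnCS carries evolutionary signal. The default scenario mirrors a
anthropoid-scale design: ~40 extant plus 13 fossil species, 14
landmarks, 3 shape axes plus lnCS, 3 specimens per species.

The generator deliberately omits: correlated (non-isotropic) landmark
noise, allometric covariation between size and shape, measurement error
on fossil tips, missing landmarks, and within-species phylogenetic
structure. Passing recovery tests therefore show that the chain is
correct *under its own model assumptions*; they do not certify behaviour
under the violations listed above, which real data will contain.

Ground-truth shift placements for recovery experiments
(`pick_shift_edges()`) avoid root-adjacent branches — at moderate-to-high
α a shift on one root child is likelihood-equivalent to a shift on its
complement — and can be forced non-sister so that a convergent pair is
distinguishable from a single deeper shift.

## Validation conditions

The test suite validates the chain at these problem sizes (chosen as
realistic study conditions for this kind of comparative data set):

* **Shift recovery:** 128-tip trees, 3 traits, α = 3/Ma, optima separated
  by 5 stationary SDs, 100 seeds — median recovered regime count 3 and
  both true branches (or immediate neighbours) found in ≥90% of seeds.
* **Convergence:** 64-tip trees, two small (~8% of tips) non-sister
  clades shifting to a shared optimum, 100 seeds — the pair collapses
  (k′ = k − 1) in the majority of seeds. Small, shallow convergent clades
  are the favourable case; a convergent pair of *deep* clades at the same
  optimum can defeat the greedy forward phase, because after one clade is
  modelled the other is partially absorbed by a lowered α (a known
  myopia of greedy stepwise shift selection).
* **Signal calibration:** mean multivariate K over 200 Brownian
  simulations on a 50-tip tree lies in [0.9, 1.1].
* **Allometry test level:** the D-PGLS permutation test holds the 5%
  level within its binomial confidence band over 500 null replicates.
* **Likelihood identities:** the painted-OU likelihood matches an
  independent recursively-derived Gaussian density to 1e−8 on small
  trees, and collapses onto the Brownian likelihood within 1e−4 at
  α = 1e−8.

## Known limitations

* Traits enter the multi-regime model independently (no multivariate
  trait covariance); correlated axes can misdirect shift placement, which
  is why the cross-trait regression report exists.
* Under fast adaptation the phylogenetic signal statistic is expected to
  fall below 1 — K near 1 is evidence *for* Brownian-like evolution, not
  a correctness check of the data.
* The stepwise search is greedy and deterministic; it returns one good
  painting, not a posterior over paintings.
* Shift-location penalties are a model-selection convention, not a
  significance test; regime counts should be read comparatively (against
  BM and OU1 via `compare_models()`), not as hypothesis tests.
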