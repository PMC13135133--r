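---
title: "Methods: multi-scale spatial association inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale spatial association inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinnet)
```

This vignette documents the statistical model behind `pinnet`, the design
decisions that were genuinely open, and what the package's tests do and do
not establish.

## The three nested scales

Point-intercept data distinguish three statements about a species pair,
from weakest to strongest:

* **co-occurrence** — both species are present somewhere in the same plot;
  this only says they tolerate the same environment;
* **local spatial association** — within one plot, the pair shares more
  (aggregation) or fewer (segregation) pinpoints than random placement
  predicts;
* **regional association** — pooling the local evidence over every plot
  where the pair co-occurs rejects the global null that the pair is
  spatially independent in *all* of them.

`pinnet` computes each level explicitly: `cooccurring_pairs()`,
`pair_plot_tests()`, and `screen_associations()`.

## Local null model

Conditional on the margins (the `n_is` pinpoints occupied by species *i*,
`n_js` by *j*, out of `N_s` per plot — 300 in the classical field design),
random placement makes the co-location count hypergeometric:

$$n_{ijs} \sim \mathrm{HG}(N_s,\, n_{is},\, n_{js}).$$

`hypergeom_pvalues()` returns both exact one-tailed Fisher p-values,
$p_s^+ = P(X \ge n_{ijs})$ and $p_s^- = P(X \le n_{ijs})$. Assumptions
worth stating:

* **Exchangeable pinpoints.** The two parallel transect lines are
  flattened into one index space; geometry within the plot is not used.
  Fine-scale environmental heterogeneity inside a plot therefore shows up
  as "association".
* **Binary presence.** Multiple contacts of one species at one pinpoint
  collapse to presence; the model counts occupied points, not cover.
* **No mid-p correction.** The combination step requires *valid*
  (superuniform) p-values; mid-p variants trade validity for power and are
  deliberately not offered.

Because the tests are discrete, each margin pair defines a finite set of
attainable p-values with known null masses (`pvalue_support()`). Two
consequences drive the rest of the pipeline: the *minimum achievable
p-value* (`min_achievable_pvalues()`) bounds what any data could show —
rare pairs cannot demonstrate segregation, saturating pairs cannot
demonstrate aggregation — and the support's staircase CDF is what any
honest combination or FDR procedure must integrate against.

## Combining evidence across plots

Per pair and tail we use Fisher's statistic $T = \sum_s -\ln p_s$ over the
plots where the pair co-occurs, referred to the exact stratified discrete
null (independent plots, each with its own attainable-value distribution).
Three evaluation routes are provided:

* `combine_exact()` — full discrete convolution of the per-stratum
  distributions of $-\ln p$, merging atoms that agree within relative
  1e-9 and capping the grid at 10^6 atoms (a capacity error beyond that
  points at the gamma variants). This is the authoritative reference for
  small numbers of plots or compact supports.
* `combine_gamma(..., variant = "gamma2")` — a gamma matched to the exact
  mean and variance of $T$.
* `variant = "gamma3"` — a shifted gamma also matching the skewness.

Three refinements, all visible in `combine_gamma()`'s contract:

1. **Truncation.** Strata whose entire support is {1} (one species fills
   the plot, or the margins admit a single outcome) carry zero evidence;
   they are dropped before moment computation so they cannot distort the
   gamma shape. Removing such a stratum provably leaves every route's
   result unchanged.
2. **Hybrid evaluation of coarse strata.** A stratum with two or four
   attainable values has a staircase null that no smooth tail can track.
   Strata with at most `coarse_cap = 4` atoms (their joint grid capped at
   4096) are convolved exactly; the gamma approximates only the smoother
   remainder. With no coarse strata this is the plain moment-matched
   gamma; with only coarse strata it degrades gracefully to the exact
   answer.
3. **Discreteness correction and dominance floor.** The exact tail
   $P(T \ge T_{obs})$ contains the observed atom's full mass; a continuous
   tail captures roughly half of it, so half the observed joint atom mass
   is added back. Finally the result is floored at the same formula
   evaluated at the most extreme attainable data, which makes the
   *minimum combined p-value* (`min_combined_pvalues()`) a true lower
   bound for every observed dataset by construction.

The tests pin this design to the exact oracle: over random configurations
(up to 3 plots, up to 40 pinpoints) the gamma2 route stays within half an
order of magnitude of the exact p wherever the latter is in
[1e-5, 0.5], and both gamma variants remain near-calibrated
(empirical size within [α/2, 1.5α] at α = 0.05) on fully null surveys.
The exact route is validated against brute-force enumeration of the joint
outcome space to 1e-12.

Whether the evidence scale is $-\ln p$ or $-2\ln p$ is immaterial under
consistent moment matching; we use $-\ln p$ throughout.

## Screening and attribution

* **Detectability pre-filter** (`prefilter_pairs()`): per tail, each
  pair's minimum achievable *combined* p-value is BH-adjusted across
  pairs, and only pairs strictly below α are tested. Because the minimum
  is a lower bound under any data, an excluded pair could never have
  reached significance; the pre-filter only removes noise from the FDR
  correction. Retention uses a strict `<`; regional calls use the
  conventional `q ≤ α`.
* **Per-tail FDR.** Aggregation and segregation are corrected separately,
  each over the pairs retained for that tail. In surveys of this kind the
  two retained sets are very unequal — far more pairs are testable for
  aggregation than for segregation — so the aggregation tail carries a
  heavier correction burden, a structural asymmetry this choice makes
  explicit. Joint correction across tails is a legitimate alternative; it
  was not chosen because pooling would let the abundant tail set the
  threshold for the scarce one. Ties in BH are resolved by stable
  original order.
* **Signs.** A pair significant in both tails is labelled `both` —
  context-dependent association — and kept as a single flagged edge.
* **Contributing plots** (`contributing_plots()`): post hoc, for each
  significant pair and tail, a *discrete* BH step-up over the pair's
  per-plot p-values identifies which plots carry the signal. The critical
  constants exploit the attainable-value CDFs:
  $\tau_k = \max\{t \in \mathcal{A}: \sum_i F_i(t) \le k\alpha\}$.
  With uniform supports this reduces exactly to classical BH; with coarse
  supports it never rejects fewer plots. The non-adaptive form is used —
  adaptive variants estimate the null proportion and are out of scope.
  The per-plot counts of attributed associations (`local_association_counts()`)
  are the response of the abiotic model below.

## Network stage

The regional network takes significant pairs as edges with their signs as
attributes. Choices:

* **Connectance has two defensible denominators** — all co-occurring pairs,
  or co-occurring pairs among associated species only. Both conventions
  are in use and give very different numbers on sparse networks, so
  `build_network()` reports both.
* **Clustering** is global transitivity (3 × triangles / connected
  triples).
* **Nulls**: 999 (configurable) Erdős–Rényi G(n, m) graphs with the same
  nodes and edges; empirical upper-tail p-values use the
  (1 + exceedances)/(R + 1) convention, so 1/(R+1) is the attainable
  minimum. Degrees are referred to the *pooled* null degree distribution
  (all nodes of a G(n, m) graph are exchangeable) and hub calls are
  BH-corrected at 0.05 — the correction method is a package choice, kept
  consistent with the screening stage.
* **SBM**: an undirected binary (Bernoulli) stochastic block model fitted
  by mean-field variational EM on the unsigned skeleton, with one spectral
  initialisation (k-means on leading eigenvectors) plus random restarts;
  the number of blocks maximises the integrated completed likelihood
  $\mathrm{ICL}(K) = \log L(X, \hat z) - \tfrac12 \tfrac{K(K+1)}{2}
  \log\tfrac{n(n-1)}{2} - \tfrac{K-1}{2}\log n$.
  Blocks are relabelled by decreasing mean degree, and the
  core / subordinate / peripheral role names are attached **only when the
  selected K is 3** — forcing that taxonomy onto other partitions would
  be misleading. Within-block connectance of a block with fewer than two
  members is reported as undefined (`NA`, flagged), never 0/0.

## Trait and environment stage

* Trait PCA is the standardised-variable (correlation) PCA; constant
  traits are refused by name.
* Pairwise PERMANOVA between block centroids runs one
  permutational MANOVA per group pair (pseudo-F from among/within squared
  distances, label permutations, BH across pairs); single-member groups
  are skipped with a warning.
* **Functional rarity**: distinctiveness is the abundance-weighted mean
  trait distance to co-occurring species,
  $D_{is} = \sum_{j \ne i} d_{ij} a_{js} / \sum_{j \ne i} a_{js}$, on
  Euclidean distances of z-scored traits rescaled to [0, 1] by the
  observed maximum (required for cross-trait comparability; a single
  trait reduces to the scaled absolute difference). Scarcity uses the
  exponential form $S_{is} = \exp(-N_p \ln 2\, a_{is})$ — the species at
  the evenness abundance $1/N_p$ scores exactly 0.5 — rather than a
  literal "inverse of relative abundance", matching the established
  functional-rarity framework this metric comes from.
* **Association richness model**: quasi-Poisson GLMs of the per-plot count
  of attributed local associations; the baseline uses the plot's total
  contact count only, the full model adds abiotic covariates and stated
  interactions. Model comparison uses the adjusted deviance R²,
  $1 - (D_{res}/(n-p)) / (D_{null}/(n-1))$ — quasi-likelihoods have no
  unique R², and this form is 0 for the intercept model and penalises
  parameters. Stepwise selection maximises that criterion searching both
  directions from the full model (the direction was an open choice; both-
  direction search from the full model is the least order-dependent).
  Covariate pairs with |r| > 0.95 are refused with an error naming the
  pair. Hierarchical partitioning distributes the selected model's R² over
  predictors by exact all-subsets (Shapley) averaging, capped at 8
  predictors (2^8 refits); the shares sum to the full-model R² to
  numerical precision, which the tests assert at 1e-9.

## The synthetic generator

`generate_survey()` emulates the study conditions: a configurable number
of plots (default 20) with 300 pinpoints each and a species pool (default
80) whose per-plot occupancy counts are Poisson draws around log-normal
medians (default median 20 contacts, sdlog 0.5) modulated by Gaussian
niches (breadth 0.35) on a latent unit gradient. Planted interactions
place the first species uniformly, then draw the partner's pinpoints
sequentially without replacement with weight $\exp(\theta \cdot
[\text{point occupied by the partner}])$; θ = 0 is *exactly* the uniform
null (equal-weight sequential sampling without replacement is uniform),
which the tests verify by chi-square goodness of fit against the
hypergeometric. Environment tables are monotone noisy functions of the
same gradient; trait tables are log-normal group syndromes (the default
core group has high LDMC, small leaves, short stature against an
acquisitive background).

What the generator does **not** emulate: within-line spatial
autocorrelation, micro-topographic heterogeneity, vegetation dynamics,
dispersal, multi-year resurveys, or cover abundances. Passing tests
therefore demonstrate the statistical machinery under the stated null and
planted alternatives — not robustness to micro-environmental confounding,
which in real transects can masquerade as association.

## Problem sizes and numerical choices

The automated checks run, per invocation: 200 random configurations for
the exact-vs-enumeration and gamma-vs-exact oracles; ~10,400 null pairs
(five 65-species, 3-plot surveys at 60 pinpoints) for type-I calibration;
500 replicates of a 45-pair survey with a ~90/10 null/planted mixture for
FDR control; 50 replicates of the 20-plot, 300-pinpoint, θ = ±3 design
for power and sign accuracy; 20 seeds each for SBM recovery
(Π = [[0.75, 0.30], [0.30, 0.02]], 30+30 nodes) and Erdős–Rényi
parsimony; and 200 G(40, 80) calibration runs with 199-replicate null
ensembles. These sizes were chosen so the full suite completes in minutes
while keeping Monte-Carlo standard errors small relative to the asserted
bounds.

Numerical conventions: exact tail sums come from the stats library's
hypergeometric routines (log-space internally); convolution atoms merge at
relative 1e-9; attainable p-values tie at relative 1e-15; empirical
p-values use the +1 convention; every stochastic routine takes an explicit
seed and is bit-reproducible.

## Known limitations

* The combination assumes independence across plots; shared gradients or
  spatially correlated microhabitats violate this and are not modelled.
* The gamma routes are approximations; their guarantees are empirical
  (oracle-bounded), not analytic. The exact route is limited by grid
  capacity for pairs co-occurring in very many plots with rich supports.
* Signed structure is kept as edge attributes only; the SBM is binary, so
  blocks reflect connection patterns, not sign patterns.
* CSR strategy coordinates are accepted as optional input columns and
  compared across groups (Kruskal–Wallis), but the allocation algorithm
  that derives them from leaf traits is out of scope.
* Trait imputation, phylogenetic methods and cover-based abundance models
  are out of scope; the trait table is taken as given.
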