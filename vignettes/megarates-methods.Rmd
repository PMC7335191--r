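---
title: "Disparity and evolutionary-rate series through deep time: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disparity and evolutionary-rate series through deep time: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megarates)
```

## The problem

Megaevolutionary studies ask when, in deep time, clades acquired their
morphological variety and how fast their phenotypes were evolving when they
did. Two complementary series answer this on a time-calibrated phylogeny
with fossil and extant tips:

* **disparity through time** — how much of morphospace a fauna occupies in
  each stratigraphic interval, measured on discrete character data; and
* **relative evolutionary-rate series** — the per-branch relative clock
  rates of a Bayesian relaxed-clock analysis, pooled over the posterior
  sample and tracked across the same intervals.

`megarates` implements the full post-inference pipeline for both series:
matrix preparation, distances and ordination, time-binned bootstrap
disparity, rate extraction/pooling/binning, trendlines, and an
assumption-driven statistical comparison of bins. Bayesian tree inference
itself (total-evidence dating, MCMC, model comparison) is out of scope; the
package consumes its *outputs* — a character matrix, dated trees annotated
with relative rates — or simulates statistically equivalent stand-ins with
known ground truth.

## Matrix preparation

Phylogenetic character matrices need adaptation before they can support a
distance-based morphospace. The pipeline applies, in this order:

1. **Missing-data filter.** Characters missing in strictly more than 30%
   of taxa are removed (`filter_missing()`); large amounts of missing data
   (above roughly a quarter of cells) systematically shrink pairwise
   distances.
2. **Inapplicability filter.** Characters inapplicable for strictly more
   than 5% of taxa are removed; the remaining inapplicable cells are
   rescored as missing (`filter_inapplicable()`). A taxon with an
   inapplicable character does not occupy that character's space at all —
   conceptually different from missing data — so widely inapplicable
   characters cannot be ordinated honestly, while rare inapplicability is
   treated agnostically.
3. **Polymorphism conversion.** Polymorphic scorings become missing
   (`polymorphisms_to_missing()`).

Both thresholds are strict inequalities; the denominators are the taxon
counts of the matrix entering each stage. The report records the overall
missing fraction both immediately after stage 1 and at the end, because
rescoring and polymorphism conversion add missing cells.

One caveat follows from the fixed order: the pipeline is idempotent only
when the stage-2/3 conversions do not push a retained character back over
the 30% threshold. A second application can then legitimately remove more
characters. The package keeps the published order rather than iterating to
a fixed point.

## Distances and ordination

**MORD** (maximum observable rescaled distance): for taxa $i,j$ over the
characters $C_{ij}$ both are scored for,

$$ d_{ij} \;=\; \frac{\sum_{c \in C_{ij}} \delta_c(i,j)}
                     {\sum_{c \in C_{ij}} m_c}, $$

where for an unordered character $\delta_c = \mathbf 1[x_{ic} \neq x_{jc}]$
and $m_c = 1$, and for an ordered character $\delta_c = |x_{ic} - x_{jc}|$
with $m_c$ the observed state range of the whole column (a column property,
not a pair property). MORD is bounded in $[0,1]$. Pairs sharing no scored
characters have no defined distance; they are reported by name and
ordination refuses to proceed — imputation in that regime would be
invention, which is exactly what the 25% missing-data guidance protects
against.

**Cailliez correction and PCoA.** Raw MORD matrices are generally
non-Euclidean (negative eigenvalues under double-centring; the triangle
inequality can fail). The smallest additive constant $c^\*$ making the
configuration Euclidean is computed by Cailliez's closed-form 2n×2n
eigenproblem, with a bisection search over PSD-ness as fallback; the two
agree to $10^{-6}$ in the test suite. Principal coordinates are then the
eigenvectors of $-\tfrac12 J D^2 J$ scaled by root eigenvalues. Axes with
eigenvalues below $10^{-8}$ times the largest are dropped as numerical
noise. After correction the embedded pairwise distances reproduce the
corrected dissimilarities (asserted to $10^{-6}$), so downstream disparity
can use *all* axes rather than an arbitrary leading subset.

**Ancestral augmentation.** `ancestral_states()` adds one pseudo-taxon row
per internal node of a fixed dated tree, estimated per character by
marginal maximum likelihood under a symmetric Mk model (unordered
characters exchange uniformly; ordered characters step between
neighbouring states). The per-character rate is itself ML-estimated on the
fixed tree. Nodes whose best state has marginal probability below 0.80
(configurable) are scored missing, so weak reconstructions do not
masquerade as observations. The implementation is validated against
exhaustive enumeration over all internal-state assignments on small trees.
Marginal ML under Mk was chosen as the default because the clock analyses
this pipeline consumes model morphology with Mk; the `method` argument
leaves room for alternative reconstruction schemes.

## Disparity through time

Disparity is the **sum of variances** of ordination scores over all
retained axes, with the population denominator $n$ (configurable to
$n-1$). With denominator $n$ it equals the mean squared distance to the
group centroid and is invariant under orthogonal rotation of the axes —
both identities are asserted numerically.

Taxa and nodes are assigned to named stratigraphic bins `[older, younger)`
(older bound inclusive; the youngest bin also closes at its younger bound
so extant material is binnable). The default rule is **range
intersection** — a taxon joins every bin its stratigraphic range overlaps —
with a midpoint rule available for sensitivity analysis. Each bin's
disparity distribution comes from `n_boot = 100` bootstrap resamples (with
replacement, same size); empty bins are reported as absent, never
interpolated, and the seed is a required argument so replicate vectors are
bit-reproducible.

## Rate series

Branch-specific relative clock rates (multipliers of the base clock rate:
above 1 accelerated, below 1 decelerated) are read from annotated trees
(`read_annotated_trees()`, BEAST-style `[&rate=...]` metacomments or a
configurable key) and pooled over **unique bipartitions** across the
posterior sample (`extract_bipartition_rates()`): each branch maps to the
taxon set on its child side (splits stay rooted because ages are
root-dependent), terminal branches included. Pooling over bipartitions
rather than a single summary tree carries topological uncertainty into the
series; occurrence counts are conserved (one row per branch per tree) and
support is the fraction of trees containing the split.

`bin_branch_rates()` assigns each occurrence to bins by interval overlap
(default) or branch midpoint. Overlap is the conservative reading when no
assignment rule is stated; midpoint partitions the occurrences and matches
the regime-lookup convention of the simulator, which is why the recovery
experiments use it. Per-bin summaries include mean, median, SD and a modal
estimate from a Gaussian KDE over *log* rates (rates are approximately
lognormal; Silverman bandwidth, configurable).

The **base clock rate prior** is derived as median posterior tree height in
substitutions divided by median root age (`derive_clock_prior()`); the
log-scale mean is the natural log of that quotient and the broad prior SD
is the exponent of the base rate as conventionally reported at four
decimals.

**Trendlines** (`loess_trend()`) are local linear regressions with tricube
weights (exact `"direct"` loess, span 0.75 by default), fitted
independently within segments (era boundaries by default) so that smoothing
never crosses a mass-extinction horizon; the 95% envelope is a percentile
bootstrap over points. Segments with fewer than five points are skipped
with a warning rather than extrapolated — sparse intervals produce
uninformative envelopes. `rate_disparity_regression()` is the OLS of log
phenotypic on log molecular rates with the two-sided slope test used to
assess rate decoupling.

## Statistical comparison of bins

`pairwise_compare()` reproduces the published decision procedure per pair
of bins:

1. Shapiro-Wilk normality per group, Fligner-Killeen homogeneity of
   variances, Shapiro-Wilk on group-centred residuals (all at
   $\alpha = 0.05$). Skewness and kurtosis are recorded in place of visual
   inspection.
2. If assumptions fail, transformations are tried in the order square
   root, cube root, log, exponential; square root and log are skipped for
   data outside their domain, and the exponential is applied as
   $\exp(x/\max|x|)$ to avoid overflow. The first transformation passing
   the full battery wins.
3. Two-sample $t$ test on the (possibly transformed) values when
   assumptions hold; otherwise the Wilcoxon rank-sum test (exact for group
   sizes up to 50 and untied data, normal approximation with continuity
   correction beyond).
4. P-values are Holm-adjusted across all pairs by default (the adjustment
   the common pairwise-test routines default to; Bonferroni, BH and none
   are selectable and the report names the method). Effect direction is
   the sign of the raw-scale mean difference.

Shapiro-Wilk is defined for $3 \le n \le 5000$; larger groups (pooled
bipartition occurrences easily exceed this) are tested on a deterministic
evenly spaced subsample of 5000. Groups below $n = 3$ or with zero
variance are flagged untestable and compared nonparametrically. Family-wise
error under a simulated global null is verified to stay at or below
nominal 5% (within Monte-Carlo error) in the acceptance suite.

## The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known ground truth without any external download. It emulates the
*statistical structure* the analyses assume:

* `simulate_fbd_tree()` — forward birth-death from one lineage at
  `t_root = 300` Ma (speciation 0.05, extinction 0.034, fossil sampling
  0.01 per lineage per Myr by default, tuned to an empirical-scale tree of
  roughly 100-400 tips). Extinct lineages with at least one Poisson fossil
  sample become fossil tips at their youngest sample age; unsampled
  extinct lineages are pruned; extant tips are all retained. Sampled
  ancestors are not placed as degree-2 nodes: no downstream operation
  distinguishes them from fossil tips. Fossil tips receive a symmetric
  ±2.5 Myr synthetic stratigraphic range so that range-intersection
  binning is exercised. Optional conditioning: minimum root age, and
  `coverage_bins` — reject trees lacking `coverage_min` branch midpoints
  in any listed interval, the synthetic analogue of a sampling design that
  deliberately covers every stratigraphic interval of interest.
* `simulate_branch_rates()` — lognormal relative rates with log-SD
  `sigma_log` around epoch-specific regime means (log-mean shifted by
  $-\sigma^2/2$ so the arithmetic mean equals the regime mean); the regime
  is looked up at the branch midpoint, so a branch crossing a boundary
  takes its midpoint's regime (a documented simplification matching the
  midpoint binning rule). The default regimes place a 2.5× acceleration
  between 251.9 and 237 Ma against a background of 1.0 — a
  Permian-Triassic-style rate pulse.
* `simulate_characters()` — exact event-sampled (Gillespie) Mk evolution:
  2-5 states per character, a quarter ordered by default, departure rate
  `base_rate × rel_rate` per Myr (default base 0.00345 substitutions per
  character per Myr, the published posterior base-rate estimate), uniform
  root states. Because events are sampled explicitly, the ground truth
  includes realised change counts per branch and character. Conditioning
  on variable characters only (an Mkv-style ascertainment) is not applied
  by default; plain Mk keeps the generator analytically checkable.
* `degrade_matrix()` — independent per-cell conversion to missing (15%),
  inapplicable (2%) and polymorphic (2%) at the defaults, with masks
  recorded. These levels leave roughly 19% missing cells after the
  preparation filters, matching the empirical scale the thresholds were
  designed around.
* `make_pseudo_posterior()` — N copies of the true tree with internal node
  ages jittered by an exact inverse-CDF truncated normal (respecting
  parent-older-than-child and fixed tip ages; root first, then preorder),
  rates redrawn lognormally about their true values, and optional random
  NNI perturbations where node ages permit, for topology-uncertainty
  experiments.

Every simulation function takes an explicit seed and is bit-reproducible.

What the generator does **not** emulate: correlated characters,
among-character rate variation beyond the regime structure, non-uniform
root states, character-dependent missingness (missingness in real fossils
concentrates in poorly preserved taxa, not uniformly at random), sampled
ancestors as internal nodes, and any molecular sequence evolution (the
molecular rate series is exercised with an independent second rate
annotation). Passing tests therefore demonstrate correctness of the
*computations* under the assumed generating model, not robustness of the
biology to violations of it.

## Numerical and design choices

* Strict `>` in both preparation thresholds (verbatim reading of "more
  than").
* Ordered-character ranges use the whole observed column, so `m_c` is
  stable across pairs.
* Eigenvalue retention tolerance $10^{-8} \times \lambda_{\max}$;
  Cailliez closed form cross-checked against bisection at $10^{-6}$ and
  against `stats::cmdscale(add = TRUE)` in the tests.
* Bins are `[older, younger)` half-open with the youngest bin closed at 0
  so boundary ages are unambiguous.
* Bootstrap and simulation seeds are required arguments; no hidden RNG
  state.
* Ancestral-state confidence threshold 0.80; below it a node's character
  is missing.
* Wilcoxon exactness switches to the normal approximation above $n = 50$
  (and under ties).
* The clock-prior SD uses the base rate as reported at 4 decimals; the
  log-scale mean uses the exact quotient. Both conventions follow how such
  priors are assembled from printed estimates, and `digits = Inf` gives
  fully exact arithmetic.

### Problem sizes in the shipped tests

The suite runs everything at desk scale, chosen as the smallest sizes at
which each statistical property is sharply testable: MORD against a
brute-force oracle on 100 random matrices (4-12 taxa, 10-30 characters);
regime recovery on 50 replicate simulations of 60-250-tip trees with
100-tree pseudo-posteriors; decoupling calibration at the published
pairing size $n = 211$ over 500 replicates; family-wise error over 1000
null replicates; end-to-end determinism on two full pipeline runs.

## Known limitations

* The preparation pipeline's idempotence caveat described above.
* Raw MORD can violate the triangle inequality; only the
  Cailliez-corrected embedding is metric, which is why disparity is always
  computed on the corrected scores.
* Zero-length branches are tolerated in dated trees, but ancestral-state
  messages across them are degenerate (the transition matrix is the
  identity); reconstructions on such trees should be interpreted with
  care.
* `loess_trend()` requires at least five points per segment and refuses to
  extrapolate across skipped segments.
* The NNI perturbation in `make_pseudo_posterior()` only swaps subtrees
  where existing node ages remain valid, so very shallow nodes are rarely
  moved; it is a topology-uncertainty stress knob, not a tree-space
  sampler.

## A minimal worked pipeline

```{r example, eval = FALSE}
cfg <- sim_config(min_tips = 40, max_tips = 80)
tt  <- simulate_fbd_tree(cfg, seed = 1)
sim <- simulate_branch_rates(tt, cfg, seed = 2)
ch  <- simulate_characters(sim$tree, cfg, seed = 3)
dg  <- degrade_matrix(ch$matrix, cfg, seed = 4)

prep <- prep_pipeline(dg$matrix)
ms   <- build_morphospace(prep$matrix, tree = sim$tree)
dtt  <- disparity_through_time(ms, default_time_bins(), n_boot = 100,
                               seed = 5)
plot(dtt)

pp <- make_pseudo_posterior(sim, cfg, seed = 6)
rt <- extract_bipartition_rates(pp$sample)
bs <- bin_branch_rates(rt, default_time_bins())
pairwise_compare(Filter(function(v) length(v) >= 3, bs$values))
```
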