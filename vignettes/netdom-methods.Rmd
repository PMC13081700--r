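---
title: "Network enrichment testing with ordinal dominance curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network enrichment testing with ordinal dominance curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdom)
```

## The problem

Brain-wide association studies fit a mass-univariate model at every cortical
location and ask where an imaging measure (cortical thickness, task
activation, ...) relates to a phenotype such as a cognitive score. A common
follow-up question is *network enrichment*: are the associations inside a
predefined network stronger than those outside it? Two families of tests
exist. *Competitive* tests compare in-network against out-of-network
statistics; they reject when the two differ, even if the in-network
associations are exactly zero and only the out-of-network ones are (say)
negative. *Self-contained* tests compare in-network statistics against zero
and ignore the rest of the brain. Neither alone captures the claim usually
intended — that in-network associations are both nonzero and stronger than
the rest — and most existing tests also mishandle the spatial
autocorrelation (SA) of imaging data, which invalidates any
independence-across-locations assumption.

This package implements an intersection–union test (IUT) that rejects only
when **both** components reject, with all inference by permutation of the
phenotype across subjects, so the spatial structure of the image is
untouched under the null.

## The test

Let `T_v` be the association statistic at location `v` (by default the
t-statistic of the target predictor from an OLS fit with nuisance
covariates), `N` the network with `m` locations, and `N^c` its complement
with `n` locations. For a right-sided test the composite null is

> H0: (in-network statistics are not stochastically greater than
> out-of-network statistics) **or** (the mean in-network association is at
> most 0).

**Stochastic ordering via the ODC.** With `F` the out-of-network CDF and
`G` the in-network CDF, the ordinal dominance curve is
`ODC(t) = F(G^{-1}(t))`, and its integral over (0, 1] equals
`P(X <= Y)` — the probability that a random out-of-network statistic lies
at or below a random in-network one. The plug-in estimate uses the two
ECDFs: `G_m^{-1}` is the left-continuous generalized inverse, `F_n` the
right-continuous ECDF with ties counted as `<=`. The enrichment statistic
truncates the shifted curve below a quantile `gamma`:

    D_gamma = integral over (gamma, 1] of ( ODC(t) - t ) dt,

computed exactly as a piecewise-constant sum (a step straddling `gamma` is
split; no quadrature). `D_0` reduces to the pairwise dominance proportion
minus 1/2; positive values mean in-network statistics tend to dominate.
Truncation matters when only a subset of in-network locations is enriched
(network misalignment, heterogeneous effects): upweighting the upper
quantiles then preserves power.

**Adaptive truncation.** `gamma` sweeps a grid (default 0, 0.05, ..., 0.95,
the same grid for observed and permuted maps). Each `gamma` yields a
permutation p-value

    p_gamma = (1 + #{k : D_gamma^(k) >= D_gamma^obs}) / (K + 1),

and the test takes `q = min(p_gamma)`. A minimum of p-values is not itself
a p-value, so `q` is calibrated against its leave-one-out permutation null:
each permuted map is treated in turn as observed against the remaining
`K - 1` (denominator `K`, as a count among `K` candidates), giving
`q^(1..K)` and

    p_diff = (1 + #{k : q^(k) <= q_obs}) / (K + 1).

Because the same adaptive minimum is taken inside the null, adaptivity does
not inflate the type I error — a property the test suite checks by
simulation.

**Self-containment.** `p_zero` compares the observed in-network mean
statistic to its permutation distribution (reference value 0, appropriate
for t, correlation, and other centered statistics; a user-supplied nonzero
reference is deliberately not offered). The final p-value is
`p = max(p_diff, p_zero)`; every permutation p-value lies in
`[1/(K+1), 1]`.

**Null maps.** Permutation respects the regression structure via
Freedman–Lane: each location's measure is regressed on the reduced model
(intercept + nuisance), the residual rows are permuted — the *same*
ordering at every location, preserving SA — reduced fits are added back and
the full model refit. With no nuisance covariates this degenerates to
permuting residuals about the intercept. Simple and stratified target
permutation are also available; stratified permutation keeps subjects
within exchangeability blocks (e.g., families). One plan is generated per
analysis and reused for every network tested, so the across-network FDR
adjustment (Benjamini–Hochberg, the only multiplicity correction offered)
rests on a common null ensemble. Identity permutations and duplicate draws
are allowed (the bias is O(1/K)).

**Sides and statistics.** A left-sided test is executed as the right-sided
test on the negated map. This choice (rather than merely flipping the
counting inequalities while still truncating the upper quantiles) makes the
truncation parameter act on the strongest *negative* associations — the
tail that matters for a left-sided alternative — and gives exact
left/right symmetry under sign flip on tie-free data, which the suite
asserts. Unsigned statistics (F) capture association strength only, so
only right-sided tests are allowed for them.

**Degenerate locations.** Locations with no variation across subjects are
flagged invalid and dropped from observed and permuted maps alike, keeping
`m` and `n` constant across permutations. Residual sums of squares are
floored at a small multiple of each location's total variation, so a
saturated fit yields a huge but finite statistic and a numerator that is
pure roundoff yields a statistic near zero rather than noise-amplified
garbage. Statistics use residual degrees of freedom
`N - (1 + #nuisance + 1)`.

## Comparator tests

Four competing enrichment tests are included for benchmarking, behind the
same data structures:

* **Thresholded Fisher's exact** (`rigea_test`): dichotomize at 1.96
  (configurable), cross-tabulate significance by membership, upper-tail
  hypergeometric p-value summed in log space.
* **Mean difference against spin surrogates** (`spin_surrogates` +
  `surrogate_test`): the association map's spherical projection is rotated
  by uniform random angles, contralateral symmetry maintained by mirroring
  the y/z rotations, values reassigned by nearest rotated vertex (ties to
  the lowest index); rotated-in medial wall values are discarded.
* **Mean difference against variogram-matched surrogates**
  (`variogram_surrogates`): permute, smooth with each candidate Gaussian
  kernel width, regress the observed binned variogram (25 equal-count
  bins, pair subsampling configurable) on the smoothed-permutation
  variogram, keep the width with the smallest SSE, then scale by the
  square root of the slope and inject the intercept as white-noise
  variance. The transform is linear only; no rank-matching of the original
  values is applied.
* **Weighted Kolmogorov–Smirnov** (`weighted_ks_enrichment`): GSEA-style
  running sum over locations ranked by statistic, in-network steps
  `+|T_v| / sum_N |T_v|` (weight exponent 1), out-of-network steps `-1/n`,
  score = signed maximum deviation, p-value against phenotype-permutation
  surrogate scores. The exact weighting of published implementations
  varies; this is a documented approximation intended for qualitative
  comparison, not bit-compatibility.

## The synthetic-data generator

Real neurodevelopmental imaging data cannot ship with a package, so the
simulation harness replaces plasmode resampling of real residuals with
smoothed Gaussian fields on a synthetic geometry:

* **Geometry.** A 2D toroidal grid (default 50 x 50 = 2500 locations) or a
  two-hemisphere sphere with a medial-wall band. Networks are grown as
  contiguous patches of requested sizes from random seeds; the three-network
  default (400, 250, 150) mimics a large, a medium, and a small network.
* **Noise.** Per subject, white Gaussian noise convolved with a Gaussian
  kernel (FFT on the torus), rescaled so every location's marginal variance
  is exactly `sigma2`. The two SA levels mirror the two modalities of the
  motivating study: *low SA* is cortical-thickness-like
  (`sigma2 = 0.09`, intercept `beta0 = 3`, kernel sd 1 cell) and *high SA*
  task-activation-like (`sigma2 = 0.36`, `beta0 = 0`, kernel sd 3 cells).
  The kernel widths are package choices: one cell gives mild, quickly
  decaying SA; three cells give correlation lengths of several cells,
  qualitatively matching heavily smoothed activation maps.
* **Effects.** `Y_iv = beta0 + 0.05 x1 - 0.05 x2 + beta3_v x3 + noise`,
  with `x1 ~ Bernoulli(0.5)`, `x2, x3 ~ N(0, 1)`, and four `beta3`
  configurations: `null_directional` (0 in-network / -0.03 outside),
  `null_equal` (0.04 everywhere), `shifted` (0.06 / 0.04), and
  `gamma_variance` (in-network Gamma(shape 2, rate 40), out-of-network
  Gamma(shape 20, rate 400): equal means 0.05, tenfold variance ratio).
  The shape–rate parameterization is the one under which the two Gamma
  fields have equal means and the stated variance ordering. Gamma fields
  are redrawn independently per location and per replicate, matching the
  view that true associations vary across locations.
* **Analysis model.** The matched design regresses each location on
  intercept, `x1`, `x2`, `x3` with `x3` the target.

`run_rejection_study()` repeats simulate-test-record with per-replicate
seeds derived from one master seed, and returns the rejection proportion
with its binomial standard error.

### What passing simulations do and do not show

Because permutation tests are valid under exchangeability regardless of the
noise field, *level-control* results on these synthetic fields transfer to
real data: if the composite null holds and subjects are exchangeable, the
test is level-alpha whatever the SA structure. *Power* numbers do not
transfer. Two differences matter. First, the desk-scale geometry (2500
locations, networks of 150–400) carries far fewer effectively independent
in-network locations than a 19k–57k-vertex cortical surface with networks
of thousands of vertices, so the plug-in ODC is much noisier here and power
in the hardest regime (variance-only enrichment under high SA) is far below
what full-resolution data support; the package reports what its own
simulations produce rather than tuning the generator to reproduce external
numbers. Second, smoothed Gaussian fields are stationary and isotropic;
real cortical data are neither.

## Numerical and design choices

* Quantile conventions: `G_m^{-1}` left-continuous, `F_n` right-continuous
  with `<=` ties. Consequence (intended): identical in/out samples give
  `D_0 = 1/(2m)`, not 0.
* All permutation p-values use `(1 + count)/(K + 1)` with inclusive ties —
  conservative and never zero. The leave-one-out null uses denominator `K`,
  exactly as the counting argument dictates.
* Gamma ties break toward the smallest gamma, which is also the reported
  "selected gamma" summary.
* The leave-one-out null is computed by per-gamma ranking in O(K log K)
  per gamma; the test suite verifies it against the O(K^2) double loop.
* Errors, not guesses: empty networks, rank-deficient designs (offending
  columns named), left-sided F tests, permuted targets collinear with
  nuisance covariates, and sub-3-bin variograms are all refused.
* Default study sizes are desk-scale: V = 2500, K = 200, 120–1000
  replicates depending on context; the full-resolution analyses the method
  targets (V ~ 19k–57k, K = 1000) use the identical code path, which is a
  handful of matrix products per permutation.

## Known limitations

* The asymptotic Brownian-bridge null for the ODC statistic is not
  implemented; inference is purely permutation-based.
* Weight functions other than the step indicator are not offered.
* Spin surrogates require a spherical projection; the synthetic sphere is a
  Fibonacci lattice, not a registered cortical mesh.
* The variogram surrogate generator uses dense distance matrices and is
  intended for desk-scale maps (a few thousand locations).
* CIFTI and volumetric NIfTI inputs are out of scope; imaging travels as
  CSV or GIFTI.

## A worked example

```{r example}
geom <- make_geometry("grid", 30, c(120, 60), seed = 5)
setting <- simulation_setting(80, "low", beta3_config = "shifted",
                              network_id = 1, seed = 9)
ds <- simulate_dataset(setting, geom)
partition <- network_partition(geom$labels, network_id = 1)
plan <- permutation_plan(80, K = 199, "freedman_lane", seed = 10)
netdom_test(ds$imaging, ds$design, partition, plan)
```

The printed result reports the partition sizes, the observed in- and
out-of-network mean statistics, the selected truncation quantile with its
minimum p-value, and the two IUT components with their maximum — the final
enrichment p-value.
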