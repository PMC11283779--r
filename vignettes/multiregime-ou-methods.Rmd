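---
title: "Multi-regime Ornstein-Uhlenbeck models of limb evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-regime Ornstein-Uhlenbeck models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ouregimes)
```

## The scientific problem

`ouregimes` implements a phylogenetic comparative pipeline for asking
whether discrete selective regimes — here, mammalian locomotor modes
(ground-dwelling, arboreal, gliding, flying) — shape the evolution of
continuous morphological traits such as size-corrected limb measurements.
The motivating application is the glider-to-flyer hypothesis for the
origin of bat flight: if gliders occupy adaptive optima intermediate
between arborealists and bats, trait evolution provides a plausible
pathway across adaptive peaks.

The analysis has four stages, each exposed as package functions:

1. **Morphometrics** — specimen measurements (mm) are averaged per
   species and size-corrected to log-shape ratios
   `log10(trait / mass^(1/3))`; dimensionality is reduced by PCA on the
   covariance matrix (divisor *n*, the `princomp` convention).
2. **Regime mapping** — locomotor categories are painted onto a dated
   phylogeny under four schemes (`loc4` keeps all four; `loc3a` merges
   glider+flyer, `loc3b` arboreal+glider, `loc3c` ground+arboreal);
   uncertainty in ancestral regimes is propagated by sampling stochastic
   character maps from an equal-rates Mk model.
3. **Evolutionary models** — Brownian motion (BM), single-optimum
   Ornstein-Uhlenbeck (OU1) and multi-optimum OU (OUM) models are fitted
   by maximum likelihood, univariately per trait or multivariately on
   retained PC scores, and compared by small-sample corrected Akaike
   weights (AICc); responsiveness to selection is summarized by the
   phylogenetic half-life `ln(2)/alpha`.
4. **Uncertainty** — parametric bootstrap percentile intervals for the
   optima, and Monte-Carlo power analysis for distinguishing OU models
   from BM.

## The OU model and its likelihood

Conditional on a regime history (a piecewise-constant painting of the
tree), a trait follows
`dX = alpha (theta_{r(t)} - X) dt + sigma dW`.  Following the
shared-dynamics convention, a single `alpha` and `sigma^2` are shared
across regimes and only the optima `theta_r` differ.  The tip
expectations integrate the painted optima with exponential decay weights;
the tip covariance uses the fixed-root, non-ultrametric form

```
cov(i, j) = sigma^2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_ij))
```

with `t_ij` the shared path time from the root and `d_ij` the tip-to-tip
divergence time.  This form is valid for fossil (non-contemporaneous)
tips and reduces continuously to the BM covariance `sigma^2 t_ij` as
`alpha -> 0` (computed with `expm1` so the limit is numerically exact).
Polytomies need no special handling because the covariance is built from
shared path times.

**Root state.** For OU models the root value is fixed at the root
regime's optimum by default (`root = "theta"`), the convention of the
standard multivariate implementations; a freely estimated root
(`root = "free"`) is available because published information criteria may
reflect either choice.  The BM root is always a free parameter profiled
out by GLS.

**Estimation.** At fixed `alpha` the optima enter the mean linearly, so
`theta` is profiled by generalized least squares and, univariately,
`sigma^2` has a closed-form profile MLE.  The univariate search is
therefore one-dimensional in `log alpha`: a coarse grid over
`[1e-7, 50] / Myr` followed by golden-section refinement around the best
grid point, which is robust to the multimodality that plagues naive OU
optimization.  Multivariately, `alpha` is diagonal (one value per PC,
shared across regimes), `sigma^2` a full positive-definite matrix
parameterized by its Cholesky factor, and the search is L-BFGS-B over
`(log alpha, Cholesky)` with three starts (a start built from per-PC
univariate fits, plus perturbed copies).  Covariance solves use Cholesky
with a jitter ladder (`1e-12 ... 1e-8` of the mean diagonal) before
declaring singularity.

**Parameter counts.** Univariate: BM `k = 2`; OU1 `k = 3`; OUM
`k = 2 + m` for `m` regimes (the root adds nothing under
`root = "theta"`).  Multivariate with `d` dimensions: `d` alphas,
`d(d+1)/2` covariance parameters, `m d` optima (plus `d` roots for BM or
`root = "free"`).  AICc uses `n` = species univariately and
`n = species x d` multivariately; the choice is recorded in every fit
and is a known comparability caveat between univariate and multivariate
tables.

**Degenerate inputs.** Constant traits drive the profile `sigma^2` to a
floor of `1e-12`, reported as-is; `alpha` estimates at the search
boundary are flagged on the fit object.  Ties in model ranking are broken
toward fewer parameters.

## Stochastic character maps

The Mk model is equal-rates with a uniform root prior — the default of
the standard simmap implementation, exposed via `fit_mk_er()`.  The rate
is maximized by Felsenstein pruning over a log-rate grid plus
golden-section refinement; all-monomorphic tips return the boundary
`q = 0` with a warning.

`sample_simmap()` draws histories from the exact posterior given tips
and `q`: node states by backward-forward conditional sampling, branch
histories by endpoint-conditioned path sampling.  Paths are drawn by
rejection (forward simulation until the endpoint matches, capped at
10,000 tries per branch) with an exact uniformization bridge as the
fallback; for the equal-rates chain the uniformized jump chain never
self-transitions, so the bridge samples the exact number and placement of
changes.  The sampler is validated in the test suite against exhaustive
enumeration (root-state posterior on a 3-tip tree), against the analytic
expected jump counts of conditioned bridges, and against an independent
simmap implementation.

Merging regime labels on a sampled map (`merge_regime_map()`) commutes
with painting merged categories directly, which the pipeline exploits
when a single four-state history must be compared under nested painting
schemes.  Note that fitting a separate Mk model per scheme (the
pipeline's default) is statistically distinct from merging four-state
maps; both routes are available.

Model comparisons based on a *single* sampled map per painting are noisy:
a mis-reconstructed history can favor a coarser painting by many AICc
units.  Averaging weights over several maps per tree — as the motivating
study does with 10 maps x 250 trees — stabilizes the comparison, and the
pipeline exposes `maps_per_tree` for exactly this reason.

## Fossils

Fossil tips are grafted as a polytomy on the host clade's stem at a
configurable stem age (the motivating analysis used 69.8 Myr for the bat
stem).  Fossil tip ages are not printed in the source material; all four
fossils are Eocene, so the default tip age is 50 Myr and is configurable
per fossil — this is why the likelihood core accepts non-ultrametric
trees.  Fossil body masses are imputed from the extant flyer allometry
`log10(mass) ~ log10(geometric mean of all measurements)` (log-log least
squares — the standard allometric scale; the choice is recorded in the
output metadata) and then passed through the identical log-shape-ratio
path as extant species.  Optima whose magnitude exceeds 10x the observed
trait range are flagged as artifact-scale, mirroring the "unrealistic
magnitudes" phenomenon reported for extant+extinct multivariate fits.
Whether PCA variance fractions should be computed from extant rows only
or from extant+extinct rows is ambiguous in practice, so both are
supported: `pca_rows = "extant"` derives the loadings from extant species
and projects fossils into that space, `pca_rows = "all"` (the default)
uses every row.

## Uncertainty machinery

`bootstrap_optima()` implements the per-map parametric bootstrap: for
each sampled character map, data are simulated under the fitted model,
the same specification is refitted *on the generating map* (histories are
not re-sampled within a replicate), and pooled percentile intervals are
reported alongside per-map summaries; refit failure above 20% is an
error, not a silent drop.  Percentile (not BCa) intervals are used: they
match the common practice of the standard bootstrap routine and are cheap
under simulation.

`distinguishability()` simulates datasets under both fitted models,
refits both to every dataset, and reports the type-I error and power of
the likelihood-ratio statistic at the null 95th percentile.

## The synthetic-data generator

`synthetic_config()` / `make_dataset()` emulate the study conditions: 231
species on a 70-Myr birth-death tree (`birth = 0.1`, `death = 0.05` per
Myr — mild extinction with a realistic turnover ratio), a four-state
equal-rates regime history with `q = 0.01`/Myr (a few dozen transitions
across the tree, comparable to plausible locomotor-mode lability), traits
evolved by exact segment-wise OU transition sampling, log-normal body
masses (`meanlog = log(300)` g, `sdlog = 1.5`, spanning shrew-to-large
sizes), 1-2 specimens per species and multiplicative log-normal
measurement noise (default CV 5%).  Latent log-shape values are converted
to mm by inverting the size correction, so the full ingestion path is
exercised end to end; with one specimen and zero noise the pipeline
recovers the latent values exactly.

Three presets fix the trait process: `strong` (`alpha = 0.1`/Myr,
`sigma^2 = 0.01`, optima spaced 0.7 apart — at least three stationary
standard deviations `sqrt(sigma^2/(2 alpha)) = 0.22`, the separation
under which rank-order recovery is a fair expectation), `weak` (spacing
well inside one stationary SD) and `bm_null` (`alpha = 0`).  The painted
tip counts of the empirical data (117 ground / 71 arboreal / 16 glider /
27 flyer) inform the scale the generator mirrors, but tip frequencies of
a simulated Mk history are random; tests that need exact counts paint
tips directly.

What the generator does *not* emulate: the shape of the real mammal tree
(it is a homogeneous birth-death tree), empirical trait correlations
(synthetic traits are conditionally independent given the history), and
regime assignments correlated with clades beyond what the Mk process
produces.  Passing tests on synthetic data therefore validate the
machinery and its statistical calibration, not any empirical claim about
mammals.

## Precision of recovered optima

At the strong-signal conditions the optimum estimates are unbiased with
a sampling SD of about 0.06-0.07 at 231-400 tips — an irreducible
consequence of phylogenetic correlation (increasing the regime-switching
rate does not shrink it).  The test suite therefore asserts
unbiasedness, rank-order recovery (>= 95% of strong-signal replicates)
and +/- 3 SE coverage rather than an over-tight absolute error, and the
bootstrap coverage check uses the binomial 89-99% band appropriate to
100 replicate pipelines.

## Problem sizes used in the checks

The suite runs entirely on synthetic data: likelihood oracles on trees of
3-6 tips (exhaustive enumeration stays exact there), sampler calibration
at 3-60 tips with 4,000-20,000 draws, estimator calibration at 150-400
tips with 20-50 replicates, bootstrap coverage at the full study scale
(231 tips, 100 pipelines, 25 bootstrap replicates each), and multivariate
pipeline checks at 60-100 tips with 2-3 PCs.  These sizes were chosen so
each check has enough replication for its Monte-Carlo tolerance while the
whole suite stays convenient to run routinely.

## Known limitations

* Multivariate `alpha` is diagonal; full selection matrices (and with
  them evolutionary correlations in the pull, not just the diffusion)
  are out of scope, as are early-burst, trend and rate-shift models and
  measurement-error variance terms.
* The equal-rates Mk model is the only regime process; all-rates-different
  and hidden-rate variants are out of scope.
* Shift detection without a priori regime assignments (EM + lasso style)
  is deliberately not implemented.
* AICc sample sizes differ between univariate (`n` = species) and
  multivariate (`n` = species x d) tables; weights are comparable within
  a table, not across tables.
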