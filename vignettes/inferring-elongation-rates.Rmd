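---
title: "Inferring polymerase progression rates from time-course occupancy profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring polymerase progression rates from time-course occupancy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polrate)
```

## The model

Transcribing RNA polymerase II is modelled as a particle on a 1-D lattice —
the gene body — hopping forward at a position-dependent rate and subject to
the exclusion rule (a hop succeeds only if the target site is free). This is
the asymmetric simple exclusion process (ASEP) with open boundaries:
injection at the TSS side, exit at the TES side. Writing `phi_i` for the
expected occupancy of site `i`, factorizing neighbour correlations closes
the dynamics into the mean-field ODE system

```
d phi_i / dt = p_{i-1} phi_{i-1} (1 - phi_i) - p_i phi_i (1 - phi_{i+1})
             + q_{i+1} phi_{i+1} (1 - phi_i) - q_i phi_i (1 - phi_{i-1})
```

with boundary sites exchanging particles with reservoirs. Under Euler
scaling (`a -> 0`, `N -> infinity`, `L = N a` fixed) the density
`rho(x, t)` obeys the nonlinear advection–diffusion law

```
d rho / dt = - d/dx [ lambda(x) rho (1 - rho) - nu(x) d rho / dx ],
lambda = p~ (1 - b),   nu = (a / 2) p~ (1 + b),
```

where `p~(x)` is the forward hop-rate profile and `b` the backward-hop
fraction (`b = 0`, the totally asymmetric case, throughout: polymerase
backtracking is not resolvable at 20-nt binning). Local minima of `p~` are
pausing regions; a sufficiently deep minimum acts as a bottleneck that
splits the stationary profile into a high-density phase upstream and a
low-density phase downstream.

Two regimes matter for inference:

* **NESS.** With both boundaries held at fixed reservoir densities the
  system relaxes to a non-equilibrium stationary state `rho*(x)` carrying a
  constant flux. This is the pre-treatment state.
* **Depletion.** Triptolide blocks initiation; we model this by switching
  to zero-influx boundaries (no injection, free exit) and integrating from
  `rho*`. The gene body empties from the TSS side, and the transient
  profiles observed at a handful of run-on times carry the information
  about `p~(x)`.

## Discretization and solver

The solver discretizes the conservative form with the discrete product-form
flux `J_{i+1/2} = p_i rho_i (1 - rho_{i+1}) - q_{i+1} rho_{i+1} (1 - rho_i)`
(advection `lambda rho(1-rho)` plus central diffusion `nu` to second order in
the spacing). With spacing `a = 1` this *is* the lattice mean-field system,
so the continuum and lattice backends agree to solver tolerance by
construction, and the stochastic (Gillespie) simulator provides an
independent check of the factorization itself on small systems.

Time stepping is adaptive embedded Runge–Kutta (Cash–Karp 4(5)) with a
CFL-limited initial step (`dt <= 0.25 / max rate`). Defaults: `rtol = 1e-8`,
`atol = 1e-10` for standalone integration; the likelihood path uses
`rtol = 1e-5`, `atol = 1e-7`, which keeps each forward solve well below a
millisecond on a 100-site grid. At these settings the solver error is
orders of magnitude below the slice levels the sampler works with, and
chains run at the looser and tighter tolerances produce identical
accept/reject sequences on the reference study.
Occupancies within a clip tolerance of `[0, 1]` are clamped; the tolerance
scales with `atol` (an undershoot of the order of the local truncation
error near an empty site is round-off, not failure), and larger excursions
raise an integration error — inside the sampler these map to a `-Inf`
log-likelihood, i.e. a rejected state.

Fixed-density boundaries are implemented as reservoir coupling: influx
`p_1 rho_L (1 - phi_1)` and exit `q_1 phi_1 (1 - rho_L)` on the left (and
symmetrically on the right), which reproduces the exact constant-rate
solution `rho* = rho_L = rho_R`, `J* = lambda / 4` at density one half.
The NESS solver is long-horizon time stepping with stationarity detection —
the residual `max |d rho / dt|` must stay below `1e-10` at three
consecutive checkpoints — rather than a nonlinear root solve; this is
robust for bottlenecked profiles, and the tolerance is tight enough that
the reported stationary flux is constant in `x` to well below one part in
`1e6`.

## Prior, likelihood, posterior

The rate profile is positive, bounded and smooth by construction:
`p~ = p~max / (1 + exp(-f))` with a Gaussian-process latent field
`f ~ N(m, K)`, squared-exponential kernel
`k(x, x') = sigma_f^2 exp(-(x - x')^2 / (2 l^2))`. Kernel matrices receive
adaptive diagonal jitter starting at `1e-10 sigma_f^2` and doubling to at
most `1e-6 sigma_f^2` before a factorization is declared failed. The latent
field lives on the solver grid; at 20-nt binning a gene is at most a few
thousand points, so dense Cholesky factorizations are affordable and no
inducing-point approximation is used.

Observations are read-scale profiles `y_ij` at positions `x_i` and run-on
times `t_j`, related to the model density by `kappa y_ij = rho(x_i, t_j) +
eps`, `eps ~ N(0, sigma_eps)`, where `kappa` is the unknown inverse
amplification factor of the assay. The log-likelihood is the Gaussian
log-density of the residuals `kappa y_ij - rho(x_i, t_j)` — squared, and
normalized over all `n * t` observations; the quadratic form is what the
Gaussian error model implies, and constants do not affect the sampler. The
forward solve starts from `rho(x, 0) = kappa y*(x)`, the scaled unperturbed
profile, recomputed whenever `kappa` changes; it is clipped into `[0, 1]`
(the upper prior bound on `kappa` can push the product slightly above one).
Observed profiles are linearly interpolated onto solver positions and
clamped outside the observed range.

The five hierarchical parameters `theta = (m, sigma_eps, kappa, sigma_f, l)`
carry a scaled sigmoid Gaussian prior, `theta = theta_min +
(theta_max - theta_min) / (1 + exp(-xi))`, `xi ~ N(mu_xi, sigma_xi^2)`
componentwise. We read the scale hyperparameter as a standard deviation;
at the only setting used, `(mu_xi, sigma_xi) = (0, 1)`, the readings
coincide.

## Sampler

The joint posterior over `(f, theta)` is sampled by elliptical slice
sampling (ESS) within block Gibbs, in whitened coordinates:

1. latent block: `eta` with `f = m + chol(K(sigma_f, l)) eta`,
2. hyperparameter block: `zeta` with `xi = mu_xi + sigma_xi zeta`.

Whitening is what keeps ESS valid when the covariance hyperparameters move:
the prior of each block is standard normal by construction, and the
likelihood function of the second block rebuilds the Cholesky factor for
each proposal. One sweep performs the two block updates in that order;
`block_updates > 1` repeats each block's update within the sweep, which
buys better hyperparameter mixing at proportionally more forward solves.
A rolling failure guard aborts the chain if more than half of the forward
solves in a 500-sweep window fail. Defaults are `1e4` sweeps with `2e3`
burn-in.

Summaries are equal-tailed quantile intervals (the linear-interpolation
quantile convention, R's default): 99% bands for the per-position rate
profile, 95% for the hyperparameters, matching how such fits are usually
reported.

## The synthetic-data generator

`generate_study()` reproduces the simulation conditions end to end: a gene
body of `L = 100` lattice units; a GP draw with `(l, sigma_f, m, p~max) =
(7.32, 0.67, 0.29, 3)`; a NESS with both boundary densities at 0.5;
depletion profiles extracted at `t = (30, 60, 300)`; and observations
`y = (rho + eps) / kappa_true` with `y* = rho* / kappa_true`. Defaults are
`kappa_true = 1` (inside its prior bounds 0.8–1.2) and `noise_sigma = 0`:
the density profiles are extracted from the integrated dynamics without
added error, so the fitted `sigma_eps` converges to the small residual
floor set by the forward-solver tolerances rather than to a data noise
level. Noise can be switched on for calibration studies, and the package's
tests verify that posterior credible widths grow monotonically with it.

What the generator emulates: a smooth positive rate profile, a stationary
initial state, transient depletion, an unknown multiplicative scale, and
(optionally) additive Gaussian noise. What it does not emulate: read-count
(Poisson/negative-binomial) sampling noise, cross-cell heterogeneity,
poised polymerase upstream of the TSS, mappability artifacts, or
library-to-library normalization. Passing the synthetic recovery tests
therefore demonstrates correctness of the inferential machinery under the
model's own assumptions, not robustness to everything real ChIP-seq data
can do.

### A caution on the noise-free posterior

With `noise_sigma = 0` the observations are an exact forward-model output,
so the posterior concentrates on a near-degenerate ridge: `sigma_eps`
drifts towards the solver-noise floor while the latent field fine-tunes,
and the covariance hyperparameters `(sigma_f, l)` mix slowly along that
ridge. Finite chains can therefore report narrow credible intervals for
`sigma_f` and `l` that miss the generative values even when the rate
*profile* is recovered well — rate estimates in regions whose influence on
the depletion profiles is weak (near the TES, or minima too shallow to
perturb the density) remain wide, and near-tied global minima can swap.
This mirrors the known behaviour of this inference problem: covariance
hyperparameters of a latent GP behind a PDE solve are weakly identified,
and some miscalibration of `(l, sigma_f)` is expected even at full chain
length.

A related point concerns posterior-predictive overlays on noise-free
data: the fitted `sigma_eps` converges to the root-mean-square of the
very residuals being displayed, so the *largest* pointwise deviation over
a few hundred positions is necessarily around three times `sigma_eps`
even when the overlay is as good as the model's own noise estimate
allows. Judging overlays by a per-position `sigma_eps` bound therefore
always flags a few positions; the meaningful statement is that the
deviations behave like draws at the fitted noise scale.

## Problem sizes used by the tests

The test suite keeps everything desk-scale by choice: recovery checks run
ten seeded replicates at 2000 sweeps with 500 burn-in on the `L = 100`
study; the near-noiseless identifiability and noise-monotonicity checks use
1500-sweep chains; kernel factorizations are exercised up to 3000 grid
points. The acceptance script (`scripts/acceptance.R`) runs the full
`1e4 / 2e3` setting on a single seeded replicate.

## Metagene aggregation

Per-gene rate profiles of different lengths are combined by conserving the
native length scale near the ends and stretching the interior: the segments
`[TSS - flank, TSS + 1000]` and `[TES - 1000, TES + flank]` are averaged at
native nucleotide offsets, while the interior is resampled by linear
interpolation to a common number of points before averaging. Genes shorter
than twice the end window are excluded with a warning. The across-gene
dispersion reported alongside the mean is the interquartile range — a
robust spread, chosen because the mean alone hides how variable rates are
between genes near the TES.

## Genomic input conventions

Coordinates are 0-based, half-open everywhere internally (bedGraph's native
convention); minus-strand genes are reversed at read time so index 1 is
always the most upstream bin, and the annotation carries the TSS at the
strand-appropriate end. A bin's value is the coverage-weighted mean
per-base signal; overlapping bedGraph records sum. The multiplicative
scale of coverage values is irrelevant to inference — `kappa` absorbs it.
For real data the upper rate bound defaults to `6e3` nucleotides per
minute (a deliberately safe cap on reported elongation speeds, converted
to lattice units by dividing by the bin width), and the bounds on `kappa`
are derived from the profile's total read count `Y` via literature
estimates of total bound polymerase per cell: `kappa in [11e5 / Y,
18e5 / Y]`.

## Known limitations

* The mean-field factorization is an approximation; on small systems with
  low injection it is accurate to a few percent (the stochastic simulator
  quantifies this), and it is exact only in the hydrodynamic limit.
* `b > 0` (backward hops) is supported by the forward model but not
  inferred; `a` and `b` are fixed, not estimated.
* Langmuir attachment/detachment, non-Markovian dwell times, extended
  particle footprints and dynamic defects are out of scope.
* The noise-free simulation posterior is near-degenerate (see above);
  hyperparameter point estimates from finite chains inherit that
  difficulty.
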