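---
title: "Errors-in-variables land use regression with spatially varying coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Errors-in-variables land use regression with spatially varying coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwtlsr)
```

## The problem

Land use regression (LUR) predicts a pollutant concentration observed at a
small network of monitoring stations from spatial covariates: traffic
volume extracted in buffers around each station, land-use shares, and
meteorological variables. Two features of such data break the assumptions
of an ordinary least squares fit. First, the covariates are themselves
products of measurement or modelling — a traffic count from a transport
model, a land-use share from map digitization — so they carry errors whose
magnitudes are often roughly known. Regressions that ignore covariate
error attenuate slope estimates toward zero, and the bias leaks into the
intercept and into any prediction made away from the covariate mean.
Second, the relationship between concentration and its drivers is rarely
constant across a city: the same traffic volume can imply different
concentrations downtown and at the periphery (spatial nonstationarity).

The estimator at the core of this package, geographically weighted total
least squares regression (GWTLSR), addresses both at once by solving a
weighted total least squares (WTLS) problem at every location, with
Gaussian distance-decay kernel weights supplying the response covariance.
The package also implements the three natural baselines — OLS, GWR
(nonstationarity only), and global WTLS (covariate error only) — on the
same design-system representation, so the four estimators are directly
comparable.

## Model and estimation

A `design_system` bundles the $m \times n$ design matrix $A$ (covariates
plus a trailing intercept column of ones), the response $y$, the per-cell
covariate measurement variances $\delta^2_{a_{ik}}$ (the diagonal of
$Q_A$, stored column-major with the intercept block identically zero — an
intercept is not observed, so it carries no error), per-observation
response variances (diagonal $Q_y$), and projected planar coordinates in
meters. Estimation requires $m > n$ and a full-rank design.

WTLS minimizes $\phi = e_y^T Q_y^{-1} e_y + e_A^T Q_A^{-1} e_A$ subject to
$y = (A - E_A)x + e_y$. Differentiating the Lagrangian gives the
stationarity system solved by fixed-point iteration from the OLS start:

1. $Q_{\tilde y} = Q_y + (\hat x^T \otimes I_m) Q_A (\hat x \otimes I_m)$
   — with per-cell variances this is the diagonal
   $Q_y + \sum_k \hat x_k^2\, \mathrm{diag}(\delta^2_{\cdot k})$, so the
   whole cycle is elementwise plus one $n \times n$ solve;
2. $\hat\lambda = Q_{\tilde y}^{-1}(y - A\hat x)$;
3. $\tilde e_A = -Q_A(\hat x \otimes I_m)\hat\lambda$ (column $k$ of
   $\tilde E_A$ is $-\delta^2_{\cdot k}\,\hat x_k\,\hat\lambda$);
4. $\hat x = (\tilde A^T Q_{\tilde y}^{-1} \tilde A)^{-1}\tilde A^T
   Q_{\tilde y}^{-1}(y - \tilde E_A \hat x)$ with
   $\tilde A = A - \tilde E_A$.

A fixed point of this cycle is exactly a stationary point of the profiled
objective $\phi(x) = (y - Ax)^T Q_{\tilde y}(x)^{-1} (y - Ax)$: the
gradient is $-2\tilde A^T \hat\lambda$, which step 4 zeroes. The test
suite exploits this by checking the iterative solution against a
brute-force grid-plus-simplex minimizer of $\phi(x)$ on small systems.

GWTLSR runs this cycle at each regression point with
$Q_y = W(u_i,v_i)^{-1}$, where $W_k = \exp(-d_k^2/b^2)$ is the fixed
Gaussian kernel. Observations sharing exact coordinates (repeated samples
at one station) share a local fit, so the per-location cost scales with
the number of distinct stations, not samples.

Two printed forms of the estimator required interpretation, resolved here
by dimensional analysis and internal consistency of the Lagrangian
solution: the design-error update is implemented in the orientation
$-Q_A(\hat x \otimes I_m)\hat\lambda$ (the transposed form is
dimensionally impossible), and the geographically weighted variant runs
the full iteration with the kernel-derived $Q_y$ rather than a one-shot
first-order correction (available via `max_iter = 1`, and equivalent to
iterating once from the OLS start).

## Tunable parameters

* **Bandwidth `b` (meters).** Decay scale of the kernel; selected by
  default through golden-section search on log-bandwidth minimizing AICc,
  bounded between 0.1× and 10× the maximum pairwise station distance, with
  search tolerance 1e-3. The search is deterministic; exact AICc ties are
  broken toward the smaller bandwidth and noted.
* **Convergence (`tol = 1e-10`, `max_iter = 100`).** The WTLS cycle stops
  when the relative sup-norm coefficient change drops below `tol`.
  Non-convergence returns an honest `converged = FALSE` with a warning; as
  a safeguard the iterate with the lowest profiled objective is returned
  if the last one is worse, so the solution never degrades the objective
  relative to its OLS start.
* **Weight floor (1e-12).** Kernel weights are clamped before inversion
  into $Q_y$; a Gaussian weight underflows to exact zero at large
  distance, which would make $Q_y$ undefined. If fewer observations than
  unknowns carry weight above the floor at some regression point, the fit
  fails there with an error naming the location rather than regularizing
  silently.
* **Exceedance percentile (90).** POD/POF classify exceedances of the
  90th percentile of the observed series, computed with linear
  interpolation between order statistics; the threshold pool is the
  series passed in.
* **Moran's I weights.** Row-standardized inverse Euclidean distance with
  zero diagonal; significance labels cut at |z| = 1.96 under the
  randomization-moments approximation. When multiple samples share a
  station, `metrics_report()` computes Moran's I on station-mean residuals
  at the station coordinates, because coincident points contribute no
  between-station spatial information and would otherwise dominate the
  inverse-distance weights through the coincidence floor.

## Model assessment

AICc is computed as $2n\ln\hat\sigma + n\ln 2\pi + n(n + \mathrm{tr}\,S)/
(n - 2 - \mathrm{tr}\,S)$ with $\hat\sigma = \sqrt{RSS/n}$, the
maximum-likelihood scale — the convention under which the criterion
matches the standard local-regression AICc. The hat rows are
$r_i = A(i,:)(A^T W_i A)^{-1} A^T W_i$ for GWR; for GWTLSR the corrected
design $\tilde A$ and the combined covariance $Q_{\tilde y}$ take the
roles of $A$ and $W^{-1}$. For the global fits the trace equals the
number of model columns. A trace at or beyond $n - 2$ signals an undefined criterion
explicitly (`Inf` with a warning) instead of returning a misleading
number.

Variable selection follows a two-stage protocol. Stage one ranks
candidates by |Pearson r| with the response and keeps, within each buffer
family (e.g. `traffic_150`, `traffic_300`), only the buffer with the
highest |r| — ties break toward the smaller buffer, then lexicographically
(both logged). Stage two enumerates all subsets up to five variables
(exhaustive, hence the 12-candidate cap), discards any subset containing a
coefficient with p > 0.05 *in that subset's fit* (a variable may be
significant in one combination and not another), and picks the surviving
subset with maximal R². The best-RMSE-per-size profile over all
enumerated subsets is reported alongside; it is non-increasing by
construction. Validation is station-wise leave-one-out: one fold per
station, training on all other stations' samples, so the model is never
scored at a location it has seen — the appropriate protocol when the goal
is prediction at unmonitored sites.

Prediction at new locations defaults to refitting the local problem at
the query point (reweighting the training data around it), the standard
practice for local regression; copying the nearest regression point's
coefficients is available as `mode = "nearest"`. New covariate rows are
used as given — no measurement-error correction is applied to them, since
their errors are unknown individual realizations.

## The synthetic-data generator

Real LUR monitoring data are rarely shareable, so the generator
(`sim_config()` / `simulate_lur()`) emulates the structure of a small
urban PM2.5 network with known ground truth. Defaults describe one season
of daily means at a 9-station network: stations placed uniformly at
random in a 20 km square, 260 samples per station, two covariates drawn
per sample with mean 10 and sd 3, base coefficients (2, −1) and intercept
5, and coefficient surfaces varying linearly along the SW–NE diagonal
with range ±50% of the mean — strong, smooth nonstationarity at the
spatial scale the network can resolve. Covariate measurement noise is
Gaussian with sd equal to 30% of the covariate sd (the variance is
reported in the `__var` columns exactly as injected), and observation
noise is 2 µg/m³. All randomness flows from one seed through named
substreams (placement, features, feature noise, observation noise), so
individual components can be frozen independently; the generated tables
satisfy the exact identity observed = truth + stored noise.

What the generator does *not* emulate: temporal autocorrelation across
days, meteorological physics, correlated covariates, non-Gaussian or
misspecified measurement-error variances, and purposeful (non-random)
station siting. Passing tests therefore demonstrate correct estimator
behavior under a known, well-specified EIV regime — not performance on
any particular real network.

`recovery_study()` operationalizes the estimator comparison: per
replicate it simulates a dataset, selects a bandwidth by AICc on the GWR
profile (shared between GWR and GWTLSR so both see the same smoothing),
fits each estimator, and scores coefficient recovery against the true
local coefficients, optionally adding held-station prediction RMSE via
leave-one-out. Under the default regime the mean coefficient-recovery
RMSE over 20 replicates orders GWTLSR < GWR < OLS: locality buys the
GWR-family estimators the nonstationary truth, and the EIV correction
buys GWTLSR the de-attenuated slopes.

One caveat worth stating: the residual-autocorrelation contrast (OLS
residuals spatially clustered, GWTLSR residuals random) is detected with
limited power at 9 stations — the Moran z-test on 9 station means flags
the OLS clustering in roughly three quarters to four fifths of
replicates, depending on how favorably the random station layout spreads.
That is a property of small monitoring networks, not of the estimator.

## Numerical choices and degenerate inputs

* OLS and the local solves use Cholesky-backed normal equations via
  `solve(crossprod(...))`; rank deficiency is reported with the offending
  column names (via the pivoted QR).
* The design covariance is diagonal by construction (per-cell variances),
  which the solver exploits throughout; a full $Q_A$ would require the
  general $mn \times mn$ machinery and is out of scope.
* Degenerate inputs fail loudly and specifically: constant observed
  series (undefined R² or Moran's I), empty inputs, negative variances,
  coincident coordinates in Moran's I (distance floor with warning),
  starved regression points, saturated hat traces.
* Library code is deterministic; all stochastic behavior lives in the
  generator and flows from explicit seeds.

## Problem sizes

The test suite runs the full default regime (9 × 260 samples) only where
the comparison needs it — recovery orderings, residual-pattern contrasts
— and smaller draws (5–30 samples per station) for structural checks;
oracle-equivalence checks use systems of up to 6 observations where brute
force is exact. The complete suite runs in under two minutes on one core;
`scripts/acceptance.R` in about one.

## Known limitations

* Only the fixed Gaussian kernel is provided (no adaptive,
  bisquare, or exponential kernels).
* Measurement variances must be supplied; the package does not estimate
  them. How to assign realistic $\delta^2$ values to traffic, land-use
  and meteorological covariates is a substantive modelling question left
  to the user.
* No GIS functionality: buffers, land-use extraction and transport
  modelling happen upstream; coordinates must already be projected to a
  planar metric CRS.
* The per-location WTLS hat matrix treats the estimated design errors as
  fixed when building $\mathrm{tr}(S)$; this is the natural plug-in
  choice, and AICc comparisons across models should be read with that
  approximation in mind.
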