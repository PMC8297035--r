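# gwtlsr

Errors-in-variables spatial regression for land use regression (LUR)
modelling of air pollution.

LUR models predict a pollutant concentration (here PM2.5, µg/m³) at
monitoring stations from spatial covariates — traffic volume in buffers,
residential/non-residential land-use shares, meteorology. Standard fits
treat those covariates as exact and the regression coefficients as constant
over space. Both assumptions usually fail: the covariates come from
measurement or modelling (so they carry known error), and the
pollution–covariate relationship varies across a city (spatial
nonstationarity). This package implements **geographically weighted total
least squares regression (GWTLSR)**, which addresses both at once, together
with its three baselines (OLS, GWR, global WTLS), the surrounding model
assessment and validation machinery, and a synthetic-data generator with
known ground truth for evaluating the estimators.

## The model

At each regression point $(u_i, v_i)$ the observations satisfy the
errors-in-variables model

$$y = (A - E_A)\,x(u_i,v_i) + e_y,$$

where $A$ is the $m \times n$ design matrix (covariates plus a trailing
intercept column of ones), $E_A$ its unknown random errors with known
per-cell variances $\delta^2_{a_{ik}}$ (diagonal of $Q_A$; zero for the
intercept column), and $e_y$ the response errors with covariance
$Q_y = W(u_i,v_i)^{-1}$, the inverse of the Gaussian kernel weights

$$W_k(u_i,v_i) = \exp(-d_k^2 / b^2),$$

with $d_k$ the Euclidean distance from site $k$ to the regression point
and $b$ the bandwidth (meters). The weighted total least squares problem

$$\phi = e_y^T Q_y^{-1} e_y + e_A^T Q_A^{-1} e_A \to \min$$

is solved by Lagrange multipliers through the fixed-point cycle

$$Q_{\tilde y} = Q_y + (\hat x^T \otimes I_m)\,Q_A\,(\hat x \otimes I_m),
\qquad \hat\lambda = Q_{\tilde y}^{-1}(y - A\hat x),$$
$$\tilde e_A = -Q_A(\hat x \otimes I_m)\hat\lambda, \qquad
\hat x = (\tilde A^T Q_{\tilde y}^{-1}\tilde A)^{-1}
\tilde A^T Q_{\tilde y}^{-1}\tilde y,$$

with $\tilde A = A - \tilde E_A$, $\tilde y = y - \tilde E_A \hat x$,
initialized at the OLS solution. Setting $Q_A = 0$ recovers GWR; setting
additionally $b \gg$ the region extent recovers OLS — identities the test
suite verifies to 1e-8.

The bandwidth is selected by minimizing the corrected Akaike criterion
$AICc = 2n\ln\hat\sigma + n\ln 2\pi + n\,(n + \mathrm{tr}\,S)/(n - 2 -
\mathrm{tr}\,S)$, with the hat-matrix trace $\mathrm{tr}(S)$ as the
effective number of parameters. Assessment metrics include R², RMSE, MAE,
POD/POF for 90th-percentile exceedances, and residual Moran's I with
randomization inference (Clustered / Random / Dispersed patterns).

## Worked example

```r
library(gwtlsr)

sim <- simulate_lur(sim_config(seed = 42))   # 9 stations, 260 samples each
fit <- gwtls(y ~ f1 + f2, sim$data, method = "gwtlsr")
summary(fit)
```

```
Spatial LUR model fit — GWTLSR
Call: gwtls(formula = y ~ f1 + f2, data = sim$data, method = "gwtlsr")
Observations: 2340  Covariates: f1, f2
Kernel bandwidth: 2191.6 m (fixed Gaussian)
Local coefficients (summary over regression points):
                  25%       50%        75%
f1           1.983019  2.266875  2.3539420
f2          -1.147112 -1.085966 -0.8743445
(Intercept)  4.187621  4.378040  4.5199336

Model assessment (n = 2340 )
  R2          0.8713
  RMSE        2.9232
  MAE         2.3163
  AICc      11709.83  (sigma_hat 2.9232, tr(S) 23.26)
  POD          0.825   POF    0.277  (90th-pct threshold 26.203)
  Moran's I   -0.133  (z -0.16, p 0.873, Random)
```

The generator's true coefficient surfaces vary linearly across the region
(base values 2, −1, intercept 5, each ±50% along the SW–NE diagonal), and
the observed covariates carry measurement noise at 30% of their spread.
The local coefficient quartiles track that spatial variation; the kernel
bandwidth (~2.2 km in a 20 km region) was selected by AICc; and the
residual Moran's I is non-significant ("Random"), i.e. the local EIV fit
leaves no spatial structure behind. Held-station validation:

```r
loocv_by_station(y ~ f1 + f2, sim$data, method = "gwtlsr",
                 bandwidth = fit$bandwidth)$mean
#  rmse_test   mae_test rmse_train  mae_train
#      3.215      2.582      2.925      2.318
```

A shell interface wrapping the same functions is installed as
`exec/gwtls`, with subcommands `simulate`, `select`, `fit`, `cv`,
`predict`, `metrics`, and `compare`.

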