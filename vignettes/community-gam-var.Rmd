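---
title: "Dynamic GAM-VAR models for multispecies count time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic GAM-VAR models for multispecies count time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamvar)
```

## The model

`gamvar` fits a Poisson state-space model to monthly capture counts of a
community of $n$ species. Writing $Y_{i,t}$ for the observed count of
species $i$ at month $t$,

$$
Y_{i,t} \sim \mathrm{Poisson}\!\big(\exp(X_{i,t})\big), \qquad
X_{t} = \mu_{t} + z_{t},
$$

where $\mu_{t}$ is a hierarchical GAM mean and $z_t$ is a latent VAR(1)
deviation process

$$
z_t = A\, z_{t-1} + \varepsilon_t, \qquad
\varepsilon_t \sim \mathcal N\!\big(0,\; \Sigma\big), \qquad
\Sigma = \mathrm{diag}(\sigma)\, C\, \mathrm{diag}(\sigma).
$$

The GAM mean combines, per species,

* an intercept $\alpha_i$;
* a hierarchical linear effect $\beta_{\mathrm{NDVI},i}$ of the z-scored
  12-month trailing moving average of NDVI (a slow resource-availability
  signal), with partial pooling
  $\beta_{\mathrm{NDVI},i} \sim \mathcal N(\mu_{\mathrm{NDVI}},
  \sigma_{\mathrm{NDVI}}^2)$;
* a *shared* distributed-lag smooth $f_{\mathrm{global}}(\ell, T_{\min})$
  of z-scored monthly minimum temperature over lags $\ell = 0,\dots,6$
  months, built as a tensor product of a cubic regression spline margin in
  lag ($k = 4$) and a low-rank thin-plate margin in temperature ($k = 3$),
  summed over the lag window per timepoint;
* for a designated subset of species, a *deviation* smooth on the same
  basis, so the species response is the sum of the community function and
  its own deviation.

The diagonal of $A$ captures density dependence; off-diagonal entries
capture lagged cross-species dependence; $C$ captures contemporaneous
process-error correlation. Missing trapping sessions contribute nothing to
the observation term, but the latent process remains defined there.

### The VAR applies to deviations

The autoregression acts on the deviations $z_t = X_t - \mu_t$, not on the
raw state. This keeps the GAM interpretable as the stationary mean of the
latent process, and it is the form under which the stationarity constraint
below has its usual meaning. The alternative (applying $A$ to $X_t$
directly) changes the interpretation of the covariate functions and was
not adopted.

### Stationarity by construction

Rather than rejecting non-stationary draws, the sampler works on an
unconstrained matrix $R$ that is mapped to a stationary coefficient
matrix. The map is the order-1 case of the partial-autocorrelation
construction for vector autoregressions:

$$
P = (I + R R^\top)^{-1/2} R, \qquad
G \,(I - P P^\top)\, G = \Sigma, \qquad
A = G P G^{-1},
$$

where $G$ is the symmetric positive-definite solution of the middle
(Riccati-type) equation, available in closed form via symmetric square
roots. $A$ is similar to $P$, whose singular values all lie below one, so
the spectral radius of $A$ is below one for *every* real $R$; moreover
$\Gamma = G^2$ is exactly the stationary covariance of $z_t$, which the
model uses for the initial state — so enforcing stationarity and
initializing from the stationary distribution come from one construction.
In one dimension the map reduces to $a = r/\sqrt{1+r^2}$. Forecast
variance therefore converges with horizon instead of growing without
bound.

### Priors and identifiability

Smooth coefficients carry the usual penalized-spline prior
$\beta_s \sim \mathcal N\!\big(0, (\lambda_s S_s)^{-}\big)$ with one
smoothing parameter per marginal penalty and
$\lambda_s \sim \mathrm{Gamma}(2, 0.1)$ — a prior whose mass (roughly
2–56) keeps penalized-direction standard deviations in the plausible
0.1–0.7 range for unit-scaled covariates and log-scale means. The
traditional much vaguer Gamma(0.05, 0.005) default was examined and
rejected: its heavy mass near $\lambda = 0$ and far right tail create
extreme curvature regions that show up as divergent Hamiltonian
transitions; on synthetic data the two priors give indistinguishable
fitted functions, but only the bounded prior samples cleanly. The global
smooth is centered
(sum-to-zero over training timepoints) against the intercepts, and its
penalty null space receives its own penalty so the prior is proper.
Deviation smooths additionally have fully penalized null spaces, so a
species deviates from the community function only where the data support
it. Remaining priors: $\alpha_i \sim \mathcal N(0, 2^2)$,
$\mu_{\mathrm{NDVI}} \sim \mathcal N(0,1)$,
$\sigma_{\mathrm{NDVI}} \sim \mathrm{Exp}(2)$ (non-centered),
$\sigma_i \sim \mathrm{Exp}(1)$, $C \sim \mathrm{LKJ}(2)$, and
$R_{jk} \sim \mathcal N(0, 0.5^2)$. These are weakly informative defaults
for unit-scaled covariates and log-scale count means, and all are
overridable through `build_model(priors = ...)`.

### Benchmarks

Four nested variants support model comparison: `GAM-VAR` (full model),
`GAM-AR` (diagonal $A$, $C = I$: no cross-species dynamics),
`GAM-AR-no-pooling` (additionally drops the shared smooth and the
hierarchical slope prior; every species gets an independent slope and an
independent full-rank distributed-lag smooth), and `AR` (intercepts and
diagonal dynamics only).

## Estimation

The joint posterior — regression and smooth coefficients, smoothing
parameters, the unconstrained dynamics matrix, process scales and
correlations, and the latent states — is sampled with an adaptive
No-U-Turn sampler written for this model, with analytic reverse-mode
gradients (including through the stationarity map's three symmetric
square roots and the correlation-matrix transform). Latent states use a
non-centered innovation parameterization
($z_1 = \Gamma^{1/2}\varepsilon_1$,
$z_t = A z_{t-1} + \Sigma^{1/2}\varepsilon_t$,
$\varepsilon \sim \mathcal N(0, I)$), which removes the scale/state
funnel that otherwise cripples mixing of $\sigma$. Warmup uses
dual-averaging step-size adaptation (target acceptance 0.9 by default)
and mass-matrix estimation over expanding memory windows — diagonal for
the latent innovations, with a dense block over the dynamics parameters
(unconstrained dependence matrix, log process scales, correlation
partials), whose strong mutual posterior correlations a diagonal metric
cannot exploit. Convergence is
monitored with rank-normalized split-$\widehat R$ and bulk effective
sample sizes on the natural-scale parameters, plus divergence counts.

Gradient correctness is pinned by tests comparing every parameter block
against central finite differences, and the sampler itself is validated
against the closed-form posterior of a conjugate Poisson–Gamma toy model.

Two practical notes on convergence monitoring. First, the unconstrained
cross-dependence entries (the raw matrix behind $A$) are the most strongly
correlated block of the posterior; they receive a dense mass-matrix block
(estimated from the warmup draws; everything else stays diagonal), and
even so their effective sample sizes are the smallest in the model — short
chains will show their largest $\widehat R$ values there, which is a
sampling-efficiency signal rather than a validity problem (long reference
runs confirm a unimodal posterior). Second, the off-diagonal entries of
$A$ itself are heavy-tailed *derived* quantities — the stationarity
constraint bounds the spectral radius, not individual entries, so when the
stationary scales of two species differ strongly, $A_{ij}$ can wander over
large values. `fit_diagnostics()` therefore monitors the sampled
(unconstrained) cross-dependence parameters alongside the natural-scale
diagonal of $A$, the slopes, intercepts, process scales and correlations.

## Model comparison and forecast evaluation

In-sample comparison uses PSIS-LOO: pointwise log-likelihoods are
reweighted by Pareto-smoothed importance weights (tail size
$\lfloor\min(0.2S,\ 3\sqrt S)\rfloor$, generalized-Pareto fit by the
Zhang–Stephens posterior-mean method with shrinkage toward $k=0.5$,
truncation at the raw maximum), giving ELPD values and pairwise
differences with standard errors; the best model is the reference row
(0.0, 0.0). Note the usual caveat for state-space models: the pointwise
likelihood conditions on the latent states, so tail-shape diagnostics are
often pessimistic; the accompanying warning is informative, not fatal.

Out-of-sample evaluation is exact leave-future-out cross-validation:
refit on an expanding window, forecast 12 months ahead from full
posterior-predictive count ensembles, and score each observed test month
with the energy score, the variogram score (exponent $p = 0.5$, unit pair
weights — the score's customary defaults, configurable) and their evenly
weighted mean. Scores are computed on the observation (count) scale,
including Poisson noise, because forecasts are judged against observed
captures. Masked test months are skipped and flagged.

## Scenario tools

* `forecast()` propagates each draw's dynamics forward and emits Poisson
  counts (hindcast mode: observed future covariates).
* `impulse_response()` maps an impulse of $k$ extra captures to the latent
  scale through the log-ratio at the draw's baseline expected captures
  (posterior median of $\mu$ over the training window), spreads it
  contemporaneously with the generalized-impulse convention
  $\delta = \Sigma_{\cdot i}\,\delta_i/\Sigma_{ii}$ (no species ordering
  is imposed, and correlated process errors produce the expected
  instantaneous spillover), and propagates with powers of $A$.
* `covariate_contrast()` evaluates the change in expected captures when
  the z-scored NDVI moving average moves from a low to a high value
  (default $-0.5 \to 0.5$), holding other covariates at training means
  and the dynamic deviation at zero; the reference state sits at the low
  value, so a slope draw $\beta$ gives
  $\Delta = e^{\mu_{\mathrm{ref}}+\beta} - e^{\mu_{\mathrm{ref}}}$.
* `conditional_lag_function()` reconstructs the seasonal temperature
  effect implied by the distributed-lag smooth for a supplied year of
  temperatures, wrapping lags across the year boundary; species outside
  the deviation subset show the global function; curves are scaled to
  unit variance for shape comparison.

## The synthetic-data generator

`simulate_covariates()` produces a seasonal minimum-temperature sinusoid
(mean 5 °C, amplitude 8 °C, noise sd 1.5 °C) and an NDVI series (base
0.25, seasonal amplitude 0.08, slow random-walk trend sd 0.01/month,
noise sd 0.02, clipped to a plausible positive range), with a 12-month
covariate lead-in before the count window. The covariates' marginal
distributions are this package's choice of a realistic semi-arid pattern;
only their qualitative features (seasonality, slow NDVI change) are taken
from the study system. `default_true_params()` draws intercepts around
$\log 3$ (low counts with many zeros), community-positive NDVI slopes
($\mathcal N(0.3, 0.15^2)$), a smooth global lag surface, process sds in
$[0.3, 0.5]$, an LKJ(2) correlation, and a dependence matrix with
off-diagonal raw entries bounded by 0.3 pushed through the stationarity
map. `simulate_community()` assembles $\mu$, simulates $z$ from the
stationary distribution (with a 24-month burn-in), draws Poisson counts,
and masks whole sessions at the missing rate (5% by default — sessions
are community-wide, so missingness is too). Counts are simulated
unbounded: the model has no trap-ceiling, so neither does its generator.

What the generator does *not* emulate: observation effort variation,
detection heterogeneity between species, trap saturation, regime shifts,
or covariate measurement error. Passing tests on these data demonstrate
that the machinery recovers the model's own structure at realistic sizes,
not that the model is adequate for any particular field system.

## Numerical choices and scale decisions

* Basis dimensions follow the design: 4 (lag, cubic) x 3 (temperature,
  thin-plate) tensor, lags 0..6 — lag 0 is included since "up to 6
  months" bounds the window from above and the current month carries the
  strongest signal. Knots sit at training-window quantiles.
* z-scoring uses the sample (n−1) standard deviation, with moments from
  the training window only.
* Species filtering keeps species with nonzero captures in at least 10%
  of observed sessions (exclusion is strictly below threshold).
* The default sampler settings are 4 chains, 500 warmup, 1,600 sampling
  iterations. Test-suite and acceptance runs use reduced sizes (2 chains,
  150-500 warmup/sampling; 3-4 species over 100-150 months) chosen so the
  full suite completes on a single CPU while leaving Monte-Carlo margins
  comfortable; the vignette states these sizes so results are
  reproducible at the same scale.
* Degenerate inputs are handled explicitly: flat importance ratios make
  PSIS smoothing a no-op; zero-variance reference windows and
  zero-variance lag curves raise an error and a warning respectively;
  constant chains make $\widehat R$ return NaN with a warning.

## Known limitations

* In-sample model comparison by conditional-likelihood PSIS-LOO separates
  the nested variants only weakly on short series: a benchmark lacking the
  GAM mean can inflate its process standard deviations and let its free
  latent states absorb the missing structure, leaving within-sample
  predictive densities nearly tied even when the generative model has
  strong covariate and cross-species effects. Leave-future-out
  cross-validation, which actually scores held-out months, discriminates
  reliably and is the comparison to trust at small scale.
* VAR order is fixed at 1 and the dependence matrix is time-invariant.
* The observation family is Poisson only — no trap ceiling and no
  explicit overdispersion beyond the latent process.
* PSIS-LOO for this model conditions on latent states (the standard
  practice for this model class), which is optimistic relative to a
  marginal likelihood and yields conservative Pareto-k diagnostics.
* Covariate forecasting is out of scope: forecasts and cross-validation
  use observed future covariates (hindcasting).
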