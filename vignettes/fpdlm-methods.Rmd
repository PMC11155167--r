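---
title: "Methods: constrained distributed lag models for repeated binary exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained distributed lag models for repeated binary exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpdlm)
```

## The estimation problem

A binary exposure $X_{ik} \in \{0,1\}$ is recorded for subject $i$ at $K$
past questionnaires, each at a per-subject lag $t_{ik}$ (months before the
binary outcome $Y_i$ is assessed). The scientific target is the per-lag log
odds ratio $\beta(t)$ and the *critical windows* — lag ranges where the
exposure–outcome association is present.

Entering the $K$ indicators separately (the "Single" model) biases each
coefficient away from the null whenever the exposure trajectory is
persistent, because each wave proxies the others. Entering them jointly
(the "Multi" model) is unbiased on average but near-collinearity inflates
the variances. `fpdlm` constrains the Multi model's lag profile to a smooth
fractional polynomial,

$$\beta(t) = \delta_0 + \delta_1 t + \delta_2 t^2 + \delta_3 \sqrt{t},$$

which converts the $K$ exposure terms into the 4-column collapsed design
$W_i = \sum_k T(t_{ik}) X_{ik}$ with $T(t) = (1, t, t^2, \sqrt t)^\top$, so

$$\operatorname{logit} \pi_i = \beta_0 + \boldsymbol\delta^\top W_i +
  \boldsymbol\eta^\top Z_i$$

is an ordinary logistic regression, fitted by maximum likelihood. The
fitted curve is $\hat\beta(t) = T(t)^\top\hat{\boldsymbol\delta}$ with
delta-method variance
$V(\hat\beta(t)) = T(t)^\top \mathrm{Cov}(\hat{\boldsymbol\delta}) T(t)$;
this variance is exact for the linear combination (no linearisation error),
which is why a Monte-Carlo draw from
$N(\hat\delta, \mathrm{Cov}(\hat\delta))$ reproduces the standard error to
Monte-Carlo accuracy — one of the oracle checks in the test suite.

### Assumptions

* The lag profile $\beta(t)$ is smooth enough to be captured by the
  four-term basis. When the truth is a sharp indicator window (scenario 3
  below), the fitted curve is the basis projection: the peak location is
  preserved but its height is attenuated — roughly halved in the window
  scenario — and side lobes appear at neighbouring lags.
* Lags are strictly positive real months; the outcome time is lag 0. The
  fractional power $\sqrt t$ (and the convention $t^0 = 1$) requires
  $t > 0$.
* Complete cases; no missing-data machinery is provided.

### Inference and windows

Wald inference on the log-odds scale with $z_{0.975} = 1.959964$ is used
throughout; intervals are reported on the odds-ratio scale. A lag grid
point is *significant* when its interval excludes 1, and
`critical_windows()` reports maximal consecutive runs of significant grid
points. These tests are **pointwise**: across a default grid of ~28 integer
lags the family-wise false-positive rate of "at least one window somewhere"
is well above 5% (the curve has about 4 effective degrees of freedom, so
the practical rate is in the 20–25% range on null data). Windows should be
read as descriptions of where the curve is individually significant, not as
a multiplicity-controlled discovery procedure. The interval shape at the
grid ends is driven by data sparsity: few subjects have realized lags
there, so the bands widen.

### Identifiability

A $p$-term basis needs at least $p$ distinct observed lags: with exactly 3
shared lags the 4-term basis is rank deficient. In practice the per-subject
jitter of questionnaire response times supplies many distinct lags and
rescues the rank. `fpdlm_fit()` computes the condition number of the design
(ratio of extreme singular values) and refuses above `cond_tol = 1e10`,
naming the number of distinct lags in the error. The basis is configurable
via `powers`; the default `c(0, 1, 2, 0.5)` is the curve family this model
class conventionally uses, and no data-driven power selection is performed
(dropping to `powers = c(0, 1, 2)` with 3 shared lags reproduces the Multi
model exactly — the "saturated" check in the tests; `powers = 0` reduces to
regression on the exposure count).

## Numerical choices

* Fitting is IRLS (`stats::glm.fit`) with relative deviance tolerance
  `1e-10` and at most 100 iterations; the coefficient covariance is the
  inverse Fisher information from the pivoted QR of the final weighted
  design.
* Non-convergence, aliasing and (quasi-)separation — fitted probabilities
  pinned at the numerical 0/1 boundary — are reported as a `converged`
  flag; `lag_effects()` refuses to report a curve from a non-converged
  fit. Individual $\delta$ components are legitimately large (the basis
  columns are highly collinear; only the curve is well determined), so
  separation is *not* inferred from coefficient magnitude.
* Delta-method variances are clipped at zero only within a relative
  `1e-10` of rounding noise; genuinely negative variances raise an error.
* Categorical covariates are reference-cell dummy coded, reference = first
  declared level (for CSV input: first category in file order).

## The simulator

The simulation design mirrors a 10-wave questionnaire study:

* **Times.** Wave $k$ targets lag $6k$; the realized lag is $6k$ with
  probability 0.45, $6k\pm1$ with 0.15 each, $6k\pm2$ with 0.10 each and
  $6k+3$ with 0.05. The support is deliberately asymmetric (a $+3$ tail
  but no $-3$): late responses happen, very early ones do not.
* **Exposures.** A latent normal vector $V \sim N(0, C)$ with AR(1)
  correlation $c_{ij} = \gamma^{|i-j|}$ is thresholded at
  $\Phi^{-1}(p_k)$, giving exact marginals $P(X_k = 1) = p_k = 0.2$ and
  trajectory persistence controlled by $\gamma \in \{0, 0.975, 0.9999\}$
  (0.975 matches the persistence of pet ownership across cohort waves).
  At $\gamma = 0.9999$ the Cholesky factorisation falls back to a `1e-12`
  diagonal jitter if needed.
* **Outcomes.** $\operatorname{logit} P(Y_i = 1) = -2.2 +
  \sum_k X_{ik}\,\beta(t_{ik})$, with the true effect evaluated at the
  *realized* jittered lag. This choice (rather than the scheduled lag
  $6k$) is what produces the boundary biases of window-type profiles:
  subjects whose response time straddles a window edge carry or miss the
  effect. The $-2.2$ intercept puts the unexposed outcome rate at
  $\operatorname{expit}(-2.2) \approx 0.0998$.
* **Scenarios.** (1) constant $\beta(t) = 0.15$; (2) a concave quadratic
  $a(t - t_0)^2 + c$, defaults $a = -2\times10^{-4}$, $t_0 = 33$,
  $c = 0.2$; (3) an indicator plateau $h\,\mathbf{1}[36 \le t \le 47]$,
  default $h = 0.25$. The scenario 2/3 magnitudes are only published
  graphically in the literature this design follows, so they are
  constructor arguments and their defaults should be treated as
  package-chosen calibrations, not verified values; they are excluded from
  the replication checks.

Replication metrics follow simulation-study convention: bias
$\bar{\hat\beta} - \beta(6k)$, EmpSE with the $n-1$ denominator, and MSE,
evaluated at the canonical times $6k$ for all models (the tables this
layout reproduces are indexed that way), reported both raw and on the
$\times 100$ scale. Per-replication seeds are a deterministic counter mix
of the master seed, so any replication is re-runnable in isolation and a
truncated run equals a shorter run.

### The synthetic cohort

`simulate_cohort()` emulates the shape of a three-wave birth cohort with a
wheezing-type outcome at age 3: waves at modal lags 39/30/18 months with
symmetric ±3-month response jitter, wave prevalences 14.3/17.2/12.5%,
latent AR(1) persistence 0.975, five categorical covariates with fixed
log-odds effects echoing the marginal differences seen in large cohort
tables (male sex +0.34, maternal asthma +0.81, preterm +0.36, small income
and area effects), and an intercept calibrated by root finding so the
realized outcome prevalence matches the 17% target. It is a synthetic
stand-in — the cohort it imitates is access restricted — so it reproduces
structure, not records: no real covariate joint distribution, no item
missingness, no within-area heterogeneity beyond a single factor, and
exposure persistence from a stationary copula rather than behavioural
dynamics. Passing tests on this generator demonstrate correctness of the
estimator under the stated generating process, not agreement with the real
cohort's estimates.

Recovery experiments use the attached `attr(, "truth")`. Two behaviours are
worth distinguishing: a basis-representable injected effect (e.g. a
constant log OR) is recovered with nominal interval coverage, while an
indicator-shaped effect confined to a few lags is smoothed — the fitted
curve concentrates the wave-average effect and sits below the in-window
truth. With three waves, an effect confined to lags 31–34 overlaps only
part of the 6-month wave's jitter range (27–33), so its effective
wave-level magnitude is roughly a third of the nominal value; detecting an
OR as small as 1.07 on such a band is underpowered at realistic cohort
sizes, and the package makes no claim to the contrary.

## Problem sizes used by the checks

The test suite replicates the study at $n = 10{,}000$ subjects per data set
with 500 replications per correlation level (a 200-replication slice is
re-evaluated at proportionally wider tolerances), and judges agreement with
the published cells at three Monte-Carlo standard errors accounting for
both runs' replication noise plus the tables' one-decimal print rounding.
`scripts/acceptance.R` uses 300 replications. These sizes were chosen so a
full run completes in minutes on one core while keeping Monte-Carlo noise
well inside the comparison tolerances.

## Known limitations

* No spline or penalized lag bases, no random effects, no Bayesian window
  selection, no continuous exposures or DLNM-style cross-bases.
* Pointwise windows (see above) — no simultaneous band is implemented, and
  whether published interval curves of this kind are pointwise or
  simultaneous is generally unstated; pointwise is assumed.
* Window determination at a fixed 5% level is sample-size driven: large
  cohorts flag tiny effects, small ones miss real windows.
* Complete-case analysis only.
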