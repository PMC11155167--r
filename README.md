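# fpdlm — fractional-polynomial distributed lag models for binary time-varying exposures

Birth-cohort studies record exposures like pet ownership on repeated
questionnaires (mid-pregnancy, age 6 months, age 1.5 years, ...) and ask at
which ages the exposure is associated with a later outcome such as wheezing —
the *critical windows*. Two standard analyses both struggle:

* **Single model** — one logistic regression per time point. Because
  exposure histories are highly persistent, each separate coefficient also
  absorbs the other time points' effects: biased away from the null.
* **Multi model** — all K exposure indicators in one logistic regression.
  Unbiased on average, but near-collinearity of the indicators inflates the
  variances, so nothing is detected.

`fpdlm` implements the middle road: a **distributed lag model (DLM)** that
constrains the per-lag log odds ratio to a fractional polynomial of the lag
*t* (months before the outcome assessment),

    beta(t) = delta0 + delta1 * t + delta2 * t^2 + delta3 * sqrt(t),

so the simultaneous model's K exposure terms collapse into 4 regressors

    W_i = sum_k (1, t_ik, t_ik^2, sqrt(t_ik)) * X_ik,

and the model `logit pi_i = beta0 + delta' W_i + eta' Z_i` is an ordinary
logistic MLE. The fitted curve `beta_hat(t) = T(t)' delta_hat` gets
delta-method pointwise Wald intervals from
`V(beta_hat(t)) = T(t)' Cov(delta_hat) T(t)`; maximal runs of lags whose
odds-ratio interval excludes 1 (two-sided 5%) are the estimated critical
windows. Identifiability of the 4-term basis comes from per-subject jitter
in questionnaire response times — with only 3 shared lags the basis is
rank-deficient, and the fit refuses with a diagnostic.

The package also ships the Single/Multi comparators, a Gaussian-copula
simulator for AR(1)-correlated binary exposure trajectories with jittered
observation times, a replication engine reporting bias, empirical SE and
MSE, a synthetic three-wave cohort generator (the real cohort it emulates is
access restricted), and a small command-line interface.

## Worked example

Fit the DLM to a synthetic 60,000-subject cohort with a smooth effect
peaking around lag 33 months:

```r
library(fpdlm)

cohort <- simulate_cohort(60000, seed = 2024,
                          effect = function(t) log(1.25) * exp(-((t - 33) / 5)^2))
fit <- fpdlm(y ~ child_sex + maternal_asthma + preterm + income + area,
             cohort, exposures = c("x1", "x2", "x3"),
             lags = c("lag1", "lag2", "lag3"))
lag_effects(fit, lags = seq(18, 42, by = 3))
critical_windows(fit)
```

```
Lag-effect curve (9 lags, 95% pointwise Wald intervals)
 lag  beta_hat      se     or ci_low ci_high significant
  18 -0.061787 0.05233 0.9401 0.8484   1.042       FALSE
  21 -0.051525 0.05315 0.9498 0.8558   1.054       FALSE
  24  0.008697 0.04839 1.0087 0.9175   1.109       FALSE
  27  0.082922 0.04110 1.0865 1.0024   1.178        TRUE
  30  0.144968 0.03904 1.1560 1.0708   1.248        TRUE
  33  0.175072 0.03952 1.1913 1.1025   1.287        TRUE
  36  0.157878 0.03752 1.1710 1.0880   1.260        TRUE
  39  0.081176 0.04560 1.0846 0.9918   1.186       FALSE
  42 -0.064935 0.08762 0.9371 0.7893   1.113       FALSE

  from to n_points
1   27 38       12
```

The curve recovers the injected bump: odds ratios rise to 1.19 near lag 33
and the pointwise tests flag lags 27–38 as the critical window (for a
3-year outcome answered at the modal age of 36 months, lag 30–36
corresponds to ages 0–6 months). `plot(fit)` draws the same curve with its
confidence band; `fit_single()` / `fit_multi()` run the comparators on the
same cohort.

For the simulation study:

```r
study <- run_replications(dlm_scenario(1), gamma = 0.975, n = 10000,
                          reps = 200, seed = 1)
compute_metrics(study)
```

gives bias / EmpSE / MSE per model and canonical lag on the conventional
x100 reporting scale, e.g. at time 24 the Single model's bias is ~102 (x100)
while Multi and DLM are near 0, and the Multi EmpSE is ~2.5x the Single's.

A shell interface wraps the same functions:

```sh
inst/cli/fpdlm gen-cohort --n 50000 --seed 1 --out cohort.csv
inst/cli/fpdlm fit --data cohort.csv --model dlm --out effects.csv
inst/cli/fpdlm simulate-study --scenario 1 --gamma 0.975 --reps 200 --out-dir out/
```

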