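# bmareg

Exact Bayesian model averaging (BMA) for Gaussian linear regression, built
for survey-epidemiology variable selection — the setting where a continuous
eyesight measure (right-eye logarithmic visual acuity on the Chinese
5-point scale) is regressed on a handful of behavioural risk factors
(weekly exercise days, diet, school-bullying, mental-stress and
internet-use scores, sleep hours) and the question is *which covariates
matter once model uncertainty is taken into account*.

Instead of conditioning on one selected regression, every subset of the
`s` candidate covariates defines a model `y = α + X_M β_M + ε`,
`ε ~ N(0, σ²I)` (intercept always included), and each model is weighted by
its posterior probability

```
P(M | y) ∝ p(y | M) P(M),     P(M) uniform over the 2^s models,
```

with the marginal likelihood available in closed form under a Zellner
g-prior `β_M | σ² ~ N(0, g σ² (X'X)⁻¹)` (flat priors on the intercept and
log σ; default `g = n`, the unit-information choice):

```
log p(y|M) = const + ((n−1−k)/2) log(1+g) − ((n−1)/2) log(1 + g(1−R²_M)).
```

Per variable, the package reports the posterior inclusion probability
(PIP = summed posterior probability of the models containing it), the
model-averaged coefficient mean and SD (law-of-total-variance form), a
sign-consistency summary, and Raftery-style evidence grades
(PIP < 0.5 none, [0.5, 0.75) weak, [0.75, 0.95) positive, ≥ 0.95 strong).
Per model, it reports exact posterior model probabilities next to the
frequency estimates of an MC3 (Metropolis–Hastings model composition)
sampler, plus the posterior model-size distribution and a signed
variable-inclusion map.  A calibrated synthetic generator reproduces the
per-stage descriptive structure of a large Tianjin school survey (primary /
junior / senior stages) so the whole pipeline is testable without the
restricted survey data.

## Worked example

```r
library(bmareg)
tab <- generate_stage(scenario_preset("junior_paper", seed = 7))
fit <- bma_lm(data = tab)     # or: bma_lm(acuity ~ exercise + ... , data = df)
summary(fit)
```

```
BMA estimation results [junior]
n = 8191 (0 incomplete rows dropped), s = 5, g = 8191

 variable     pip  post_mean   post_sd sign_consistency evidence
 exercise 0.80110  1.841e-02 1.095e-02           0.9997 positive
  network 0.02995  2.600e-04 1.813e-03           0.9241     none
 bullying 0.01463  5.570e-05 7.539e-04           0.7788     none
     diet 0.01159 -1.922e-05 5.462e-04           0.6352     none
 m_stress 0.01131 -2.358e-06 8.673e-05           0.6042     none

Top models by posterior probability:
 model_rank exercise bullying m_stress network diet size pmp_exact
          1        1        0        0       0    0    1   0.74830
          2        0        0        0       0    0    0   0.18580
          3        1        0        0       1    0    2   0.02302

Posterior model-size distribution:
        0         1         2         3         4         5
1.858e-01 7.611e-01 5.185e-02 1.241e-03 1.260e-05 4.644e-08
```

Reading this: exercise is included in models carrying 80% of the posterior
mass (PIP 0.8011, "positive" evidence), its model-averaged effect is
+0.018 acuity units per weekly exercise day with SD 0.011, and its sign is
stable across models (0.9997).  The best single model contains exactly one
variable — exercise — with posterior probability 0.748, and the posterior
model-size distribution peaks at size 1.  The other four covariates have
PIPs near the s-fold-null baseline and grade "none".

The same analysis runs from a CSV
(`run_stage(run_config("data.csv", outcome = "acuity"))`), and
`run_three_stages(seed)` runs the primary/junior/senior presets in one call
on independent RNG streams.  `plot(fit)` draws the model-size distribution
and the signed inclusion map; `render_report(run_stage(...), dir)` writes
the variable table, top-model table, size distribution and inclusion map as
deterministic CSVs plus a JSON run manifest.

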