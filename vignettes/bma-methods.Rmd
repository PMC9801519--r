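---
title: "Model averaging for school-stage visual-acuity risk factors: methods"
author: "bmareg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model averaging for school-stage visual-acuity risk factors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmareg)
```

## The problem

Epidemiological studies of myopia risk factors in schoolchildren routinely
regress a continuous eyesight measure — here the right-eye record on the
Chinese 5-point logarithmic acuity chart, roughly 4.0–5.3 — on a handful of
candidate behavioural covariates: weekly exercise days (0–7), diet, school
bullying, mental-stress and internet-use questionnaire scores, or sleep
hours.  Conclusions drawn from one selected regression understate
uncertainty, because they condition on the selected model being the right
one.  Bayesian model averaging (BMA) treats the model itself as unknown:
every subset of the $s$ candidate covariates defines one linear model, each
model is weighted by its posterior probability, and all per-variable
conclusions are averaged over the full space of $2^s$ models.

## The model

For each subset model $M$ with $k$ included covariates,

$$y = \alpha + X_M \beta_M + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2 I),$$

with the intercept $\alpha$ in every model and never counted in the model
size.  The posterior over models follows from Bayes' theorem,
$P(M \mid y) \propto p(y \mid M)\,P(M)$, with a uniform prior over the $2^s$
models, and any quantity of interest is the posterior-probability-weighted
average of its per-model value.

**Coefficient prior.** Within a model we place a Zellner $g$-prior on the
slopes, $\beta_M \mid \sigma^2 \sim N(0,\, g\sigma^2 (X_M'X_M)^{-1})$, with
flat priors on $\alpha$ and $\log\sigma$.  This is the one conjugate family
that yields a closed-form marginal likelihood for every subset model; after
centering outcome and covariates,

$$\log p(y \mid M) = \text{const} +
  \tfrac{n-1-k}{2}\log(1+g) -
  \tfrac{n-1}{2}\log\!\bigl(1 + g(1 - R^2_M)\bigr),$$

where $R^2_M$ is the in-model coefficient of determination ($R^2 = 0$ for
the null model) and the constant
$\log\Gamma(\tfrac{n-1}{2}) - \tfrac{n-1}{2}\log\pi - \tfrac12\log n -
\tfrac{n-1}{2}\log \mathrm{TSS}$ is model-independent.  The test suite
verifies this closed form against direct two-dimensional quadrature of
likelihood $\times$ prior over $(\beta, \sigma^2)$ on small tables.

Conditional on a model, the slopes have a multivariate-$t$ posterior with
$n-1$ degrees of freedom, location $\tfrac{g}{1+g}\hat\beta_{\mathrm{OLS}}$
(the shrinkage identity, also tested directly against `lm()`), and scale
matrix $\tfrac{g}{1+g}(X'X)^{-1}\,\mathrm{TSS}\,(1 - \tfrac{g}{1+g}R^2)/(n-1)$.

**Choosing $g$.** The default is the unit-information prior $g = n$
(`g_rule = "uip"`), the default of the standard BMA software family for this
kind of analysis; `"bric"` ($g = \max(n, s^2)$) and fixed values are
available.  Large $g$ expresses a diffuse coefficient prior and pushes
posterior mass toward the null model on fixed data (the Lindley–Bartlett
effect, asserted as a monotonicity test over $g \in \{10^2, 10^4, 10^8\}$).

## Reported summaries

* **PIP** — posterior inclusion probability of covariate $j$: the summed
  posterior probability of all models containing $j$.
* **Post mean** — the model-averaged coefficient, with the coefficient
  exactly 0 in models that exclude the covariate.
* **Post SD** — by default the law-of-total-variance form
  $\sqrt{\sum_M P(M\mid y)\,(\mathrm{var}_M + \mathrm{mean}_M^2) -
  \text{post mean}^2}$.  Averaging only within-model variances (a form some
  reports use) omits the between-model dispersion of the conditional means
  and understates uncertainty; that literal form remains available via
  `variance = "within"` and is tested to coincide with the pmp-weighted
  conditional variances.
* **Sign consistency ("Sig.")** — the inclusion-weighted probability, under
  each conditional posterior $t$, that the coefficient's sign agrees with
  the model-averaged mean; a sign-robustness summary, defined as 1 for a
  never-included covariate.  This definition was fixed deliberately: the
  quantity is sometimes described only loosely in applied reports, and the
  inclusion-weighted tail probability is the one reading that is a proper
  probability, reproduces the preponderance of 1.0 values for stable
  covariates, and is computable from the conditional posteriors alone.
* **Evidence grades** — Raftery-style bands on the PIP with left-closed
  boundaries: $[0, 0.5)$ *none*, $[0.5, 0.75)$ *weak*, $[0.75, 0.95)$
  *positive*, $[0.95, 1]$ *strong*.  Applied write-ups occasionally label
  both upper bands "strong"; we keep the four original grades and fix the
  boundary convention explicitly because the strict/non-strict inequalities
  in prose descriptions overlap at the cut points.

## MC3 sampler

`mc3_run()` is Metropolis–Hastings model composition over the inclusion
hypercube: propose flipping one uniformly chosen inclusion bit, accept with
probability $\min(1, \mathrm{ML}(M')/\mathrm{ML}(M))$ computed in log space
(the uniform model prior and the symmetric proposal cancel).  Single-bit
flips are the simplest irreducible, aperiodic kernel and are adequate for
$s \le 25$; marginal likelihoods are memoized per inclusion pattern because
revisits dominate iteration cost.  Posterior model probabilities are
estimated by raw post-burn-in visit frequencies — the frequency-based
estimator that per-model report tables conventionally show next to the
exact column — so on an enumerable space the two columns should agree; the
suite requires total-variation distance $\le 0.01$ at the default 100,000
iterations with 10,000 burn-in.  The chain is byte-reproducible given its
seed, and acceptance depends only on log-marginal *differences*, which a
test asserts by shifting all log marginals by a constant.

## The synthetic generator

The real survey data are restricted, so the generator emulates their
published per-stage structure: stage sample sizes (8,457 primary; 8,191
junior; 5,901 senior), covariate means and SDs on their questionnaire
scales, and outcome means/SDs in acuity units.  Covariates are drawn
independently; the weekly-exercise item is drawn as
$\mathrm{round}(N(\mu, \sqrt{\sigma^2 - 1/12}))$ clipped to 0–7 — rounding
adds approximately $1/12$ of quantization variance, so the deflated latent
SD makes the realized SD match its target — and continuous scores are
normal draws truncated at zero (the truncation never binds at the shipped
means).  Outcomes follow the linear model with configurable true
coefficients and noise SD; `noise_sd = 0` is allowed as the exact
deterministic limit used by the coefficient-recovery test.  Intercepts are
set so the implied outcome means land near the published stage means given
the covariate means (marginal means are all the tables report).

Preset design choices:

* `junior_paper` / `senior_paper` copy the published single exercise effect
  (0.0177 and 0.0196 acuity units per exercise day) verbatim.  Note these
  are *weak* standardized effects at these sample sizes (expected inclusion
  $|t| \approx 2.7$), so single synthetic replicates legitimately fluctuate
  between a null and a one-variable best model; only qualitative patterns
  (exercise ranked first; one-variable best models when the effect is
  detected) are stable, which is why no test asserts the published PIP/PMP
  values.
* `primary_null` uses the primary-stage covariate panel with sleep in place
  of the mental-stress score (the depression questionnaire was not
  administered to pupils) and all true coefficients zero.
* `strong_single` is the parameter-recovery stress preset: one coefficient
  of 0.03 with noise SD 0.61 at $n = 8191$.  The effect is placed on the
  bullying-score scale (SD 1.35): a design-time power analysis shows the
  PIP $\ge 0.95$ recovery threshold needs expected inclusion
  $|t| \gtrsim 3.9$, and 0.03 on this scale gives $E|t| \approx 6$
  (per-replicate recovery probability $\approx 0.98$), whereas on the
  exercise scale (SD 1.01) the same coefficient gives $E|t| \approx 4.5$ —
  a borderline effect that would not deserve the name "strong".
* `pure_null` is the null-calibration preset: $n = 2000$, all coefficients
  zero.

What the generator does **not** emulate: the stratified cluster sampling
design (draws are i.i.d.; design effects are ignored), covariate
correlations (independence is the conservative default for selection
tests), item-level questionnaire structure, and any left/right-eye or
binary myopia outcome.  Passing tests therefore certify the inferential
machinery under the assumed linear model, not robustness to clustering or
correlated covariates in real survey data.

## Numerical and degenerate-input policy

All model-probability arithmetic is done in log space with a log-sum-exp
reduction (checked against a 50-decimal-digit high-precision normalization
on spreads of $\pm 700$ log units).  Outcome and covariates are centered
once, up front, so the intercept drops out of every per-model computation;
centering is idempotent and the raw means are kept so reports, `coef()` and
`predict()` work on the original scale.  Model enumeration order (by size,
then lexicographic) is the deterministic tie-break for equal posterior
probabilities.  Rows with missing values are dropped with a logged count;
zero-variance covariate columns are rejected by name rather than silently
dropped; collinear columns inside a candidate model raise an error naming
the model; `n \le s + 2` is rejected outright.  The enumeration cap is
$s \le 25$; beyond it only the sampler is available.

## Problem sizes used by the test suite

The suite exercises the full published sample sizes where a single run
suffices (one junior-scale table is fit in well under a second — 32 QR
decompositions on an $8191 \times 5$ matrix).  Replicated checks use the
sizes stated with each property: 25 replicates at $n = 8191$ for recovery,
200 replicates at $n = 2000$ for null calibration, 100 random small tables
for the shrinkage identity, $n \le 10$ tables for quadrature.  These sizes
were chosen as the smallest that make the binomial pass/fail thresholds
sharp, and they are the sizes the properties are stated at.

## Known limitations

Exact enumeration is exponential in $s$; the intended regime is the
survey's $s = 5$.  The g-prior family is the only coefficient prior
offered.  Outcomes are treated as continuous Gaussian — no ordinal or
logistic modelling of acuity categories or myopia status.  Survey weights
and cluster random effects are out of scope, so standard errors from real
multistage samples would be optimistic.
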