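---
title: "Methods: resampling inference and thermal performance curves in thermotol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampling inference and thermal performance curves in thermotol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotol)
```

## The scientific setting

Winter-acclimatized *Drosophila melanogaster* show dramatically shifted
thermal limits relative to flies reared under benign laboratory
conditions: much lower critical thermal minima (CTmin), lower critical
thermal maxima (CTmax) and shorter heat-knockdown times, together with
a cross-generational cost — eggs laid by winter-acclimatized females
develop poorly at high temperatures. `thermotol` implements the
statistical machinery used to quantify such cost–benefit patterns:

1. **Difference-in-medians randomization tests** for per-individual
   tolerance scores,
2. **percentile bootstrap confidence intervals** for group medians,
3. a **quasi-binomial cubic logistic model** of egg-to-adult viability
   across developmental temperatures, with overdispersion-corrected
   F-tests and benign-temperature standardization.

A set of calibrated synthetic-data generators reproduces the assay
designs these methods expect, so the full pipeline runs, and can be
validated, without access to field data.

## Why medians and randomization?

Scores from thermal assays (knockdown times, chill-coma recovery
times, coma-onset temperatures) are routinely non-normal, with group-
specific skew and unequal variances; transformations rarely fix all
groups at once, and rank tests also assume equal shapes. The package
therefore uses the difference of group medians,
\(Md = \tilde{x}_A - \tilde{x}_B\), as the test statistic and builds
its null distribution by re-partitioning the pooled scores into groups
of the original sizes.

Implementation choices, all surfaced in `randomization_test()`:

* **Two-tailed p by the absolute-value method**: the p-value counts
  null statistics with \(|T^*| \ge |T_{obs}|\) rather than doubling a
  one-tail probability. This is standard for randomization tests and
  requires no symmetry assumption.
* **Add-one Monte-Carlo correction**: with `n_perm` random partitions,
  \(p = (1 + \#\{|T^*| \ge |T_{obs}|\})/(n_{perm}+1)\). This keeps the
  test valid and p strictly positive; the smallest attainable p is
  \(1/(n_{perm}+1)\).
* **Exact small-sample path**: when the number of distinct partitions
  is at most `exact_threshold` (default \(10^5\)), all partitions are
  enumerated and \(p = \#\{|T^*| \ge |T_{obs}|\}/\#partitions\) is
  exact. The test suite checks this path against an independent
  brute-force oracle.
* **Ties**: \(|T^*| \ge |T_{obs}|\) uses exact floating-point
  comparison. With heavily tied data (e.g. vial proportions that are
  multiples of 1/20) many permutations tie with the observed statistic,
  which makes the test *conservative*, never anti-conservative. We do
  not add a tolerance band to the comparison.
* **Symmetry**: null partitions are drawn from the sorted pooled
  values with the smaller group size assigned first, so
  `randomization_test(a, b)` and `randomization_test(b, a)` under the
  same seed return the same p-value and negated Md.

Confidence intervals for single medians use the percentile bootstrap
(`bootstrap_median_ci()`, default 10,000 resamples): the interval is
the pair of \((\alpha/2, 1-\alpha/2)\) empirical quantiles of the
resampled medians. The percentile method is the simplest interval
consistent with resampling the median; BCa-type corrections are out of
scope. Simulation in the test suite shows 92–97% empirical coverage
for 95% intervals at \(n = 25\) under skewed (gamma) data.

## The viability model

Egg-to-adult viability across constant developmental temperatures is a
thermal performance curve. The observation unit is the **vial** (20
eggs each in the default design), not the individual egg: vials share
micro-environment and handling, which induces extra-binomial variation
among vials and is exactly what the quasi-binomial dispersion absorbs.

`fit_viability_curve()` models the emerged/not-emerged counts per vial
with a logit link and a cubic polynomial in standardized temperature,
optionally crossed with acclimation treatment:

\[
\operatorname{logit} p = \beta_0 + \beta_1 z + \beta_2 z^2 + \beta_3 z^3
 + \tau\,\mathbb{1}[\text{lab}] + (\gamma_1 z + \gamma_2 z^2 + \gamma_3 z^3)\,\mathbb{1}[\text{lab}]
\]

* **Standardized temperature**: \(z = (T - \bar{T})/s_T\), with mean
  and sd taken over the distinct design temperatures. Raw powers of
  degrees Celsius (e.g. \(33^3 = 35937\)) make the IRLS normal
  equations ill-conditioned; centering and scaling fixes that without
  changing fits, deviances or F-tests. Coefficients are reported on
  both scales (`coefficients`, `coefficients_raw`).
* **Raw polynomial basis** rather than orthogonal polynomials: basis
  choice cannot change any reported test (deviance is basis-invariant),
  and raw powers keep the coefficient table interpretable.
* **Estimation** is binomial IRLS (`stats::glm`), declared converged
  when the relative deviance change falls below \(10^{-10}\) within
  100 iterations; non-convergence and separation (fitted probabilities
  collapsing to 0/1 with diverging coefficients) raise classed errors.
  The test suite verifies the coefficients against an independent
  Newton–Raphson maximizer of the binomial log-likelihood to \(10^{-6}\).
* **Overdispersion**: \(\hat\varphi = \chi^2_{Pearson}/\text{df}_{resid}\).
  The quasi-binomial treatment multiplies standard errors by
  \(\sqrt{\hat\varphi}\) and enters F-tests, but leaves point estimates
  identical to the plain binomial fit (checked bit-for-bit in the
  tests).

Nested models are compared with `f_test_nested()`:
\(F = [(D_{reduced} - D_{full})/\text{df}_{num}] / \hat\varphi_{full}\)
on \((\text{df}_{num}, \text{df}_{resid,full})\) degrees of freedom,
with the dispersion always estimated from the larger model. On the
default design (2 treatments × 10 temperatures × 20 vials) the
interaction test has numerator df 3 and denominator df 392.

**Benign-temperature standardization.** A lower overall viability in
one treatment can masquerade as a curve-shape interaction. To compare
shapes, `standardize_viability()` divides each vial's proportion by
its treatment's mean proportion over the benign temperatures (20 and
25 °C): within each treatment the standardized benign vials average
exactly 1. Standardized values are no longer counts, so logistic
regression does not apply to them; instead
`per_temperature_tests()` runs the median randomization test between
treatments at every non-benign temperature on the vial-level relative
viabilities. P-values are reported unadjusted, as such per-temperature
tables conventionally are; a Holm-adjusted column is available via
`holm = TRUE` but defaults off.

## What the synthetic generators emulate

### Tolerance scores

`simulate_tolerance()` draws each group from a location-shifted gamma
family: for skewness \(g \ne 0\), shape \(k = (2/|g|)^2\) and scale
\(\theta = s/\sqrt{k}\) give a gamma with sd \(s\) and skewness
\(|g|\); the draw is re-centered by the gamma's median (and
sign-flipped for \(g < 0\)) so the *theoretical median equals the
target exactly*. \(g = 0\) falls back to a normal, and spread 0 to the
degenerate constant — useful in tests.

The shipped defaults (`default_tolerance_specs()`) pin the group
medians to the published ramping-assay values (e.g. cold-ramp CTmin
0.62 °C field females vs 6.19 °C laboratory females, so
Md = 5.57 °C) and to the published differences for the time-based
assays. Two published quantities are not recoverable from print alone
and were fixed once at field-realistic values: the absolute knockdown
level of field females (40 min at 37 °C) and the absolute 2 h
chill-coma recovery level (25 min). The printed chill-coma values are
mutually inconsistent by 0.02 min (the four printed differences
over-determine the four medians), so the laboratory male median honours
the treatment-difference and field-sex-difference values exactly and
lets the laboratory sex difference come out at −0.67 rather than
−0.65 min. Spreads and skews are unpublished free parameters; they
were chosen once, by power reasoning before any end-to-end run, so
that the large published effects (ramping assays, knockdown) are
detected essentially always at \(n = 25\) while the small chill-coma
differences (≈2 min against an 18 min spread) stay non-significant in
most runs — mirroring the published significance pattern.

### Viability vials

`simulate_viability()` draws beta-binomial counts around each
treatment's cubic-logistic curve: vial-level success probabilities
\(\sim \text{Beta}(p(1-\rho)/\rho,\,(1-p)(1-\rho)/\rho)\), so the count
variance is inflated by \(1 + (m-1)\rho\) and \(\rho = 0\) reduces
*exactly* to binomial sampling. The closed-form variance makes the
generator testable against an analytic oracle; a logit-normal mixture
would not offer that.

The default curves were calibrated as follows. The laboratory curve is
a least-squares cubic through a realistic unimodal viability profile
(≈0.90 at 20–25 °C, falling to ≈0.45 at 11 °C and ≈0.20 at 33 °C). The
field curve's four logit-scale coefficients were then optimized so
that, *after* benign standardization, the field deficit is as close to
zero as possible at 11–17 °C while large (0.2–0.5 standardized units)
at 27–31 °C. Default \(\rho = 0.05\) gives a dispersion factor of
\(\approx 1.95\) at 20 eggs — clearly detectable overdispersion.

One limitation is mathematically forced and worth understanding: two
cubics that agree at four or more points are identical, so the field
curve cannot match the laboratory curve at 11, 14, 17, 32 **and**
33 °C yet differ at 27–31 °C. The calibration spends the cubic's
freedom on the low-temperature side (where the published pattern shows
agreement); the synthetic field curve therefore keeps a substantial
standardized deficit at 32–33 °C, and per-temperature tests there are
nearly always significant on synthetic data, unlike the published
real-data table. Qualitative-pattern checks in the test suite
accordingly target agreement at 11–17 °C and divergence at 27–31 °C.

### Temperature logs

`simulate_temperature_log()` produces half-hourly traces for an air
sensor and two heap sensors. Air follows a sinusoidal daily cycle
(default mean 2 °C, amplitude 4 °C — Danish early-winter values);
heap sensors add a fermentation offset (default 8 °C) and damp the
daily amplitude (default 0.35 at the top sensor, 0.10 at the bottom,
reflecting thermal buffering with depth). Gaussian noise (0.3 °C) is
added and readings are quantized to 0.1 °C *after* noise, as a logger
would record them. `summarize_microclimate()` computes per-sensor
means, mean daily ranges and heap-minus-air offsets over whole days
only.

### What passing tests do and do not show

The generators reproduce the *statistical structure* the analysis
assumes — skewed heteroscedastic scores with controlled medians,
overdispersed grouped counts on a smooth curve, buffered periodic
microclimate — but not biology: no fly age, parasite load, diet or
diapause state, no correlation between assays, no vial-position or
batch effects, and vial counts are exchangeable within temperature.
Green tests therefore validate the inference machinery and the
pipeline plumbing under the stated model, not the field conclusions
themselves.

## Determinism and seeds

Every stochastic stage takes an explicit seed and restores the
caller's RNG state. Pipeline runs derive per-stage seeds from the
master seed via a stable 31-bit polynomial hash of a stage label
(`derive_seed()`), so results are independent of stage execution order
and a configuration determines its report byte-for-byte. Identical
`(spec, seed)` pairs produce byte-identical CSVs.

## Problem sizes and budgets

Defaults match the study design: \(n = 25\) flies per group, 100,000
permutations per test, 10,000 bootstrap resamples, 20 vials × 20 eggs ×
10 temperatures × 2 treatments. `analysis_config(fast = TRUE)` drops
the budgets to 5,000/1,000 for smoke runs. The simulation-based checks
in the test suite use scaled-down designs chosen by Monte-Carlo-error
reasoning (e.g. 1,000 replicate null tests at 5,000 permutations for
the type-I error check; 500 replicates at 2,000 resamples for bootstrap
coverage; 50 end-to-end seeded runs at 2,000 permutations for the
pattern checks), sizes at which the quantities of interest are
estimated to within a few percent.

## Known limitations

* The percentile bootstrap for a median at \(n = 25\) relies on the
  discrete resampled-median distribution; coverage is nominal-ish but
  not exact, and BCa/Studentized intervals are not implemented.
* The permutation test assumes exchangeability under the null; with
  very unequal group shapes it tests a broader null than a pure
  location shift.
* `fit_viability_curve()` offers only the cubic-logistic family — no
  Gaussian, Weibull or Sharpe–Schoolfield thermal performance forms,
  and no random-effect (GLMM) treatment of vials.
* Per-temperature tests are reported unadjusted by default; with eight
  temperatures, occasional isolated false positives at null
  temperatures are expected at \(\alpha = 0.05\).
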