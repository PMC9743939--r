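---
title: "Methods: wearable-specific indicators of physical activity behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable-specific indicators of physical activity behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wipab)
```

## Scope and data model

`wipab` computes *wearable-specific indicators of physical activity
behaviour* (WIPAB) from epoch-level wrist acceleration and relates them to
glycaemic outcomes. The pipeline starts at calibrated 5-second ENMO epochs
(Euclidean Norm Minus One, in milli-*g*); raw 30 Hz signal handling,
autocalibration and full z-angle sleep algorithms are out of scope. The
stages are:

1. **Screening** — the first and last half-days of wear are trimmed to
   whole midnight-to-midnight days, at most six days retained. A day is
   *valid* with at least 10 h of wear; a participant is *included* with at
   least four valid days, at least one of them a Saturday or Sunday, and a
   post-calibration error of at most 10 milli-*g*.
2. **Sleep masking** — one main sleep window per noon-to-noon period is
   removed from behaviour analysis; daytime naps (windows starting between
   10:00 and 18:00) are kept as analysable time.
3. **Intensity classification** — wrist ENMO cut-points 44.8 and
   100.6 milli-*g* separate sedentary behaviour (SB), light activity (LPA)
   and moderate-to-vigorous activity (MVPA). The boundary convention is
   lower-bound inclusive on the upper class (an epoch exactly at a
   cut-point takes the higher intensity); the sources defining the
   cut-points do not fix this, so it is stated here once.
4. **Bouts** — maximal runs of identical non-sleep labels. The default is
   a strict (100 %) run-length criterion; a tolerance-based mode (fraction
   of in-intensity epochs, maximum single gap) is exposed because tolerant
   bouting is common in accelerometry pipelines but its parameters vary
   between studies. Sleep always splits a run.
5. **Features** — three conventional variables (daily SB hours, daily MVPA
   hours, 24-h average acceleration) and the WIPAB metrics described
   below.
6. **Association models** — per exposure and outcome (insulin sensitivity
   via the QUICKI index, HbA1c): an unadjusted model, a model adjusted for
   age and sex, and a model further adjusted for income, education,
   alcohol, smoking, total sleep duration, depression and BMI; chained-
   equation multiple imputation with Rubin pooling; the fully adjusted
   model optionally stratified by sex.

## The metrics

**Intensity gradient.** Time is histogrammed in 25 milli-*g* bins (0–25,
…, 3975–4000, >4000) in minutes/day averaged over valid days; the gradient
is the OLS slope of `ln(minutes)` on `ln(bin midpoint)` over non-empty
bins. Natural logarithms are used, bin midpoints serve as the abscissa,
and the open-ended top bin is dropped (no finite midpoint). The histogram
covers the full 24 h including sleep by default (`awake_only` switches).

**MX metrics.** The acceleration above which the most active *x* of the
day is accumulated: per day the k-th largest epoch ENMO with
`k = x / epoch_len`, averaged over valid days (per-day-then-average, not
pooled epochs). Defaults follow the 8-h (M8) and 15-min (M0.25) windows.

**Accumulation metrics** (bouts pooled over awake time of all valid days):
the power-law exponent of bout durations by the continuous maximum-
likelihood estimator `alpha = 1 + n / sum(ln(x/xmin))` with `xmin` the
shortest observed bout — the MLE is preferred over log–log regression for
its lower bias — reported as missing unless at least three distinct
durations exist; the proportion of time in bouts strictly longer than
60 min (SB) or 10 min (MVPA); and the Gini index of SB bout lengths,
`G = sum |xi − xj| / (2 n² x̄)` without small-sample correction, matching
the convention of the standard inequality-index implementation.

**Detrended fluctuation analysis.** DFA-1: the mean-removed series is
integrated, split into non-overlapping windows per scale, linearly
detrended, and the RMS fluctuation regressed on scale in log–log space.
One hundred candidate scales are log-spaced over 5–360 min and snapped to
whole epochs (duplicates removed); the short band covers 5–90 min, the
long band 120–360 min, omitting the transitional region. Non-overlapping
windows were chosen over sliding windows for speed and independence of
window residuals; the calibration tests (white noise ≈ 0.5, integrated
noise ≈ 1.5, pink noise ≈ 1.0) pin the behaviour down regardless.

**24-h autocorrelation.** The standard biased-normalised estimator (as in
`stats::acf`). Note a structural property: with `d` days of data the
coefficient at a 24-h lag cannot exceed `(d − 1)/d` even for perfectly
periodic activity, because the biased convention divides by the full-series
variance. Values should be compared between participants with equal wear
length.

**Lempel–Ziv complexity.** Awake epochs are reduced to a PA-state sequence
(intensity × bout-duration class) and parsed with the LZ76 scheme; the
phrase count is normalised as `c(n) · log_alpha(n) / n` so the measure is
length-independent. The published state table this package's default
alphabet stands in for was not available; the default is a *synthetic
reconstruction* — SB in three duration classes (<10, 10–30, ≥30 min), LPA
and MVPA in two each (<10, ≥10 min), seven states — and any user-supplied
map (`state_alphabet()` format) may replace it.

**Sample entropy.** `−ln(A/B)` with template length `m = 2`, tolerance
`r = 0.2` on the series standardised to zero mean and unit variance (so
the tolerance is exactly 0.2 SD), Chebyshev distance, self-matches
excluded; computed on the awake ENMO sequence. Raw sample entropy is
non-negative by construction; descriptive statistics reported elsewhere on
a transformed scale cannot be reproduced from the definition, and this
package deliberately returns the raw value.

**Symbolic dynamics.** The awake series is clipped to mean ± 3 SD,
quantised into six equal-width symbols (left-closed bins, top bin closed),
and overlapping length-3 windows are classified into the four variation
families (0V, 1V, 2LV, 2UV); the reported feature is the percentage of 2UV
windows (one rise and one fall), the most complex family. Only one family
is reported because the four shares are compositional.

## Outcomes and models

QUICKI is `1 / (log10(insulin) + log10(glucose))` with insulin in µU/mL
and glucose in mg/dL (decadic logarithms, per the index's original
definition). Exposures are rescaled before model fitting (divided by 10:
SB hours, average acceleration, M8, M0.25; by 100: MVPA power-law
exponent, sample entropy) so coefficients land on readable scales;
`feature_scaling()` is the single source of truth for these divisors.
Models are Gaussian identity-link GLMs; reference categories are
never-smoker, non-drinker and female (configurable by releveling). No
multiple-testing correction is applied, mirroring the single-exposure-at-
a-time design; interpret families of models accordingly.

**Imputation.** `impute_chained()` implements multiple imputation by
chained equations: for each of *m* streams, missing entries are
initialised from observed values and updated over iterative sweeps, each
incomplete variable regressed on its predictor set in the current
completed data. Numeric variables use type-1 predictive mean matching
(five donors, Bayesian parameter draw); `method = "norm"` switches to
Bayesian normal draws. Logical variables use logistic draws; categorical
variables multinomial draws from fitted class probabilities. Predictors
are selected quickpred-style — absolute pairwise correlation of at least
0.1 with the target or its missingness indicator — with the analysis
outcomes always retained. Defaults are 30 datasets and 20 iterations.
Pooling follows Rubin's rules with Barnard–Rubin degrees of freedom;
`pool_rubin()` reproduces the closed form (estimates {1, 3}, variances
{1, 1} give a pooled estimate of 2 and total variance 4) and collapses to
the single-dataset analysis when the between-imputation variance is zero.

## The synthetic cohort

No public accession exists for the kind of cohort this pipeline targets,
so `generate_epoch_series()` and `generate_cohort()` provide planted-truth
data for every test.

The signal generator lays out whole days of 5-s epochs with a nightly
sleep window (default 23:00–07:00, near-zero activity), and fills waking
time with bouts whose intensities follow configurable transition weights
and whose lengths follow per-intensity distributions (power law,
log-normal or fixed). Consecutive bouts never repeat an intensity, so
planted bout boundaries are exactly recoverable; the recorded truth is the
realized maximal-run sequence, which is what any bout detector can be
asked to reproduce. Noise (white, AR(1) or spectrally synthesised 1/f
pink) is added on top and the series floored at zero; pink noise uses
1/f amplitude shaping of white noise, which is simple and sufficient for
DFA calibration. Defaults were calibrated once against the adult
general-population profile the package targets — about 12 h/day sedentary,
1.2–1.5 h/day MVPA, 24-h average acceleration near 25 milli-*g*, an SB
bout power-law exponent near 2.4 and an 8-h night — and are not tuned
thereafter.

What the generator does *not* emulate: non-wear episodes, device idle
modes, raw-signal artefacts, within-day circadian modulation of intensity
levels beyond the sleep window, or the heavy real-data spread of epoch
ENMO within a behavioural state. Consequently some distribution-shape
features of real cohorts (e.g. the share of SB time in >60-min bouts, or
M8 magnitudes driven by within-state spread) are not matched numerically —
passing tests demonstrate correctness of the computations and recovery of
planted truth, not population realism of every marginal.

The cohort generator draws covariates from population-plausible marginals
(age 25–79, 55 % women, BMI around 25 kg/m², CES-D depression prevalence
about 21 %) and builds outcomes as linear functions of the *scaled*
features plus Gaussian noise, per a user-supplied effect map, so that
recovery tests compare like with like. Fasting glucose is drawn around
95 mg/dL and insulin back-computed so `quicki()` reproduces the generated
index exactly. Missingness is inserted completely at random (MCAR);
assuming-missing-at-random machinery is thereby exercised without
constructing an MNAR mechanism. Because a replicate study at cohort scale
cannot regenerate thousands of six-day epoch series, `generate_cohort()`
has two modes: `"signal"` (full epoch series per participant, features
extracted by the pipeline) for end-to-end runs on small n, and
`"parametric"` (features drawn directly from cohort-calibrated marginals)
for large replicate experiments such as confidence-interval coverage.

## Numerical choices and degenerate inputs

* DFA needs at least twice the largest scale; otherwise the long band is
  reported missing while the short band is computed when feasible.
* The intensity gradient is missing (with a log message) below two
  non-empty finite bins; the autocorrelation is missing for constant
  series; sample entropy is missing when no extended template matches
  (infinite entropy) and 0 for constant series.
* The sleep detector thresholds at the day's 10th percentile of 5-min
  rolling means plus a 5 milli-*g* margin, capped at 20 milli-*g* so a
  uniformly active day yields "no sleep found" (with a warning) rather
  than spurious sleep; candidate windows must last 30 min inside a
  21:00–11:00 search window. Ground-truth windows can be injected for
  sensitivity analyses.
* Symbol quantisation uses left-closed equal-width bins with a closed top
  bin; values beyond mean ± 3 SD are clipped into the end bins.
* Bout durations enter the accumulation metrics pooled across all valid
  days (not per-day-then-averaged): bout distributions are heavy-tailed
  and day-level averages of tail statistics are badly behaved at six days.

## Problem sizes in the test suite

The suite exercises DFA calibration on twenty six-day series (103 680
epochs each), oracle equivalence on fifty random series up to length 200,
and confidence-interval coverage on 500 parametric replicate cohorts of
n = 300 with five imputations and five sweeps each. Five hundred
replicates estimate the coverage rate with about one point of Monte Carlo
error; the pipeline's end-to-end signal mode is run on ten four-day
participants. With covariate-side MCAR missingness the unadjusted model's
pooled interval is exactly the complete-data t-interval (between-
imputation variance zero), which is the configuration whose nominal 95 %
coverage the suite checks; with outcome-side missingness and a rich
predictor set, Rubin intervals are expected to be mildly conservative
(the classic uncongeniality effect), which is a property of the method,
not a defect of the implementation.

## Known limitations

* The sleep detector is a deliberately simple heuristic stand-in for
  z-angle-based algorithms; it assumes a single consolidated night.
* The default PA-state alphabet is a reconstruction (see above); LZC
  values depend on the alphabet and should not be compared across
  different state maps.
* MCAR-only missingness in the generator; the imputation engine itself
  does not require MCAR, but MNAR behaviour is untested.
* The 24-h autocorrelation's (d−1)/d ceiling (above) makes it sensitive
  to wear length.
* Multinomial imputation draws from fitted class probabilities without a
  posterior draw of the coefficients, which slightly understates
  categorical imputation uncertainty.
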