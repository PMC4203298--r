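---
title: "Methods: measuring observer-aging effects in long-term bird surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring observer-aging effects in long-term bird surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(obsaging)
```

## The problem

Long-term volunteer surveys confound two slow processes: change in bird
populations and change in the observers counting them. Age-related hearing
loss grows roughly quadratically past age 18, fastest above 6 kHz and, for
noise-induced loss, in a 3–6 kHz "notch"; men lose high frequencies faster
than women. Since most detections in roadside and atlas surveys are aural,
species with high-pitched or single-pitch songs should become progressively
harder to detect for a fixed, aging observer — a bias that standard trend
models (which at most correct a first-year start-up effect) do not remove.

`obsaging` implements the analysis chain for measuring this effect and its
consequences, with a simulation layer that makes every stage testable
against known truth.

## The occupancy/detection model

For one species, atlas squares `i` are sampling units and survey years are
replicate visits. The model has two parts:

* occupancy: `z_i ~ Bernoulli(ψ_i)`, `logit(ψ_i) = α0 + α1·firstAtlas_i`,
  where `firstAtlas` records detection in the previous atlas period —
  occupancy is assumed closed within the 5-year atlas window;
* detection, conditional on occupancy:
  `y_ik ~ Bernoulli(z_i · p_ik)`,
  `logit(p_ik) = β0 + β1·effort_ik + β2·I(over50_ik) + β3·I(male_ik)`.

`β2` is the old-vs-young detection contrast on the logit scale. Mid-aged
(40–50) observers are excluded from the primary fit to keep the cohorts
cleanly separated; the sensitivity refit (`sensitivity_refit()`) instead
pools them into the "young" class while keeping the age-50 cutoff. In a
world where detection declines monotonically with age, this dilution must
shrink `|β2|` — the package verifies that direction on simulations.

Numerical choices:

* the latent `z_i` is marginalized exactly (a square with a detection
  contributes `ψ_i · ∏ Bern(y|p)`; an all-zero square adds `(1-ψ_i)`), so
  the sampler works on a 6-parameter posterior with no augmentation and the
  likelihood can be checked against brute-force enumeration (the test suite
  does, to 1e-10);
* priors are independent Normal(0, 10) — "minimally informative" made
  concrete, with the scale configurable;
* sampling is adaptive Metropolis-within-Gibbs (compiled), 3 chains x
  20,000 iterations with half burn-in by default; proposal scales adapt
  only during burn-in, targeting ~44% acceptance. Convergence is judged by
  split-R̂ ≤ 1.1 per coefficient (plus Geyer effective sizes); failing fits
  are flagged loudly and `extract_beta2()` refuses them unless overridden;
* effort enters linearly on the logit scale after standardization
  (log-effort is available behind a flag); this only reparameterizes
  `β0`/`β1` and leaves `β2` untouched;
* a species must have ≥ 100 detection records to be fitted (override
  available), and squares need ≥ 2 visit-years.

A species "declines" when the 95% credible interval of `β2` lies below
zero. The posterior variance of `β2` is exported as the inverse-variance
weight for the downstream regressions.

## Vocalization classification

Peak (dominant) frequency is the argmax of a Welch-averaged power spectrum
(Hann window, 50% overlap, FFT size 4096 by default; ties break to the
lowest frequency). Peaks are binned with half-open thresholds at 3, 6 and
7 kHz: low (< 3), notch (3–6, the noise-induced-loss band), medium (6–7),
high (≥ 7).

The monotone/heterogeneous split takes each species' spectrum SD and labels
it monotone when the SD is at or below the median of the whole supplied
cohort. Two statistics are offered:

* `spectrum_sd(..., db_scale = FALSE)` — SD of linear power after
  normalizing each spectrum to unit total power (amplitude-invariant, with
  clean closed forms: a flat spectrum gives 0, a single hot bin among `n`
  gives `1/sqrt(n)`);
* `db_scale = TRUE` — SD of relative power in dB (floored at −120 dB).

`classify_species_set()` defaults to the **dB** statistic. The reason is a
genuine direction ambiguity: on linear power a narrowband song concentrates
everything in one bin and therefore *maximizes* the SD, so the
at-or-below-median rule would label pure tones heterogeneous — the opposite
of what "monotone" means. On the dB scale a narrowband song leaves most
bins near the noise floor (small SD) while multi-note songs elevate many
bins across the dynamic range (large SD), so the median rule selects
single-pitch songs as monotone, and wide-band noisy songs come out
heterogeneous — the conservative direction, since downstream inference
leans on the monotone groups. Multiple recordings per species are averaged
as unit-normalized spectra before the peak/SD are taken.

Synthetic vocalizations (`synthesize_vocalization()`) are stacks of
optionally swept sinusoids plus a white noise floor — enough structure to
exercise peak detection, bandwidth classification, and WAV round-tripping,
but deliberately not a model of real birdsong (no syllable timing, no
harmonic rolloff, no recording artifacts). A green classification test
establishes the estimator and the binning rules, not field performance on
noisy recordings.

## BBS count pipeline

Counts are prepared in a fixed order, each step auditable via the
`FilterReport`:

1. zero-fill: every surveyed (observer, route, year) gains explicit zero
   counts for listed species it did not report. Zeros are added **before**
   filtering; the test suite documents on a fixture that reversing the
   order changes what survives (a sparsely reported species can be dropped
   by the 3-observer rule and only resurrected as zeros);
2. minimum observer age = `year − first_service_year + 1` (first year of
   service = age 1), with first service taken from the complete historical
   record, which may begin before the analysis window;
3. filters, in order: single-observer/weather flags; each observer-route's
   first calendar year (start-up effect); only observer-route runs of ≥ 10
   *consecutive* surveyed years (a gap resets the run); ≥ 3 distinct
   observers per species-stratum; and the confounding guard
   |Pearson r(pooled age, year)| ≤ 0.7 per species-stratum. A stratum where
   age and calendar year move in lockstep cannot separate detection decline
   from population change and never reaches the model.

The per-species model is an overdispersed Poisson GAMM fitted with mgcv
(the canonical implementation of penalized regression splines with
mixed-model smoothness selection):
`log μ = intercept + f_age(age) + Σ_s f_s(year)·I(stratum s) + u_observer`,
cubic regression splines with basis size 10 (shrunk to the data when
needed), observer intercepts as a ridge-penalized random-effect smooth,
REML smoothness selection, quasi-Poisson dispersion estimated by Pearson
χ²/df. The age-smooth p-value is the usual Wald test on penalized
coefficients with effective degrees of freedom — approximate by
construction, as such p-values are. Degenerate designs are handled
explicitly (single year → year smooths dropped; single observer → random
intercept dropped; < 30 records → refusal). At infinite smoothing the age
smooth collapses to its linear null space and the fit matches an
unpenalized Poisson GLM — the test suite asserts this to 1e-6.

Proportional age-effect curves are `exp(f_age(a) − f_age(1))` — exactly 1
at age 1 — with pointwise 95% bands from the smooth's standard errors on
the log scale (the covariance with the age-1 anchor is ignored, standard
practice for pointwise bands). Group curves pool the per-species normalized
predictions (species weighted equally, literally "pooled predictions"
rather than a joint refit of raw counts) and pass them through a
second-stage spline on the log scale, renormalized at age 1.

## Linkage to frequency and published trends

Per-species `β2` estimates are regressed on peak frequency with thin-plate
spline smooths, separately for monotone and heterogeneous species, weighted
by inverse posterior variance; the model intercept estimates the central
tendency of the contrasts. A post-hoc inverse-variance-weighted *linear*
model is fitted to monotone species at ≥ 6 kHz — the band where age-related
loss accelerates — and its two-sided slope p-value is the headline
hearing-loss test. Published population trends enter as exogenous inputs
with source-specific weights (inverse 95%-interval width, or route counts),
normalized to mean 1 (fits are scale-invariant in the weights, which the
tests assert). Trend-vs-`β2` association uses unweighted Pearson
correlations with the exact t-transform p-value and a leave-one-out table,
the instrument for spotting single influential species. Both trend sources
are correlated separately (two reported r values) rather than only against
their mean. Significance is 0.05 two-sided throughout, with **no**
multiple-testing correction — a deliberate mirror of how such results are
conventionally reported, to be kept in mind when reading many p-values.

## The synthetic world

The simulators' defaults state one concrete world rather than a tunable
benchmark:

* atlas: 400 squares, 5 replicate years, `β2 = −0.66` (a negative contrast
  of the size typically at issue), male effect +0.17, occupancy raised by
  first-atlas detection, log-normal effort centred near 30 party-hours
  (surveys mandate ≥ 20), a male-skewed observer pool (70%) split
  25/35/40% across young/mid/old cohorts;
* BBS: routes nested in strata, consecutive observer tenures laid down
  from 15 years before the analysis window (ages are computed from the
  full history, which also decorrelates age from calendar year across
  routes — without this, age and year would be perfectly collinear and the
  0.7 guard would correctly discard everything), observer intercepts with
  SD 0.3, overdispersion 1.5 implemented as gamma mean-1 multiplicative
  noise calibrated so Var = φ·mean exactly, and a default smooth log-scale
  decline reaching 50% by observer age 39 (mid-range of the group declines
  the method is designed to detect);
* the hearing-shift helper uses a per-sex quadratic `a·(age−18)²` per test
  frequency with built-in approximate coefficients (the audiometric
  standard's exact constants are not reproduced; the table is overridable
  and is used only to parameterize simulations);
* where the data-generating scale of a parameter was not dictated by the
  analyses (effort coefficient, observer-intercept SD), values were chosen
  once at realistic magnitudes and are documented in the config defaults,
  not asserted as facts about any real survey.

What the generators deliberately omit: spatial structure beyond
stratum/route labels, observer demographics, multi-observer squares (one
observer per square-year; one per route tenure), false-positive
detections, and real acoustics. Green tests therefore establish that the
*estimators and rules* behave as specified on data with the assumed
statistical structure — not that any particular real dataset satisfies
those assumptions.

## Design decisions taken where the design was open

* "Surveyed continuously for 10 years" reads as ≥ 10 consecutive calendar
  years with no gap; a gap resets the run and only years inside a
  qualifying run are kept.
* The first-year exclusion is per observer-route combination (its natural
  reading), using the earliest year present in the analysis records.
* The age convention `year − first + 1` anchors the first year of service
  at age 1, matching curves normalized to "the first year".
* Mid-aged visits are dropped by row (not by observer) in the primary fit;
  squares falling below 2 visit-years are then dropped.
* Per-stage seeds derive from the master seed by a string hash of the
  stage name, so any stage can be rerun in isolation, bit-reproducibly.
* Peak-frequency ties break to the lowest frequency: deterministic, and
  conservative toward frequencies observers hear better.

## Known limitations

* The occupancy sampler is a random-walk scheme on 6 parameters; it is
  verified against enumeration and ML reductions, but for models extended
  with many more covariates a gradient-based sampler would be preferable.
* GAMM p-values are approximate; the package reports them as such and the
  type-I-error simulation in the test suite checks calibration only at the
  stated world's sample sizes.
* Minimum observer age is a proxy for true age: an observer may join the
  survey at any age, so the simulated link between service years and
  hearing loss is cleaner than reality's.
* The linkage stage treats published trends as error-free beyond their
  weights; no errors-in-variables correction is attempted.
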