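# obsaging

Observer-aging effects in long-term bird survey data.

Volunteer bird surveys — breeding-bird atlases and the North American
Breeding Bird Survey (BBS) — reuse the same observers for decades. As
observers age their hearing degrades, fastest at high frequencies (and, for
noise-induced loss, in the 3–6 kHz "notch"), so species with high-pitched or
single-pitch songs slowly become harder to *detect* even when their
populations are stable. Left uncorrected, that detection drift leaks into
population trend estimates. `obsaging` implements the full analysis chain
for quantifying this effect, exercised end to end on synthetic data with
known truth, for ecologists and biostatisticians working with
detection/nondetection or count survey data.

## What it computes

**Occupancy/detection model (atlas data).** Per species, a two-part
hierarchical model: square-level occupancy
`logit(ψ_i) = α0 + α1·firstAtlas_i`, visit-level detection conditional on
occupancy `logit(p_ik) = β0 + β1·effort + β2·I(over 50) + β3·I(male)`.
The latent occupancy state is marginalized exactly, and the posterior is
sampled by adaptive Metropolis-within-Gibbs (Rcpp). **β2** is the quantity
of interest: the logit-scale detection difference between observers over 50
and under 40; negative means older observers detect less. A sensitivity
refit moves mid-aged (40–50) observers into the "young" class.

**Vocalization classification.** Welch-averaged power spectra of (synthetic
or WAV) recordings give each species a peak (dominant) frequency, binned at
3/6/7 kHz into low / notch / medium / high, crossed with a
monotone/heterogeneous split at the cohort-median spectrum SD — eight groups
in all.

**BBS count pipeline.** Zero-filling of unreported species, minimum observer
age (years since first service, first year = 1), exclusion filters
(single-observer/weather flags, first-year effect, ≥10 consecutive years,
≥3 observers per stratum, |r(age, year)| ≤ 0.7), then per-species
overdispersed Poisson GAMMs (mgcv):
`log μ = f_age(age) + Σ_s f_s(year) + u_observer`, pooled into per-group
proportional-change curves normalized to 1 at age 1.

**Linkage.** Inverse-variance-weighted spline fits of β2 against peak
frequency, a post-hoc weighted linear model for monotone species ≥ 6 kHz,
weighted smooths of published population trends against frequency, and
Pearson correlations (with leave-one-out) between β2 and trends.

## Worked example

```r
library(obsaging)

# A 400-square atlas world where older observers lose 1 logit of detection
sim <- simulate_atlas(atlas_sim_config(n_squares = 400, years = 2001:2004,
                                       beta2 = -1.0, seed = 11))
fit <- fit_occupancy_mcmc(sim$detections,
                          occu_model_spec(n_iter = 6000, n_chains = 3,
                                          seed = 5))
fit$summary[fit$summary$coefficient == "beta2", ]
#>   coefficient       mean        sd      q2.5      q97.5     rhat  ess
#> 5       beta2 -0.8738046 0.1744116 -1.228906 -0.5435135 1.005441 430
extract_beta2(fit)$significant_negative
#> [1] TRUE
```

The posterior mean recovers the simulated contrast (−0.87, truth −1.0) and
the 95% credible interval excludes zero, so this species would be flagged as
showing an age-related detection decline.

The whole pipeline (simulate → classify → occupancy → BBS GAMMs → linkage)
runs from one config:

```r
m <- run_all(run_config(seed = 2, out_dir = "demo_run"))
read.csv("demo_run/linkage_summary.csv")
#>        quantity        value
#> 1 posthoc_slope -0.870344416
#> 2     posthoc_p  0.007244360
#> 3   pearson_r_a  0.990431329
#> 4   pearson_p_a  0.009568671
```

In the demo world only monotone species at ≥ 6 kHz carry true detection
loss; the post-hoc model recovers the negative slope of detection decline
with song pitch (p ≈ 0.007), and estimated declines correlate strongly with
the synthetic published trends. A CLI wrapper is in
`inst/cli/observer-drift` (`observer-drift run-all --seed 2 --out demo_run`).

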