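---
title: "Methods: personalized relapse monitoring from actigraphy and weekly self-reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized relapse monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nof1relapse)
```

## The problem and the modeling stance

Relapse in recurrent major depressive disorder is rare at the visit level,
heterogeneous across patients, and fast relative to the usual bimonthly
clinic schedule. Pooled classifiers struggle with both the class imbalance
and the inter-individual variability of activity patterns. This package
takes the N-of-1 route instead: each patient's own relapse-free history
defines their "normal", a personalized model scores departures from it, and
a departure only becomes a relapse flag when the patient's concurrent
self-reports corroborate it. The pipeline is

1. minute-resolution activity counts, quality-screened;
2. a daily 8-dimensional feature vector describing the *structure* (not the
   volume) of motor activity;
3. an LSTM encoder-decoder trained to reconstruct relapse-free feature
   segments, with Mahalanobis-scored reconstruction errors;
4. adaptive thresholding of the score sequence into anomalous instances;
5. weekly alignment and confirmation against two brief self-reports
   (VQIDS-SR5 for core depressive symptoms, GAD-7 for anxiety);
6. visit-level evaluation with burden and lead-time metrics.

## Daily features

All features are computed per day from the trailing 7 days of data, so that
day *d* uses only information available on day *d*.

**Quality screen.** Minutes are flagged as gaps when missing, when inside a
zero run longer than 60 minutes (strict), or when the count deviates from
the patient-global mean by at least 10 SD (two-sided). Missing minutes
count toward zero runs: device-off time and true inactivity are
indistinguishable for windowing purposes.

**DFA.** The counts are mean-centered and integrated; non-overlapping
windows of the profile at 20 log-spaced scales between 10 and 600 minutes
(forward and reverse passes) are detrended with an order-2 polynomial, and
the root-mean-square residual `F(n)` is fitted in log-log space over
10-90 min (`alpha1`, fractal motor regulation) and 120-600 min (`alpha2`,
circadian-scale regulation). `alpha = 0.5` is uncorrelated noise; healthy
activity sits near 1. Segments must span at least 2 consecutive days with
no gap over 72 minutes (5% of a day); the most recent qualifying run inside
the trailing week is used. Tolerated gaps are not imputed — windows touching
them are simply dropped from the residual average, which leaves `F(n)`
unbiased at the cost of a few windows. Because the profile is detrended
with an order-2 polynomial, a purely linear count trend yields exactly zero
residuals everywhere; this degenerate case is flagged and the fractal
features set to missing rather than fitted.

**MFDFA.** The same window fluctuations are raised to moments `q` from -5
to 5 (step 0.1 in `mfdfa()`; the daily feature needs only the endpoints),
with the logarithmic average at `q = 0`. The multifractal width is defined
as `h(-5) - h(+5)` of the generalized Hurst exponents. The singularity
spectrum width would be monotone-equivalent for the fitted Legendre
transform; the generalized-Hurst form avoids an extra numerical
derivative. Zero-variance windows (flat stretches) are excluded from the
moment averages — they would otherwise dominate negative moments.

**Sample entropy.** SaEn is computed on the z-normalized first difference
of the counts (activity is long-range correlated; differencing gives an
anti-correlated series suitable for entropy estimation), with template
length `m = 2`, delay 1, and Chebyshev tolerance `r = 0.2` — i.e. 20% of
the SD of the normalized increments, which is exactly 1 after
normalization. Matching uses strict inequality and excludes self-matches;
`B` (length-`m`) and `A` (length-`m+1`) matches are counted over the same
template set so `-log(A/B)` is a conditional probability. Zero-variance
increments are a degenerate-input error; `B = 0` or `A = 0` yields a
missing value. The day and each 6-hour epoch (night 00-06, morning 06-12,
afternoon 12-18, evening 18-24) give five features, each the median over
the trailing 7 days whose span contains no identified gap (index day
included; at least one qualifying day required).

All eight features are invariant to rescaling the counts by a positive
constant, which is what makes them device-agnostic.

## The anomaly model

`encdec_ad()` fits a single-layer LSTM encoder-decoder (hidden size 32 by
default) on sliding 14-day segments of the feature series, z-normalized
with training-period statistics; missing values are imputed with zero
*after* normalization, i.e. with the training mean. The decoder is
conditioned on the encoder's final state, re-feeds its own previous
prediction (no teacher forcing), and emits the segment in reverse order.
Training is full-batch Adam on mean squared reconstruction error, at most
200 epochs with early stopping (patience 15) on the trailing 20% of
segments, which are held out from weight fitting. Full-batch training with
a seeded initialization makes refits bit-reproducible. These architecture
and optimizer choices are sized so that one patient trains in seconds on a
CPU; at 8 input dimensions a larger model only overfits faster.

The held-out segments also supply the error model: per-day error vectors
`e(i) = |x(i) - x_hat(i)|` (averaged across overlapping segments covering
the same day) are fitted with a maximum-likelihood normal `N(mu, Sigma)`
(covariance normalized by `1/N`). Holding these days out of weight fitting
avoids an optimistically small `Sigma`. If `Sigma` is ill-conditioned, the
smallest power-of-ten ridge bringing its condition number below `1e8` is
added. The anomaly score is the Mahalanobis distance
`a(i) = sqrt((e - mu)' Sigma^-1 (e - mu))`, computed with a Cholesky solve
rather than an explicit inverse.

## Anomalous instances and weekly alignment

Scores are smoothed with an EWMA (span 7). Candidate thresholds
`mean + z * sd` over `z` in 2-10 (step 0.5) are each evaluated by the
relative drop in mean and SD after removing supra-threshold points,
penalized by the number of removed points plus the squared number of
removed runs; ties prefer the larger `z`. Flagged runs are then pruned
unless each run maximum exceeds the next retained maximum by at least 13%.
Inside the monitoring protocol this detector runs in every 14-day block of
the score sequence, advancing one day at a time, and the union of flagged
days is kept: a local threshold sees the leading edge of a sustained
prodromal shift, which a single global threshold would absorb into its own
statistics. A constant score sequence yields no instances by construction.

A day is labeled anomalous when an instance occurred in the trailing 7
days — matching the recall period of the weekly questionnaires — and a week
(7-day blocks anchored at enrollment) is flagged when any of its days is
labeled.

## Confirmation, flags and the visit protocol

For each passively flagged week `w`, the surveys of weeks `w` and `w + 1`
are consulted. Exacerbation requires either one moderate-to-severe score
(VQIDS-SR5 >= 6 or GAD-7 >= 10) anywhere in the window, or two mild scores
(VQIDS-SR5 = 5; 5 <= GAD-7 < 10). The wording "two mild symptomatology
scores in both the surveys" admits two readings; the default requires one
mild score from *each* instrument anywhere in the two weeks
(`mild_rule = "cross_instrument"`), with the same-instrument-both-weeks
reading available as a configuration switch. A missing survey is treated as
non-exacerbating. Since confirmation needs week `w + 1`'s survey, the flag
is dated to that survey (last day of week `w + 1`) and attributed to the
next scheduled visit on or after that date.

The continuous protocol: the model first trains on the relapse-free
lead-in (enrollment to first visit, at least 60 days — patients without it
are excluded); each inter-visit interval is scored; the first confirmed
week raises the flag and suspends prediction until the next visit; after a
non-relapse visit the training window grows by that interval and the model
is retrained (warm start from the previous weights by default, 60 epochs;
a from-scratch refit is a config option). Follow-up is truncated at the
first relapse visit. The Active-only comparator applies the same survey
criterion every week and never consults the activity stream; it defines
maximal patient burden (every weekly survey used).

Visits are labeled relapse by any of: MADRS >= 22 confirmed at a
verification visit (verification MADRS >= 22, CGI-S change from baseline
>= 2, or medication change within 14 days — the latter two only in
conjunction with the MADRS >= 22 index visit); hospitalization for
depression; suicidal ideation with intent or behavior; investigator
decision.

## Evaluation metrics

Visit-level confusion counts feed sensitivity, specificity, balanced
accuracy, PPV, NPV and FPR in percent. The false alarm rate is reported
both as `100 * FP / total visits` — the definition that is consistent with
all the published combinations of sensitivity, preemptive-visit counts and
visit totals — and as `365 * FP / patient-days` (alarms per patient-year; a
365-day year). Provider burden is `365 * (TP + FP) / patient-days`.
Patient burden is the share of scheduled weekly surveys actually consulted
(two per passively flagged week, capped at the schedule; 100% by
definition in Active-only mode). Time of detection is the day count from
flag to the relapse visit, summarized by median and IQR (type-7
quantiles). Empty denominators yield missing values, never zeros.

## The synthetic cohort

Because the clinical data are proprietary, the package ships a generator
whose defaults emulate the study design: 365-day follow-up, visits every
60 days, a 60-day clean lead-in, and a latent daily severity in [0, 1]
that is zero for healthy patients and, for relapsing ones, ramps up over a
2-4 week prodrome (bounded upward random walk) to a sustained high from
onset. Counts follow `round(max(0, gate(t) * exp(0.5 * g(t))))`: a cosine
circadian gate (mesor 150, amplitude 120 counts/min, mid-afternoon peak)
times lognormal noise driven by fractional Gaussian noise `g`. The Hurst
index interpolates with severity between the healthy scaling target
(alpha 0.95) and the relapse target (0.65); severity also shrinks the gate
amplitude to 35%, which flattens and quantizes the signal and thereby
lowers sample entropy — the "more monotonous activity" signature. One
seeded fGn stream per patient-day (circulant embedding, exact stationary
covariance) makes cohorts reproducible and day-parallel; the cost is that
correlations do not extend across midnight, which leaves the 10-90 min
exponent untouched and mildly attenuates only the longest fitted scales.
Weekly surveys map mean weekly severity through a clipped linear rule plus
Gaussian noise (healthy weeks sit below both mild bands; full severity
clears both moderate thresholds); clinic MADRS is a saturating linear
proxy calibrated so healthy visits stay far below the enrollment ceiling
of 14 and the designated relapse visit crosses 22 with verification
persistence. Artifacts are injected at low rates: short non-wear runs,
>60-minute zero runs, and extreme spikes.

What the generator does *not* emulate: day-to-day autocorrelation of the
latent state beyond the severity ramp, behavioral confounders (travel,
shift work, weekends), device-specific count calibration, survey
non-compliance patterns correlated with severity, and relapses without a
prodrome. A pipeline that passes the end-to-end test therefore
demonstrates internal coherence under the generator's assumptions — not
clinical performance.

## Numerical choices and problem sizes

* Scales: 20 log-spaced integers, 10-600 min, shared by DFA and MFDFA;
  log spacing is standard for power-law fitting and the exact count is not
  critical.
* Exponent fits require at least 3 positive `F(n)` values in range.
* Detrending uses a cached polynomial basis per scale; residuals via
  `Y - X (X'X)^-1 X'Y`.
* The z-grid tie-break picks the larger `z` (the more conservative
  threshold); the pruning walk resets whenever a percent decrease exceeds
  `p`, so equal-magnitude spikes are both kept.
* SD floor `1e-8` in feature normalization: constant features pass through
  unscaled instead of dividing by zero.
* Warm-start retraining uses seed `seed + visit index` for any fresh
  initialization so that scratch refits differ deterministically across
  visits.
* Test problem sizes are chosen to finish a full run in minutes on one
  CPU: exponent-recovery checks use 20 replicates of 2,880-4,096 points;
  the end-to-end check uses a 20-patient cohort at the default 365-day
  follow-up with strong effect sizes (scaling target drop 0.3, relapse
  surveys reaching moderate, a sharp 14-day prodrome). These sizes are the
  package's own trade-off between statistical resolution and turnaround.
* A slow near-linear severity ramp is the detector's blind spot: within a
  14-day block a linear ramp's maximum sits about 1.7 SD above the block
  mean, below the smallest candidate threshold (z = 2). Longer, gentler
  prodromes (the generator's default draws 14-28 days) are therefore
  detected less reliably than sharp ones — a property of the thresholding
  family, reported here rather than hidden.

## Known limitations

* The adaptive-threshold constants (EWMA span, z-grid, pruning percentage)
  follow the cited telemetry detector's defaults and are exposed as
  configuration rather than asserted as clinically optimal.
* The LSTM is deliberately small; it models 14-day feature dynamics, not
  raw minute data.
* Weekly alignment assumes surveys are answered on schedule; late surveys
  are treated as missing for the week they cover.
* `alpha` targets above ~0.98 cannot be realized by stationary fGn (the
  generator clamps the Hurst index below 1); the healthy default of 0.95
  is inside the representable range.

## A worked run

```{r example}
cfg <- sim_config(n_patients = 4, follow_up_days = 240, seed = 7)
cohort <- simulate_cohort(cfg)
runs <- lapply(cohort, function(rec) {
  mask <- detect_gaps(rec$minutes)
  ft <- feature_table(rec$minutes, mask)
  nof1_run(rec, "passive_active", features = ft, mask = mask)
})
evaluate_cohort(runs)
```
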