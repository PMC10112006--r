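---
title: "Methods: high-gamma dynamics and white-matter-gated connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-gamma dynamics and white-matter-gated connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hgconn` turns multichannel intracranial EEG (iEEG) recordings from a
three-task naming experiment into millisecond-scale dynamic
functional-connectivity networks. This vignette documents the analysis
model, the statistical conventions, and the design decisions behind the
implementation, including the places where the package deliberately
deviates from the most obvious construction and why.

## 1. Analysis model

The pipeline is a fixed chain:

1. **Time-frequency extraction.** Each channel is complex-demodulated at
   nine center frequencies, 70-110 Hz in 5-Hz steps. Demodulation
   multiplies the signal by `exp(-2*pi*i*f*t)` and low-pass filters the
   product with a Gaussian FIR whose *temporal* full width at half maximum
   is 31.6 ms; with a Gaussian filter this is exactly a Gabor transform.
   The filter is truncated at ±3 sigma (sigma ≈ 13.42 samples at 1000 Hz)
   and normalized to unit sum, so a pure sinusoid of peak amplitude *a* at
   a grid frequency demodulates to amplitude *a*. The band amplitude is
   the unweighted mean across the nine frequencies, reported every 10 ms.
   The temporal width is the authoritative parameter; the spectral
   amplitude response (sigma ≈ 11.9 Hz) follows from it.

2. **Event-related timelines.** Band amplitudes are sampled in three
   windows per trial — stimulus onset (-200 to +900 ms, 111 bins),
   stimulus offset (±900 ms, 181 bins), response onset (±900 ms,
   181 bins), together 473 bins — and normalized to percent change
   against the 600-200 ms pre-stimulus baseline. Trials answered
   incorrectly, trials without a quiescent baseline (channel-mean
   baseline maximum above the across-trial median plus three robust
   standard deviations), and trials whose baseline loses filter support
   at a recording edge are excluded; exclusion counts are carried into
   the run manifest.

3. **Group statistics.** Electrode sites are pooled across patients into
   36 cortical regions (18 gyri × 2 hemispheres); regions with fewer
   than 9 sites are excluded. Per region, task and bin, the
   across-electrode mean percent change gets a studentized
   (bootstrap-t) 99.99% confidence interval from 2000 electrode
   resamples; bins whose interval excludes zero for at least 50 ms
   (5 consecutive bins, at least three high-gamma cycles) are flagged as
   significant augmentation or attenuation.

4. **Connectivity.** Two regions co-modulate when both masks share the
   same polarity for at least 100 ms. A co-modulation becomes a
   functional-connectivity event only if diffusion tractography finds
   direct white-matter streamlines between the regions (binary adjacency
   gate). Events are rendered as a dynamic connectome in 100-ms epochs
   sliding by 10 ms, and summarized per laterality class (left-intra,
   right-intra, interhemispheric).

5. **Chance probability.** Under independence across bins and regions,
   the expected count of co-augmentation runs of length `L` bins among
   `R` regions and `n` bins with marginal significance rate `chi` is
   `choose(R, 2) * (n - L + 1) * (chi/100)^(2L)`; with
   (36, 473, 10, 21.9%) this gives 1.9e-8. Being an expected count it
   upper-bounds the probability of at least one chance event.

6. **Behavioral statistics.** Per-task response-time medians, a Friedman
   test across the three tasks, and pairwise Wilcoxon signed-rank tests
   with effect size `r = |Z|/sqrt(N)`.

## 2. Statistical conventions worth stating exactly

**Studentized bootstrap.** The interval is built from the pivot
`t* = (mean* - mean)/se*`, with one resample of electrodes shared by all
bins of a region/task/alignment so that the temporal correlation of the
interval is the temporal correlation of the data. Resamples in which a
single electrode is drawn n times have no within-resample variance and
are redrawn (up to 100 rounds). For five or fewer electrodes,
`studentized_bootstrap_ci(..., enumerate = TRUE)` replaces Monte Carlo by
exhaustive enumeration of all `n^n` resamples with multinomial weights.
Between-task contrasts resample each side independently and studentize
the difference.

**Wilcoxon variant.** Zero differences dropped, average ranks on ties,
tie-corrected variance, no continuity correction,
`Z = (W+ - n(n+1)/4)/SD`. The Friedman statistic is the classic
`12/(nk(k+1)) * sum(Rj^2) - 3n(k+1)` without tie correction. The
effect-size denominator is `N = 2 * n_pairs`, the total observation
count of the paired comparison. These conventions were chosen because
they are the unique combination that reproduces the reference behavioral
table's printed statistics (`behavior_summary()`), and they are
cross-checked in the test suite against `stats::wilcox.test()` and
`stats::friedman.test()` where the conventions coincide.

**Period-extent comparison.** The per-bin count of connected pairs is
compared across three 600-ms periods (post-stimulus, pre-response,
post-response) using the 60 bins of each period as blocks; the pairwise
significance threshold 0.0056 is a Bonferroni correction over nine
comparisons.

## 3. Design decisions and deviations

**Percent-change normalization defaults to the ratio of means.** The
obvious construction normalizes each trial by its own baseline mean and
averages the per-trial percent changes (`normalization = "per_trial"`,
still available). That estimator carries a positive small-sample bias of
approximately `CV^2` of the single-trial baseline mean — with a 13.4-ms
filter over a 400-ms baseline, roughly 8-9 effectively independent
samples, i.e. a bias of a few percent — which is *shared across all
electrodes of a channel-homogeneous region* and therefore does not
average out across electrodes; at a 99.99% confidence level it measurably
inflates the false-flag rate on null data. The default
`"trial_mean"` (average amplitudes across trials first, then one ratio)
has negligible bias. The package treats the null-calibration property
(few flagged runs on modulation-free data) as the binding requirement
and makes the low-bias estimator the default.

**Burst injection band is wider than the analysis band.** The generator
plants bursts by multiplicatively rescaling the channel's band-limited
noise component under a Tukey (10% taper) envelope. If that component
were brick-wall limited to exactly 70-110 Hz, the demodulation filters at
70 and 110 Hz would mix roughly half unscaled spectral content through
their skirts and a +100% burst would measure as only ≈ +82%. The
injected component therefore spans the analysis band widened by 25 Hz
(≈ 3 sigma of the filter's spectral power response) on each side —
physiological high-gamma is broadband — which makes the measured
70-110 Hz amplitude change equal the configured `amplitude_pct` by
construction (+100% measures +99.2%). Temporal smearing of ≈ one bin at
burst edges remains, which is the filter's actual resolution.

**Common average reference is applied after burst injection**, mirroring
a real recording chain; a burst therefore leaks `-1/n_channels` of
itself into every other channel. Tests account for this rather than
pretending the reference is transparent.

**FFT lengths.** Background noise is synthesized by spectral shaping
(`1/f^alpha` amplitude, default `alpha = 1`) on the next 2-3-5-smooth
length and truncated, because mixed-radix FFTs degrade badly on lengths
with large prime factors. This is a performance choice with no
statistical content.

## 4. The synthetic-data generator as ground truth

Defaults mirror the targeted study design: 1000-Hz sampling, 13
patients, 60/60/100 trials for picture/sound/question naming, 1.8-s
stimuli, next stimulus 2-2.5 s after the response, log-normal response
times calibrated to the bundled behavioral table. `sim_config()`
validates every parameter; `simulate_recording()` returns the recording,
trial events, electrode table, and a ground-truth block including the
expected connectivity events (`expected_co_events()`: temporal
intersections ≥ 100 ms of same-polarity bursts on streamline-connected
pairs), so recovery can be scored without re-deriving truth in tests.

Realism limits, stated plainly: noise is Gaussian `1/f^alpha` without
physiological rhythms or artifacts; bursts are amplitude rescalings, not
waveform models; electrode counts per region are uniform. The generator
is built for calibration and recovery testing, not for mimicking every
property of patient data.

## 5. Problem sizes used in the test suite

The package's own desk-scale choices (full study scale would take hours):

* **Parameter recovery:** 6 left-hemisphere regions × 20 electrodes,
  20 trials of one task, four planted +100% bursts forming three
  expected events through a 4-edge adjacency, 200 bootstrap resamples.
  Recovery is scored against the ground-truth block: onset error ≤ 1 bin,
  all expected events found, none off the streamline graph.
* **Null calibration:** 200 independently seeded null datasets, 36
  regions × 9 electrodes, 6 trials of one task, 200 resamples; at most
  5% of datasets may show any flagged run.
* **Coverage:** 3000 replications of a 20-electrode normal sample at the
  99.99% level; empirical coverage must be ≥ 99.7%.
* **Chance-probability oracle:** 100 000 Monte-Carlo draws on a
  (4 regions, 50 bins, L = 3, chi = 30%) configuration, agreement within
  3 standard errors of the analytic value.

With 200 resamples and a 99.99% interval, the bootstrap quantiles sit at
the extremes of the resample distribution, so the effective per-bin,
per-tail flag probability is bounded near `1/(B+1)` by exchangeability;
the run-length gate then suppresses isolated excursions. The null
calibration above tests exactly this combined behavior.

## 6. Reproducibility contract

Every randomized stage takes an explicit seed (`sim_config()`,
`boot_spec()`, `pipeline_config()`); `with_seed()` isolates all internal
RNG use from the caller's stream. `run_pipeline()` writes a manifest
with a config hash, input checksums and per-stage counts satisfying
`trials_in = retained + excluded_incorrect + excluded_baseline +
excluded_edge`, and reruns with identical config and seed are
bit-identical. A stage failure keeps completed outputs and records the
failed stage in the manifest.
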