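---
title: "Methods: hemodynamic laterality analysis of prefrontal fNIRS stress recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemodynamic laterality analysis of prefrontal fNIRS stress recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Psychological stress lateralizes prefrontal hemodynamic activity: under
stress, the right prefrontal cortex tends to be more strongly activated than
the left. Functional near-infrared spectroscopy (fNIRS) measures this
non-invasively as concentration changes of oxyhemoglobin (dHbO) and
deoxyhemoglobin (dHbR). `nirslat` implements an event-related analysis that
quantifies that asymmetry with a laterality index for stress,

$$\mathrm{LIS} = \frac{R - L}{R + L},$$

where $R$ and $L$ are the maximum absolute dHbO amplitudes over the
right-hemisphere (channels 1–7) and left-hemisphere (channels 9–15) channel
sets of a 15-channel prefrontal montage. LIS lies in $[-1, 1]$; positive
values indicate right lateralization. The analysis separates three groups
defined by the salivary alpha-amylase (sAA) biomarker — control
(sAA < 28 KU/L), eustress (33–44 KU/L) and distress (> 44 KU/L) — the
working hypothesis being an inverted-U relation: moderate stress (eustress)
shows the strongest right-lateralized response, excessive stress (distress)
almost none.

## Pipeline stages and their assumptions

1. **Conversion** (`mbll_inverse`): two-wavelength (780/850 nm)
   optical-density changes are converted to dHbO/dHbR by solving the 2×2
   modified Beer–Lambert system per channel and sample, with 25 mm
   source–detector separation and a differential pathlength factor (DPF).
2. **Filtering** (`bandpass`): a zero-phase band-pass isolates the
   task-locked frequency. One trial lasts 61 s, so the stimulation
   fundamental is ≈ 0.0164 Hz; the default 0.01–0.02 Hz band retains it
   while rejecting DC, drift, Mayer waves (~0.1 Hz), respiration (~0.25 Hz)
   and cardiac pulsation. A wider 0.01–0.1 Hz band is available via
   `high_hz = 0.1`.
3. **Epoching** (`epoch`, `baseline_correct`): trials are cut to
   $[-1, 60]$ s around each task onset (the start of a trial's first warning
   stimulus) and the mean over $[-1, 0)$ s is subtracted per trial and
   channel.
4. **Averaging and laterality** (`grand_average`,
   `lis_by_group_session`): epochs are averaged over trials within
   participant, then participants are pooled within a (group, session) cell;
   the hemisphere amplitudes of the pooled average give one LIS per cell.
   Per-participant LIS values supply a standard error across participants.
   Only dHbO enters the laterality analysis; dHbR is carried through the
   preprocessing for completeness.
5. **Statistics** (`compare_two_groups`, `compare_three_groups`,
   `correlate`): Levene's variance check followed by a two-sample t-test
   (control vs. pooled stress) and a one-way ANOVA with Dunnett T3 post hoc
   (three groups), plus two-tailed Pearson correlations between sAA and
   behavioural covariates.

## Filter design

The band-pass is a Chebyshev type-I design of prototype order 6 applied
forward–backward, i.e. the standard reading of a "sixth-order zero-phase"
filter: the effective magnitude response is $|H(f)|^2$ with exactly zero
phase. At 8.138 Hz sampling, a 0.01–0.02 Hz band puts all twelve poles at
radii above 0.9987, where the expanded transfer-function polynomial is
numerically singular; the design is therefore built and applied in
second-order sections (closed-form analog prototype → band-pass transform →
bilinear transform), validated in the test suite against an independent
implementation on a well-conditioned band.

Numerical choices:

* **Passband ripple 0.5 dB.** Ripple is squared by the forward–backward
  pass: with $r$ dB of design ripple the in-band amplitude can dip to
  $10^{-r/10}$. At 0.5 dB an in-band tone is preserved to within ~3.5%,
  keeping the passband essentially transparent to the task frequency; at
  1 dB the dip would exceed 5%, which we consider too lossy for an
  amplitude-based laterality statistic. Ripple is a configuration knob
  (`ripple_db`).
* **Edge handling.** The per-channel mean is removed, the record is
  extended by odd reflection over `3 * fs / low_hz` samples (three slowest
  passband periods) on each side, and the cascade is run forward and
  backward with zero initial state. This keeps the narrow-band recursion's
  long edge transients out of the analyzed record.
* **Epoch indexing.** The $t = 0$ sample of an epoch is
  `floor(onset * fs)`; the window takes `floor(fs)` samples before and
  `floor(60 * fs)` after it, inclusive — 497 samples at 8.138 Hz. The
  baseline interval is half-open, $[-1, 0)$: the onset sample belongs to
  the task.
* **Beer–Lambert constants.** Extinction coefficients at 780/850 nm from
  the standard Prahl / Cope–Delpy compilations and DPF = 6.0 at both
  wavelengths, both editable (`extinction_coefficients()`, `dpf`
  arguments). The DPF convention only scales concentrations; LIS is
  invariant to it by construction.

## What the synthetic generator emulates

`sample_cohort()` and `simulate_hemodynamics()` reproduce the statistical
structure the analysis assumes, so the whole pipeline is testable without
any recording:

* **Paradigm**: two sessions of 20 trials; each trial is 1 s trial-number
  display, five repetitions of (0.5 s warning, 2 s anticipation, 2 s target
  image + response, 0.5 s feedback), then 35 s rest — 1220 s per session.
  Exactly 30% of the 100 target events carry the session's minority valence
  (positive in session 1, negative in session 2), as a seeded permutation.
* **Cohort**: sAA per group from truncated normals with the reported group
  means/SDs (control 12.73 ± 9.76, eustress 37.82 ± 3.49, distress
  61.82 ± 18.07 KU/L), resampled into the strict group intervals so sAA
  classification recovers the generating group exactly. Behavioural
  covariates follow the reported group accuracies (96.9/95.8/95.5%) and an
  inverted-U reaction-time pattern (eustress fastest, distress slowest).
* **Hemodynamics**: the clean dHbO response is the target-period boxcar
  convolved with a canonical double-gamma HRF (peak ≈ 6 s, undershoot
  ≈ 16 s, ratio 1/6 — the field-standard response model), scaled by a
  per-participant right-hemisphere gain $g$ (left fixed at 1, midline the
  mean of both). dHbR is $-1/3$ of the clean dHbO component. Noise adds
  slow drift, Mayer/respiratory/cardiac sinusoids with random per-channel
  phases, and white measurement noise; the cardiac component aliases at
  8.138 Hz, which real recordings also exhibit.

Because filtering, epoching and averaging are linear, the noiseless
pipeline yields $\mathrm{LIS} = (g - 1)/(g + 1)$ exactly. The default group
gains — control 1.20, eustress 1.67, distress 1.008 — were chosen once from
this closed form to land at LIS ≈ 0.09, 0.25 and 0.004, inside the ranges
reported for such cohorts, and are configuration (`cohort_parameters()`),
not constants.

**Calibration of between-subject variability.** Published group-level LIS
bar graphs carry standard errors across ~11 participants that are visible
but small relative to the 0.09–0.25 group separations. We model the
dominant source of that variability as between-subject lateral-gain
spread: each participant's right gain is the group default times
$\exp\!\big(\mathcal N(0, 0.10)\big)$. With the default sensor-noise
amplitudes this yields per-participant LIS standard errors of roughly
0.01–0.02 per group — the targeted magnitude. This is a one-time modelling
choice, not a fitted quantity.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: motion artifacts, superficial/systemic
contamination (no short-separation channels), inter-channel correlated
physiology, session-specific valence effects (the generator's gain is
session-independent), non-stationary drift, and any biophysically detailed
photon transport. Agreement of the pipeline on synthetic data demonstrates
correctness of the computation, not fidelity of the generator to any
particular cohort.

## Design choices on genuinely open points

* **Hemisphere aggregation.** "Maximum absolute amplitude" of a
  multi-channel hemisphere can be read as the amplitude of the most active
  channel (max of per-channel maxima) or the mean across channels of
  per-channel maxima. Both are implemented; `max` is the default and `mean`
  is selectable (`aggregation_mode`), and end-to-end runs report the mode
  used in every output row. This ambiguity is the main expected source of
  discrepancy when reproducing published group values.
* **Group-level vs. per-participant laterality.** The headline LIS pools
  participants before taking amplitudes (one value per group/session); a
  per-participant LIS is also computed to provide the standard error, since
  published bar graphs show exactly that pairing.
* **Task onset.** The onset used for epoching is the start of a trial's
  first warning stimulus, not the trial-number display: the 61 s epoch then
  tiles the 25 s stimulus-response block plus the 35 s rest exactly.
* **Amplitude window.** Hemisphere amplitudes use $[0, 60]$ s (task portion
  of the epoch), configurable via `interval`; the baseline segment is
  excluded by default.
* **t-test variant.** Levene at $\alpha = 0.05$ decides between the
  pooled-variance and Welch t-test — the conventional coupling when a
  variance check precedes the comparison.
* **Strict sAA boundaries.** 28, 33 and 44 KU/L are exclusive: values in
  $[28, 33]$ and exactly 44 are `unclassified`, mirroring enrollment rules
  that left the gap empty.
* **Dunnett T3.** No installed implementation exists, so the studentized
  maximum modulus reference distribution is integrated directly
  (`psmm()`, relative tolerance 1e-9); with one comparison it reduces to
  the two-sided t distribution, which the tests exploit as an oracle.

## Problem sizes used by the test suite

The reference conditions are 11 participants per group, 20 trials per
session, 1220 s sessions at 8.138 Hz. Stochastic guarantees are checked at
these sizes: group-ordering recovery (eustress > control > distress) over
200 simulated session-1 cohorts (session 2 is statistically identical under
the session-independent gain model), and type-I calibration of the t-test
and ANOVA over 2000 null replicates each. Deterministic properties
(closed-form LIS recovery, Beer–Lambert round trips, filter response) run
on single recordings.

## Known limitations

* The SNIRF/HDF5 container is not read; recordings enter via the wide-CSV
  dialect (`write_recording`/`read_recording`) or the simulator.
* The laterality statistic is the global hemisphere contrast of the probe;
  channel-wise lateralization maps and LI-curve variants from the wider
  laterality literature are out of scope.
* No motion-artifact correction or short-channel regression is provided;
  recordings are assumed clean enough for band-pass + epoch averaging.
* With near-symmetric responses (gains close to 1), the group LIS estimate
  is noise-limited; at the default noise level the distress group's
  estimate scatters by about ±0.02 around its small true value.

## A minimal run

```{r, eval = FALSE}
library(nirslat)
config <- default_config()
config$seed <- 1L
res <- run_pipeline(config)
res$lis_three_group
```

The same analysis applies to recordings on disk: read each participant's
sessions with `read_recording()`, convert raw optical densities with
`mbll_inverse()` if needed, preprocess with `bandpass()`, `epoch()` (onsets
from `trial_onsets(build_session_schedule(...))` or a recorded event file)
and `baseline_correct()`, and pass the per-participant epoch sets to
`lis_by_group_session()`.
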