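---
title: "Quantifying VEP timing plasticity: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying VEP timing plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veptime)
```

## The scientific problem

A visually evoked potential (VEP) is the trial-averaged local field
potential (LFP) deflection time-locked to a visual stimulus. In mouse V1,
daily exposure to one grating orientation potentiates the VEP's
peak-to-peak magnitude (stimulus-selective response potentiation, SRP). In
the anterior cingulate cortex (ACC) the signature of familiarity is
different: the *latency* of the second negative component (N2, written
"A2" when driven by stimulus A, trough roughly 160-190 ms after onset)
shortens across days, specifically for the familiar orientation (SRPT). An
Angelman-syndrome model genotype dissociates the two: its ACC latency
shift is absent while the positivity that follows the A2 trough is
enlarged, and its V1 SRP is preserved.

Measuring a latency shift of a few tens of milliseconds on top of noisy
continuous recordings raises a chain of methodological questions — how to
epoch, how many trials a quantifiable VEP needs, how overlapping
components of sequence stimuli confound each other, which statistics to
use across days and genotypes. `veptime` implements that chain and pairs
it with a generative model whose ground truth is known exactly, so every
stage can be validated by parameter recovery rather than by eye.

## The forward model

Each stimulus drives, per channel, a set of *component kernels*. A kernel
is a negative Gaussian lobe (the trough whose time defines component
latency) plus an optional positive lobe, truncated at 4 sigma:

$$k(t) = -A_-\, G(t;\mu_-,\sigma_-) + A_+\, G(t;\mu_+,\sigma_+)$$

with $G$ a unit-peak Gaussian. A recording is the superposition of the
role-appropriate kernels at every event onset, plus Gaussian white noise,
plus 1/f ("pink") noise, plus — in V1 — a decaying oscillation in the
0.5-1.5 s post-onset stationary window. Gray periods and the 30 s
inter-block gaps are simulated as noise-only spans rather than truncated,
so epoching runs against realistic continuous data.

The Gaussian-lobe form is the simplest shape with independent latency,
magnitude, and positivity ground truth; no waveform model is claimed by
the underlying physiology, and all defaults are configurable.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| sample rate | 1000 Hz | standard post-acquisition downsampling for LFP work |
| ACC N1 | trough 60 ms, 30 uV, sigma 10 ms | fast component at its empirically observed ~60 ms |
| ACC N2 ("A2") | trough 170 ms, 25 uV, sigma 12 ms; positivity 260 ms, 10 uV, sigma 25 ms | trough inside the observed 160-190 ms range; the width is unreported anywhere, so it was fixed once from a design simulation such that 200-trial averages recover latency to about 1 ms (see "Numerical choices") |
| V1 wave | trough 75 ms, 80 uV; positivity 140 ms, 40 uV | classical large biphasic V1 VEP |
| WT plasticity | familiar-orientation A2 trough -20 ms from Day 2 onward | the bulk of the latency change occurs between the first two sessions |
| AS plasticity | no latency shift; A2 positivity ramps to x2 by Day 4 | qualitative genotype pattern; the exact effect size is unreported, hence configurable |
| V1 SRP | familiar-orientation amplitudes ramp to x1.5 by Day 4 (both genotypes) | typical SRP magnitude growth |
| noise | white SD 20 uV + pink SD 10 uV | makes single trials unquantifiable while 200-trial averages are clean (average white noise 20/sqrt(200) ~ 1.4 uV against a 25 uV trough) |
| V1 oscillation | 10 Hz, 15 uV, tau 600 ms, familiar gain ramping to x3 by Day 4 | produces a clear familiar-day band-power contrast in the stationary window; the true frequency is unreported, hence configurable |
| population spread | N2 latency SD 5 ms, log-amplitude SD 0.15, shift SD 3 ms | typical between-animal variability for cohort simulations |

Orientation vocabulary: A = 45(deg), B = 105, C = 15, D = 75, E = 135,
novel N = 165 (135 for the single-stimulus scenarios). Protocols: 200
trials in 4 blocks of 50, elements abutting within a sequence, 1.5 s gray
after each sequence, 30 s gray between blocks; phase reversal: 400
reversals at 2 Hz in 4 blocks of 100 with no gray between reversals.
Pseudorandom sequences draw the three trailing elements without
replacement from {B, C, D, E}, so no element repeats within a sequence.

## Quantification conventions

* **Epochs** are half-open windows `[start, end)` in ms relative to the
  alignment event's onset, at the recording rate. Component latencies of
  B/C/D/X elements are reported relative to *their own* stimulus onset
  (an auxiliary column keeps the lead-aligned time, since the alternative
  convention is also in circulation).
* **Latency** is the time of the minimum voltage in the component's search
  window; ties break to the earliest sample. Default search windows: fast
  components 20-120 ms, slow components 120-320 ms capped at the next
  element's onset. With 150 ms elements the slow lead component and the
  fast follower overlap in time, so only a single composite window is
  quantifiable — the package refuses to emit a slow-component window
  narrower than ~100 ms rather than report a confounded number.
* **Magnitude** is peak negativity to the *following* peak positivity
  (through the window end), non-negative by construction; **positivity**
  is the post-trough maximum relative to the voltage at the alignment
  onset (time 0), making it DC-offset invariant.
* Flat windows, windows whose minimum lands on the final sample, and
  averages of fewer than 50 trials are flagged unquantifiable (`NA`,
  `valid = FALSE`) and propagate as missing values, never as zeros.
* **Hemisphere averaging**: bilateral V1 measures are averaged per
  subject; if one hemisphere is invalid the other is used alone; two
  invalid hemispheres are an error, not a zero.

## Spectral conventions

The continuous record is high-pass filtered (ninth-order Butterworth,
0.5 Hz, applied forward-backward so evoked latencies are untouched), then
the 1 s stationary window beginning 0.5 s after stimulus onset is Fourier
transformed per trial with no taper: a 1 s window at 1 kHz gives exactly
1 Hz bins. Power is $|\mathrm{fft}(x)/N|^2$: the full two-sided set then
sums to the mean squared voltage (Parseval), and an integer-frequency
sinusoid of amplitude $a$ contributes exactly $a^2/4$ to its one-sided
bin. One-sided spectra are cropped to 1-100 Hz without doubling, and band
power sums bins with $1 \le f \le 30$ Hz inclusive. Trial spectra are
averaged pointwise before band quantification.

## Statistics

Day-level plasticity is tested with a one-way repeated-measures ANOVA;
genotype contrasts with a two-way mixed (between genotype x within
session) ANOVA. The Greenhouse-Geisser epsilon is estimated from the
(pooled) within-subject covariance and applied *unconditionally* to the
within-subject degrees of freedom — fractional dfs are always reported,
matching the field's reporting convention. The mixed design's session
main effect uses the unweighted-means (type III) convention so unbalanced
groups are handled the way standard statistics packages handle them;
`car::Anova` on the equivalent multivariate model is the cross-check
oracle in the test suite. Exact Dunnett and Tukey studentized-range
distributions are deliberately out of scope; Sidak
($p_{adj} = 1-(1-p)^m$) and Holm step-down adjustments are provided
instead, and t tests are classical pooled-variance two-sided tests.

Unconditional GG correction is mildly conservative for small cohorts
(Monte-Carlo size ~0.03 at n = 8-10 under exact sphericity); the
end-to-end null calibration of the full simulate-quantify-test chain in
the acceptance suite lands inside 5% +/- 2.5%.

## Numerical choices

* **Peak picking on noisy averages.** The base extractor follows the bare
  definition (minimum sample). The component-measurement layer defaults to
  a 13 ms boxcar followed by 3-point parabolic interpolation — standard
  ERP practice. Both are exact (within one sample) on noiseless symmetric
  troughs; on 200-trial averages at default noise the smoothed/refined
  estimator has ~1 ms latency jitter, which is what makes a -20 ms shift
  recoverable within +/-3 ms in more than 95% of sessions. The smoothing
  width was fixed at design time from that recovery requirement.
* **High-pass filter.** A ninth-order Butterworth at 0.5 Hz/1 kHz is
  numerically singular in expanded transfer-function form (all poles
  cluster near z = 1), so the filter is designed and applied as a cascade
  of second-order sections derived from the analytic Butterworth poles via
  the bilinear transform, with odd-reflection padding. The cascade's
  double-precision floor leaves a ~3e-6 relative residual at 0.1 Hz
  (reference implementations in other ecosystems show the same order);
  tests assert >1e5 attenuation rather than the unattainable analytic
  two-pass value.
* **Pink noise** is white noise shaped by a three-pole pinking filter
  (Kellet coefficients), scaled to unit variance by the filter's impulse
  response energy, with a 1000-sample burn-in.
* **Determinism.** Every stochastic stage takes an explicit seed;
  `simulate_cohort` derives all protocol, model and noise seeds from one
  master seed, so identical calls are bit-identical. Seeded draws use the
  Kinderman-Ramage normal generator (chosen for speed on the ~1e6 deviates
  per simulated session). The LFP container stores float32, so one
  write-read cycle quantises and is lossless thereafter.
* **Tie-breaks and degenerate inputs.** Latency ties resolve to the
  earliest sample (deterministic and symmetric across conditions);
  all-equal windows are unquantifiable; a repeated-measures table with no
  condition variance reports F = 0; zero within-error variance is flagged
  rather than reported as infinite.

## What the synthetic data does and does not show

The generator reproduces the *structure* of the experiments — event
timing, component overlap at short durations, familiar-specific plasticity
schedules, genotype dissociation, stationary-window oscillations, and
realistic trial-average SNR. It deliberately omits single-trial amplitude
and latency variability beyond additive noise, locomotion/arousal state,
electrode drift, cross-channel correlation, and any claim about true
waveform shape. Passing recovery tests therefore demonstrates that the
measurement chain is unbiased and appropriately powered *under the stated
generative assumptions*, not that real recordings satisfy those
assumptions.

## Problem sizes used in the automated checks

The test suite runs cohorts at the study's native session size (200
trials, 4 days): 100 sessions for latency recovery, 20 subjects for the
composite/resolved contrast, 50 cohorts of 8 + 8 for the genotype
dissociation (simulating ACC plus one V1 hemisphere; the second
hemisphere adds statistical redundancy and is exercised in unit tests),
and 400 cohorts of 8 for the null calibration. The acceptance script
reports the same quantities at moderately reduced replicate counts
(60/20/20/150), chosen as the smallest sizes at which the reported rates
are stable to a few percent.

## Known limitations

* The B1-vs-A2 attribution at 150 ms stimulus duration is inherently
  confounded; the package quantifies the composite window and flags the
  confound mechanically (via `detect_biphasic`) instead of resolving it.
* The hemisphere-exclusion rule ("poor signal") has no published
  criterion; the validity flag (unquantifiable or < 50 trials) is a
  repository convention.
* Post hoc families are limited to Sidak/Holm; exact Dunnett/Tukey
  distributions are not implemented.
* The simulator's noise is stationary; slow nonstationarities that the
  0.5 Hz high-pass is meant to remove in real data are only present as
  pink noise.
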