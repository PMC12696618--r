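# veptime

Tools for studying experience-dependent plasticity in the **timing** and
**magnitude** of visually evoked potentials (VEPs) recorded as local field
potentials (LFPs) in mouse cortex.

Repeated daily exposure to a visual stimulus changes cortical responses in
two qualitatively different ways:

* **V1 (primary visual cortex)** expresses *stimulus-selective response
  potentiation* (SRP): the peak-to-peak magnitude of the VEP to a familiar
  stimulus grows across days.
* **ACC (anterior cingulate cortex)** expresses *stimulus-specific response
  plasticity in timing* (SRPT): the latency of the second negative VEP
  component (N2; "A2" when driven by stimulus A) to a familiar stimulus
  shortens across days, while its magnitude is largely unchanged. In an
  Angelman-syndrome model genotype (*Ube3a m-/p+*) the latency shift is
  absent and the A2 positivity is enlarged instead.

`veptime` packages the complete analysis chain needed to quantify these
phenomena, together with a forward simulator that generates continuous
multichannel LFP with *known* ground truth, so that every stage of the
chain is verifiable by parameter recovery:

* **Stimulus protocols** — ordered four-element grating sequences (ABCD /
  DCBA), pseudorandom sequences with a fixed lead (AXXX / NXXX),
  single-orientation trials, and classical 2 Hz phase-reversal blocks;
  200 trials in 4 blocks of 50 (400 reversals in 4 x 100), 1.5 s gray
  between sequences, 30 s between blocks.
* **Forward model** — each stimulus drives per-channel component kernels
  (sums of truncated Gaussian lobes: ACC N1 at ~60 ms, N2 at ~170 ms with a
  late positivity; a large biphasic V1 wave), placed at event onsets and
  superposed with white + 1/f noise and, in V1, a decaying 10 Hz
  oscillation in the 0.5-1.5 s stationary window. Plasticity schedules move
  the familiar-orientation N2 trough (-20 ms by Day 2 in WT), enlarge the
  N2 positivity (x2 by Day 4 in the AS genotype), and scale V1 amplitudes
  (x1.5 by Day 4, both genotypes).
* **Quantification** — event-aligned epoching, trial averaging, negative
  peak latency (`vep_latency`), peak-to-peak magnitude (`vep_magnitude`),
  multi-component decomposition (`component_measures`), A2 positivity,
  sequence magnitude ((A+B+C+D)/4), block-of-50 latencies, hemisphere
  averaging with validity flags, Day4 - Day1 plasticity deltas, and
  biphasic (composite) response detection.
* **Spectral analysis** — zero-phase ninth-order 0.5 Hz Butterworth
  high-pass, per-trial rectangular-window Fourier power of the 1 s
  stationary window (exactly 1 Hz bins), trial-averaged spectra, inclusive
  1-30 Hz band power.
* **Statistics** — one-way repeated-measures ANOVA and two-way mixed
  (group x session) ANOVA, both with unconditional Greenhouse-Geisser
  correction and fractional degrees of freedom, Sidak/Holm post hocs, and
  classical t tests.

## Worked example

```r
library(veptime)

# one wild-type subject, single-orientation training, days 1 and 4
m  <- subject_model("WT")
p1 <- make_protocol("SINGLE", day = 1, stimulus_duration_ms = 300)
p4 <- make_protocol("SINGLE", day = 4, stimulus_duration_ms = 300)
r1 <- simulate_session(evolve_model(m, 1), p1, seed = 11, channels = "ACC")
r4 <- simulate_session(evolve_model(m, 4), p4, seed = 12, channels = "ACC")

lat <- function(rec) {
  v <- average_vep(extract_epochs(rec, c(-100, 500), channel = "ACC"))
  vep_latency(v, c(120, 320), smooth_ms = 13, refine = TRUE)
}
lat(r1)
#> [1] 170.9109
lat(r4)
#> [1] 149.8647
plasticity_delta(lat(r1), lat(r4))
#> [1] -21.04626
```

The recovered Day 1 latency sits at the programmed 170 ms N2 trough, and
the Day4 - Day1 delta recovers the programmed -20 ms familiar-stimulus
shift to within the estimator's ~1 ms jitter at 200 trials.

The same chain scales to cohorts: `simulate_cohort()` draws subjects from
population distributions and emits a ground-truth kernel table;
`run_pipeline()` chains simulate -> quantify -> spectra -> ANOVA into tidy
CSVs with a seeded, hash-logged run record. A thin CLI over these functions
is installed at `inst/cli/veptime`.

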