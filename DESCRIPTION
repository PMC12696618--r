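Package: veptime
Title: Simulation and Quantification of Visually Evoked Potential Timing
    Plasticity in Continuous LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying experience-dependent plasticity in the timing
    and magnitude of visually evoked potentials (VEPs) recorded as local field
    potentials (LFPs). Provides generators for visual stimulus protocols
    (ordered four-element sequences, pseudorandom sequences, single
    orientations, and phase reversals), a forward simulator producing
    continuous multichannel LFP with known component kernels, plasticity
    schedules, genotype regimes and noise, event-aligned epoching and trial
    averaging, VEP component quantification (negative-peak latency,
    peak-to-peak magnitude, post-trough positivity, sequence magnitude,
    block-wise latency, hemisphere averaging, biphasic detection), fixed-window
    Fourier band-power analysis with a zero-phase Butterworth high-pass, and
    repeated-measures statistics (one-way RM ANOVA and two-way mixed ANOVA
    with Greenhouse-Geisser correction, Sidak/Holm post hocs, t tests),
    together with a reproducible end-to-end pipeline and plain-text file
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
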