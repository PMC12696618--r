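# --- zero-phase Butterworth high-pass -------------------------------------
#
# A ninth-order Butterworth at 0.5 Hz / 1 kHz is numerically singular in
# expanded transfer-function form (all poles cluster at z = 1), so the
# filter is designed and applied as a cascade of second-order sections
# derived from the analytic Butterworth poles via the bilinear transform.

butter_highpass_sos <- function(order, cutoff_hz, sample_rate_hz) {
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < sample_rate_hz / 2)
  fs2 <- 2 * sample_rate_hz
  wc <- fs2 * tan(pi * cutoff_hz / sample_rate_hz)  # prewarped rad/s
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP poles
  p_hp <- wc / p_lp                                          # analog HP poles
  z <- (fs2 + p_hp) / (fs2 - p_hp)                           # bilinear

  sections <- list()
  used <- rep(FALSE, order)
  for (i in k) {
    if (used[i]) next
    if (abs(Im(z[i])) < 1e-9) {
      a <- c(1, -Re(z[i]), 0)
      b <- c(1, -1, 0)
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(z - Conj(z[i])) < 1e-9 & seq_len(order) != i)[1]
      a <- c(1, -2 * Re(z[i]), Mod(z[i])^2)
      b <- c(1, -2, 1)
      used[c(i, j)] <- TRUE
    }
    gain <- (a[1] - a[2] + a[3]) / (b[1] - b[2] + b[3])  # |H| = 1 at Nyquist
    sections[[length(sections) + 1L]] <- list(b = b * gain, a = a)
  }
  sections
}

sosfilt <- function(sections, x) {
  for (s in sections) x <- apply_arma(x, s$b, s$a)
  x
}

#' Zero-phase Butterworth high-pass filter
#'
#' Removes slow drifts from a continuous LFP series with a ninth-order
#' Butterworth high-pass (0.5 Hz cutoff by default), applied
#' forward-backward for zero phase so evoked-component latencies are
#' untouched. The series is extended by odd reflection at both ends before
#' filtering to suppress edge transients.
#'
#' @param x Numeric voltage series, or an `lfp_recording` (all channels are
#'   filtered in place).
#' @param sample_rate_hz Sampling rate (taken from the recording when one is
#'   given).
#' @param order Filter order (default 9).
#' @param cutoff_hz High-pass cutoff (default 0.5 Hz).
#' @return The filtered series (or recording).
#' @export
lfp_highpass <- function(x, sample_rate_hz = 1000, order = 9, cutoff_hz = 0.5) {
  if (inherits(x, "lfp_recording")) {
    for (ch in names(x$channels)) {
      x$channels[[ch]] <- lfp_highpass(x$channels[[ch]], x$sample_rate_hz,
                                       order, cutoff_hz)
    }
    return(x)
  }
  n <- length(x)
  pad <- min(n - 1L, 3L * round(sample_rate_hz / cutoff_hz))
  if (n <= 3L * order || pad < 3L * order)
    stop_veptime("series too short for the filter's padding requirement")
  sos <- butter_highpass_sos(order, cutoff_hz, sample_rate_hz)
  x <- x - mean(x)  # the filter removes DC; demeaning keeps roundoff small
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- sosfilt(sos, xp)
  y <- rev(sosfilt(sos, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# closed-form magnitude response of the analog Butterworth high-pass
#' Analytic Butterworth high-pass gain
#'
#' Single-pass magnitude response `1 / sqrt(1 + (cutoff/f)^(2 order))` used
#' as the reference in filter tests.
#'
#' @param f_hz Frequency, Hz.
#' @param cutoff_hz Cutoff, Hz.
#' @param order Filter order.
#' @return Gain in `[0, 1]`.
#' @export
butterworth_gain <- function(f_hz, cutoff_hz = 0.5, order = 9) {
  1 / sqrt(1 + (cutoff_hz / f_hz)^(2 * order))
}

# --- fixed-window Fourier power -------------------------------------------

#' Power spectrum of one trial segment
#'
#' Computes the Fourier power of one fixed analysis segment (canonically the
#' 1 s stationary window beginning 0.5 s after stimulus onset, giving exactly
#' 1 Hz bin spacing at 1 kHz). No taper is applied. Power is the squared
#' magnitude of the amplitude-normalised coefficients `|fft(x)/N|^2`, so the
#' full two-sided set sums to the mean squared voltage (Parseval) and an
#' integer-frequency sinusoid of amplitude `a` contributes `a^2/4` to its
#' one-sided bin. The one-sided spectrum is cropped to `crop_hz` (default
#' 1-100 Hz).
#'
#' @param x Numeric segment (voltage, uV), e.g. one row of a cropped trial
#'   matrix.
#' @param sample_rate_hz Sampling rate.
#' @param window_ms Metadata: the segment's position relative to stimulus
#'   onset.
#' @param crop_hz Length-2 inclusive frequency bounds of the retained bins;
#'   `NULL` keeps all one-sided bins from 0 to Nyquist.
#' @return A `power_spectrum`: `freqs_hz`, `power_uv2`, `df_hz` (bin
#'   spacing, `1/segment seconds`), `n_trials = 1`, `window_ms`, and
#'   `total_power_uv2` (the two-sided Parseval sum `mean(x^2)`).
#' @export
trial_spectrum <- function(x, sample_rate_hz = 1000,
                           window_ms = c(500, 1500), crop_hz = c(1, 100)) {
  n <- length(x)
  if (n < 2L) stop_veptime("segment too short for a spectrum")
  co <- stats::fft(x) / n
  pw <- Mod(co)^2
  df <- sample_rate_hz / n
  n_half <- floor(n / 2)
  freqs <- (0:n_half) * df
  power <- pw[1:(n_half + 1L)]
  if (!is.null(crop_hz)) {
    sel <- freqs >= crop_hz[1] - 1e-9 & freqs <= crop_hz[2] + 1e-9
    if (!any(sel)) stop_veptime("crop band contains no frequency bins")
    freqs <- freqs[sel]
    power <- power[sel]
  }
  structure(
    list(freqs_hz = freqs, power_uv2 = power, df_hz = df, n_trials = 1L,
         window_ms = window_ms, total_power_uv2 = sum(pw)),
    class = "power_spectrum"
  )
}

#' Pointwise average of per-trial spectra
#'
#' @param spectra List of `power_spectrum` objects on identical frequency
#'   grids.
#' @return A `power_spectrum` with pointwise mean power and `n_trials`
#'   summed.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  f0 <- spectra[[1]]$freqs_hz
  for (s in spectra) {
    if (!isTRUE(all.equal(s$freqs_hz, f0)))
      stop_veptime("spectra are on different frequency grids")
  }
  out <- spectra[[1]]
  out$power_uv2 <- Reduce(`+`, lapply(spectra, `[[`, "power_uv2")) / length(spectra)
  out$total_power_uv2 <- mean(vapply(spectra, `[[`, 0, "total_power_uv2"))
  out$n_trials <- sum(vapply(spectra, `[[`, 0L, "n_trials"))
  out
}

#' Band power
#'
#' Sum of the power in all bins with `lo <= f <= hi` (both bounds
#' inclusive); canonically 1-30 Hz.
#'
#' @param spectrum A `power_spectrum`.
#' @param lo,hi Band bounds in Hz.
#' @return Band power in uV^2.
#' @export
band_power <- function(spectrum, lo = 1, hi = 30) {
  sel <- spectrum$freqs_hz >= lo - 1e-9 & spectrum$freqs_hz <= hi + 1e-9
  if (!any(sel)) stop_veptime("band contains no frequency bins")
  sum(spectrum$power_uv2[sel])
}

#' Trial-averaged stationary-window band power for one recording
#'
#' High-pass filters the continuous record (0.5 Hz, ninth order,
#' zero-phase), epochs the stationary window after each aligned stimulus,
#' computes the per-trial power spectrum, trial-averages, and sums the
#' band.
#'
#' @param recording An `lfp_recording`.
#' @param channel Channel name.
#' @param window_ms Stationary window relative to stimulus onset (default
#'   500-1500 ms).
#' @param band Length-2 inclusive band bounds, Hz (default 1-30).
#' @param highpass Apply the continuous-record high-pass first?
#' @param seq_positions Alignment events (default the first sequence
#'   element).
#' @return List with `band_power_uv2`, the trial-averaged `spectrum`, and
#'   `n_trials`.
#' @export
session_band_power <- function(recording, channel = "V1L",
                               window_ms = c(500, 1500), band = c(1, 30),
                               highpass = TRUE, seq_positions = 1L) {
  v <- recording$channels[[channel]]
  if (is.null(v)) stop_veptime("channel '", channel, "' not in recording")
  if (highpass)
    v <- lfp_highpass(v, recording$sample_rate_hz)
  rec <- recording
  rec$channels[[channel]] <- v
  tm <- extract_epochs(rec, window_ms, channel = channel,
                       seq_positions = seq_positions)
  spectra <- lapply(seq_len(nrow(tm$values)), function(i) {
    trial_spectrum(tm$values[i, ], rec$sample_rate_hz, window_ms)
  })
  avg <- average_spectra(spectra)
  list(band_power_uv2 = band_power(avg, band[1], band[2]),
       spectrum = avg, n_trials = avg$n_trials)
}
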