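#' Search window for one named VEP component
#'
#' @param name Component label (`"A1"`, `"A2"`, `"B1"`, ...).
#' @param search_window_ms Length-2 `(lo, hi)` in ms relative to the onset of
#'   the component's driving stimulus.
#' @param driving_role Role label of the driving stimulus.
#' @param onset_offset_ms Onset of the driving stimulus relative to the
#'   epoch's alignment event (e.g. the B components of a 300 ms sequence have
#'   offset 300 when epochs are aligned to stimulus A).
#' @param measure_positivity Also quantify the post-trough positivity
#'   (relative to the voltage at alignment time 0)?
#' @return A `component_spec` list.
#' @export
component_spec <- function(name, search_window_ms, driving_role = "A",
                           onset_offset_ms = 0, measure_positivity = FALSE) {
  if (search_window_ms[1] >= search_window_ms[2])
    stop_veptime("component search window must satisfy lo < hi")
  structure(
    list(name = name, search_window_ms = as.numeric(search_window_ms),
         driving_role = driving_role,
         onset_offset_ms = as.numeric(onset_offset_ms),
         measure_positivity = isTRUE(measure_positivity)),
    class = "component_spec"
  )
}

#' Default component windows for a protocol
#'
#' Convention (configurable): the fast component ("1") is searched
#' 20-120 ms after its own stimulus onset, the slow component ("2")
#' 120-320 ms, capped at the next stimulus onset for sequence elements.
#' With 150 ms elements the slow lead component and the fast follower
#' overlap in time, so a single composite window (0-120 ms after the second
#' element's onset) is returned for the second element and no "2" components
#' are emitted: short stimuli cannot resolve them.
#'
#' @param protocol A `session_protocol` (or a kind string) used to determine
#'   element roles and stimulus duration.
#' @param stimulus_duration_ms Element duration, taken from the protocol when
#'   one is given.
#' @param n_elements How many leading sequence elements to cover (default 2;
#'   the slow components of later elements are rarely analysed).
#' @return List of [component_spec()]s.
#' @export
default_component_specs <- function(protocol, stimulus_duration_ms = NULL,
                                    n_elements = 2L) {
  if (inherits(protocol, "session_protocol")) {
    kind <- protocol$kind
    dur <- protocol$stimulus_duration_ms
    first <- protocol$events[protocol$events$trial == 1L, ]
    roles <- first$role[order(first$seq_position)]
  } else {
    kind <- protocol
    dur <- stimulus_duration_ms %||% 300
    roles <- switch(kind,
      ABCD = c("A", "B", "C", "D"), DCBA = c("D", "C", "B", "A"),
      AXXX = c("A", "X", "X", "X"), NXXX = c("N", "X", "X", "X"),
      SINGLE = "A", PHASE_REVERSAL = "X")
  }
  n_elements <- min(n_elements, length(roles))
  specs <- list()
  for (j in seq_len(n_elements)) {
    off <- (j - 1) * dur
    r <- roles[j]
    if (j == 1L || dur >= 300) {
      hi2 <- if (j < length(roles)) min(320, dur) else 320
      specs[[length(specs) + 1L]] <-
        component_spec(paste0(r, "1"), c(20, 120), r, off)
      # the slow component needs room for its 160-190 ms trough; short
      # elements cannot resolve it
      if (hi2 >= 220)
        specs[[length(specs) + 1L]] <-
          component_spec(paste0(r, "2"), c(120, hi2), r, off,
                         measure_positivity = j == 1L)
    } else {
      # short stimuli: composite window over the overlapping lead-2/follow-1
      specs[[length(specs) + 1L]] <-
        component_spec(paste0(r, "1"), c(0, 120), r, off)
    }
  }
  specs
}

# smoothed waveform + selection for a window (absolute epoch time)
window_slice <- function(vep, window_ms, smooth_ms = 0) {
  t <- vep_time(vep)
  sel <- which(t >= window_ms[1] & t < window_ms[2])
  if (length(sel) == 0L) stop_veptime("search window contains no samples")
  v <- vep$waveform
  if (smooth_ms > 0) {
    width <- max(1L, round(smooth_ms * vep$sample_rate_hz / 1000))
    v <- boxcar_smooth(v, width)
  }
  list(t = t, v = v, sel = sel)
}

#' Latency of the maximal negative-going peak
#'
#' Returns the time of the minimum voltage inside the search window, in ms
#' on the epoch's time axis (i.e. relative to the alignment-event onset).
#' Ties break toward the earliest sample. A flat window (no peak) is
#' unquantifiable and returns `NA`.
#'
#' @param vep A [average_vep()] result.
#' @param search_window_ms Half-open `(lo, hi)` window on the epoch time
#'   axis, ms.
#' @param smooth_ms Width of a centred boxcar applied before peak picking
#'   (0 = none). Smoothing stabilises the estimate on noisy averages and is
#'   exact for symmetric troughs.
#' @param refine Use 3-point parabolic interpolation around the minimum for
#'   sub-sample latency.
#' @return Latency in ms, or `NA_real_` if unquantifiable.
#' @export
vep_latency <- function(vep, search_window_ms, smooth_ms = 0, refine = FALSE) {
  ws <- window_slice(vep, search_window_ms, smooth_ms)
  vs <- ws$v[ws$sel]
  if (diff(range(vs)) < 1e-12) return(NA_real_)
  i <- which.min(vs)
  lat <- ws$t[ws$sel[i]]
  if (refine) {
    gi <- ws$sel[i]
    if (gi > 1L && gi < length(ws$v)) {
      a <- ws$v[gi - 1L]; b <- ws$v[gi]; cc <- ws$v[gi + 1L]
      den <- a - 2 * b + cc
      if (den > 0) {
        d <- (a - cc) / (2 * den)
        lat <- lat + d * 1000 / vep$sample_rate_hz
      }
    }
  }
  lat
}

#' Peak-to-peak VEP magnitude
#'
#' Voltage difference between the peak negativity in the window and the peak
#' positivity occurring *after* it (through the window end); non-negative by
#' construction. Flat windows, or windows whose minimum falls on the final
#' sample (leaving no room for the positivity), are unquantifiable (`NA`).
#'
#' @inheritParams vep_latency
#' @return Magnitude in uV, or `NA_real_`.
#' @export
vep_magnitude <- function(vep, search_window_ms, smooth_ms = 0) {
  ws <- window_slice(vep, search_window_ms, smooth_ms)
  vs <- ws$v[ws$sel]
  if (diff(range(vs)) < 1e-12) return(NA_real_)
  i <- which.min(vs)
  if (i == length(vs)) return(NA_real_)
  max(vs[i:length(vs)]) - vs[i]
}

#' Positivity of the slow (N2/A2) component
#'
#' The positive deflection following the component's trough, measured
#' relative to the voltage at the alignment-event onset (epoch time 0).
#' Insensitive to DC offsets by construction.
#'
#' @param vep A [average_vep()] result whose window covers time 0.
#' @param a2_spec [component_spec()] of the slow component.
#' @param smooth_ms Boxcar width for trough localisation (the onset voltage
#'   and the maximum are read from the raw waveform).
#' @return Positivity in uV, or `NA_real_` if the trough is unquantifiable.
#' @export
a2_positivity <- function(vep, a2_spec, smooth_ms = 0) {
  stopifnot(inherits(a2_spec, "component_spec"))
  t <- vep_time(vep)
  if (min(t) > 0 || max(t) < 0)
    stop_veptime("epoch must include the alignment onset (time 0)")
  w <- a2_spec$search_window_ms + a2_spec$onset_offset_ms
  t_neg <- vep_latency(vep, w, smooth_ms = smooth_ms)
  if (is.na(t_neg)) return(NA_real_)
  v0 <- vep$waveform[which.min(abs(t))]
  sel <- t >= t_neg & t < w[2]
  max(vep$waveform[sel]) - v0
}

#' Quantify a list of VEP components on one trial-averaged epoch
#'
#' Applies [vep_latency()] and [vep_magnitude()] inside each component's
#' search window (shifted by the component's driving-stimulus onset within
#' the epoch) and [a2_positivity()] where requested. Latencies are reported
#' relative to the component's own driving stimulus (`latency_ms`) and, as
#' an auxiliary, relative to the alignment event (`latency_from_align_ms`).
#'
#' @param vep A [average_vep()] result.
#' @param specs List of [component_spec()]s with non-overlapping absolute
#'   windows.
#' @param smooth_ms Boxcar width for latency picking (default 13 ms; robust
#'   peak picking on noisy 200-trial averages).
#' @param refine Parabolic sub-sample refinement (default `TRUE`).
#' @return Tibble: component, driving_role, latency_ms,
#'   latency_from_align_ms, magnitude_uv, positivity_uv, n_trials, valid.
#' @export
component_measures <- function(vep, specs, smooth_ms = 13, refine = TRUE) {
  if (inherits(specs, "component_spec")) specs <- list(specs)
  # overlapping windows are a spec error
  wins <- lapply(specs, function(s) s$search_window_ms + s$onset_offset_ms)
  if (length(wins) > 1L) {
    ord <- order(vapply(wins, `[`, 0, 1L))
    for (j in seq_len(length(wins) - 1L)) {
      if (wins[[ord[j + 1L]]][1] < wins[[ord[j]]][2])
        stop_veptime("component search windows may not overlap")
    }
  }
  rows <- lapply(specs, function(s) {
    w <- s$search_window_ms + s$onset_offset_ms
    lat_abs <- vep_latency(vep, w, smooth_ms = smooth_ms, refine = refine)
    mag <- vep_magnitude(vep, w, smooth_ms = 0)
    pos <- if (s$measure_positivity)
      a2_positivity(vep, s, smooth_ms = smooth_ms) else NA_real_
    tibble::tibble(
      component = s$name, driving_role = s$driving_role,
      latency_ms = lat_abs - s$onset_offset_ms,
      latency_from_align_ms = lat_abs,
      magnitude_uv = mag, positivity_uv = pos,
      n_trials = vep$n_trials,
      valid = !is.na(lat_abs) && !is.na(mag) && vep$n_trials >= 50L
    )
  })
  dplyr::bind_rows(rows)
}

#' Sequence magnitude: mean of the four element magnitudes
#'
#' @param magnitudes Numeric vector of exactly four per-element peak-to-peak
#'   magnitudes (uV); missing values are an error, since an unquantifiable
#'   element invalidates the session's sequence magnitude.
#' @return Mean magnitude in uV.
#' @export
sequence_magnitude <- function(magnitudes) {
  if (length(magnitudes) != 4L)
    stop_veptime("sequence magnitude requires exactly four element magnitudes")
  if (anyNA(magnitudes))
    stop_veptime("sequence magnitude is undefined with missing elements")
  mean(magnitudes)
}

#' Component latency in consecutive trial blocks
#'
#' Splits the trials of a session into contiguous blocks (trials 1-50,
#' 51-100, ... by default), trial-averages each block and quantifies the
#' component latency, exposing within-session drift.
#'
#' @param matrix A `trial_matrix`.
#' @param spec A [component_spec()].
#' @param block_size Trials per block; the trial count must be divisible by
#'   it (no partial blocks).
#' @param smooth_ms,refine Passed to [vep_latency()].
#' @return Tibble with `block` and `latency_ms` (own-onset).
#' @export
block_latencies <- function(matrix, spec, block_size = 50L,
                            smooth_ms = 13, refine = TRUE) {
  stopifnot(inherits(matrix, "trial_matrix"), inherits(spec, "component_spec"))
  n <- nrow(matrix$values)
  if (n %% block_size != 0L)
    stop_veptime("trial count (", n, ") is not divisible by block_size (",
                 block_size, ")")
  w <- spec$search_window_ms + spec$onset_offset_ms
  n_blocks <- n %/% block_size
  lat <- vapply(seq_len(n_blocks), function(b) {
    rows <- ((b - 1L) * block_size + 1L):(b * block_size)
    v <- average_vep(matrix, rows)
    vep_latency(v, w, smooth_ms = smooth_ms, refine = refine) -
      spec$onset_offset_ms
  }, 0)
  tibble::tibble(block = seq_len(n_blocks), latency_ms = lat)
}

#' Average a measure across hemispheres
#'
#' Bilateral V1 measures are averaged per subject; when the signal in one
#' hemisphere is unusable only the valid hemisphere is kept. Accepts either
#' two numeric scalars with a validity flag pair, or two one-row measure
#' tibbles (as produced by [component_measures()]) sharing the same
#' component, whose numeric columns are averaged over the valid inputs.
#'
#' @param left,right The two hemisphere measures.
#' @param valid Logical length-2 validity flags (for numeric input; tibbles
#'   carry their own `valid` column).
#' @return The averaged measure (same type as the inputs). Both hemispheres
#'   invalid is an error.
#' @export
average_hemispheres <- function(left, right, valid = c(TRUE, TRUE)) {
  if (is.numeric(left) && is.numeric(right)) {
    valid <- valid & !is.na(c(left, right))
    if (!any(valid)) stop_veptime("both hemispheres are invalid")
    return(mean(c(left, right)[valid]))
  }
  stopifnot(is.data.frame(left), is.data.frame(right),
            nrow(left) == 1L, nrow(right) == 1L)
  for (key in intersect(c("component", "day", "condition"),
                        intersect(names(left), names(right)))) {
    if (!identical(left[[key]], right[[key]]))
      stop_veptime("hemisphere measures disagree on '", key, "'")
  }
  ok <- c(isTRUE(left$valid), isTRUE(right$valid))
  if (!any(ok)) stop_veptime("both hemispheres are invalid")
  out <- left
  num <- vapply(left, is.numeric, TRUE)
  for (cn in names(left)[num]) {
    vals <- c(left[[cn]], right[[cn]])[ok]
    out[[cn]] <- mean(vals)
  }
  out$valid <- TRUE
  out
}

#' Across-day plasticity delta
#'
#' The amount of latency plasticity is the Day-4 value minus the Day-1
#' value; negative values mean the response sped up.
#'
#' @param day1,day4 Latencies (ms) on the first and last training day; both
#'   must be quantifiable.
#' @return `day4 - day1` in ms.
#' @export
plasticity_delta <- function(day1, day4) {
  if (anyNA(day1) || anyNA(day4))
    stop_veptime("plasticity delta requires quantifiable latencies on both days")
  day4 - day1
}

#' Detect a biphasic (two-trough) response
#'
#' Reports whether the window contains at least two local minima, each
#' deeper than `depth_fraction` of the global minimum and mutually separated
#' by at least `min_separation_ms`. Flat or everywhere-positive windows
#' return `FALSE`.
#'
#' @param vep A [average_vep()] result.
#' @param window_ms Search window on the epoch time axis.
#' @param depth_fraction Minimum trough depth as a fraction of the global
#'   minimum depth (default 0.5).
#' @param min_separation_ms Minimum spacing between reported troughs.
#' @param smooth_ms Boxcar width applied before minima detection.
#' @return List with `biphasic` (logical) and `minima_ms` (times of the
#'   retained troughs, deepest first).
#' @export
detect_biphasic <- function(vep, window_ms, depth_fraction = 0.5,
                            min_separation_ms = 20, smooth_ms = 5) {
  ws <- window_slice(vep, window_ms, smooth_ms)
  v <- ws$v[ws$sel]
  t <- ws$t[ws$sel]
  gmin <- min(v)
  if (gmin >= 0 || diff(range(v)) < 1e-12)
    return(list(biphasic = FALSE, minima_ms = numeric(0)))
  n <- length(v)
  is_min <- c(FALSE, v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n], FALSE)
  cand <- which(is_min & v <= depth_fraction * gmin)
  # include window-interior global minimum even if at an edge sample
  cand <- sort(union(cand, which.min(v)))
  if (length(cand) > 1L) {
    keep <- integer(0)
    for (i in cand[order(v[cand])]) {
      if (all(abs(t[i] - t[keep]) >= min_separation_ms)) keep <- c(keep, i)
    }
    cand <- keep
  }
  list(biphasic = length(cand) >= 2L, minima_ms = t[cand])
}

#' Tidy component measures for one simulated recording
#'
#' Convenience wrapper chaining [extract_epochs()] (aligned to the first
#' sequence element), [average_vep()] and [component_measures()], attaching
#' the recording's simulation metadata.
#'
#' @param recording An `lfp_recording` with cohort metadata.
#' @param channel Channel to quantify.
#' @param specs Component specs (default [default_component_specs()] for the
#'   recording's protocol).
#' @param window_ms Epoch window; default spans 100 ms of baseline to 500 ms
#'   past the last sequence element.
#' @param smooth_ms,refine Passed to [component_measures()].
#' @return Tibble of measures with subject/genotype/day/condition columns
#'   when present in the recording metadata.
#' @export
measure_session <- function(recording, channel = "ACC", specs = NULL,
                            window_ms = NULL, smooth_ms = 13, refine = TRUE) {
  prot <- recording$protocol
  specs <- specs %||% default_component_specs(prot)
  n_elem <- max(prot$events$seq_position)
  window_ms <- window_ms %||%
    c(-100, n_elem * prot$stimulus_duration_ms + 500)
  tm <- extract_epochs(recording, window_ms, channel = channel,
                       seq_positions = 1L)
  m <- component_measures(average_vep(tm), specs,
                          smooth_ms = smooth_ms, refine = refine)
  meta <- recording$meta
  for (f in c("subject", "genotype", "day", "condition", "scenario")) {
    if (!is.null(meta[[f]])) m[[f]] <- meta[[f]]
  }
  m$channel <- channel
  m
}
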