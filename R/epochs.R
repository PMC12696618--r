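#' Slice a continuous recording into event-aligned trials
#'
#' Builds the trials x samples voltage matrix for one channel, aligning each
#' selected event's onset to time 0. Windows are half-open `[start, end)` in
#' ms relative to onset, sampled at the recording rate.
#'
#' @param recording An `lfp_recording`.
#' @param window_ms Length-2 numeric `(start, end)` in ms relative to event
#'   onset; `start <= 0 <= end` is permitted but not required.
#' @param channel Channel name.
#' @param roles,orientations,seq_positions Optional event filters (kept events
#'   must match all supplied filters).
#' @param events Optional explicit event tibble overriding the protocol's.
#' @return A `trial_matrix`: `values` (trials x samples), `window_ms`,
#'   `sample_rate_hz`, `n_trials`, `channel`, and the selected `events`.
#' @export
extract_epochs <- function(recording, window_ms, channel = "ACC",
                           roles = NULL, orientations = NULL,
                           seq_positions = NULL, events = NULL) {
  stopifnot(inherits(recording, "lfp_recording"), length(window_ms) == 2L)
  if (window_ms[2] <= window_ms[1]) stop_veptime("window end must exceed start")
  if (!channel %in% names(recording$channels))
    stop_veptime("channel '", channel, "' not in recording")
  ev <- events %||% recording$protocol$events
  if (!is.null(roles)) ev <- ev[ev$role %in% roles, ]
  if (!is.null(orientations)) ev <- ev[ev$orientation_deg %in% orientations, ]
  if (!is.null(seq_positions)) ev <- ev[ev$seq_position %in% seq_positions, ]
  if (nrow(ev) == 0L) stop_veptime("no events match the requested selection")

  fs <- recording$sample_rate_hz
  v <- recording$channels[[channel]]
  nsamp <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  i0 <- round((ev$onset_ms - recording$t0_ms + window_ms[1]) * fs / 1000) + 1L
  if (any(i0 < 1L) || any(i0 + nsamp - 1L > length(v)))
    stop_veptime("requested epoch exceeds recording bounds")

  idx <- outer(i0, 0:(nsamp - 1L), `+`)
  structure(
    list(
      values = matrix(v[idx], nrow = nrow(ev)),
      window_ms = as.numeric(window_ms),
      sample_rate_hz = fs,
      n_trials = nrow(ev),
      channel = channel,
      alignment_role = paste(sort(unique(ev$role)), collapse = "/"),
      events = ev
    ),
    class = "trial_matrix"
  )
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("<trial_matrix> %s: %d trials x %d samples, window [%g, %g) ms\n",
              x$channel, nrow(x$values), ncol(x$values),
              x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Trial-average a trial matrix into a VEP
#'
#' Pointwise arithmetic mean over the selected trials.
#'
#' @param matrix A `trial_matrix` from [extract_epochs()].
#' @param trials Optional integer vector of row indices to average (default
#'   all); must be non-empty.
#' @return A `vep`: `waveform` (uV), `window_ms`, `sample_rate_hz`,
#'   `n_trials`, `channel`.
#' @export
average_vep <- function(matrix, trials = NULL) {
  stopifnot(inherits(matrix, "trial_matrix"))
  rows <- trials %||% seq_len(nrow(matrix$values))
  if (length(rows) == 0L) stop_veptime("trial subset is empty")
  structure(
    list(
      waveform = colMeans(matrix$values[rows, , drop = FALSE]),
      window_ms = matrix$window_ms,
      sample_rate_hz = matrix$sample_rate_hz,
      n_trials = length(rows),
      channel = matrix$channel
    ),
    class = "vep"
  )
}

#' @export
print.vep <- function(x, ...) {
  cat(sprintf("<vep> %s: %d samples, window [%g, %g) ms, n = %d trials\n",
              x$channel, length(x$waveform), x$window_ms[1], x$window_ms[2],
              x$n_trials))
  invisible(x)
}

# time axis of a vep (ms relative to alignment onset)
vep_time <- function(vep) {
  vep$window_ms[1] + (seq_along(vep$waveform) - 1L) * 1000 / vep$sample_rate_hz
}
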