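event_log_columns <- c("session_id", "day", "kind", "trial", "block",
                       "seq_position", "role", "orientation_deg",
                       "onset_ms", "duration_ms")

#' Write a protocol's event log to CSV
#'
#' One row per stimulus event with the schema: session_id, day, kind, trial,
#' block, seq_position, role, orientation_deg, onset_ms, duration_ms (UTF-8,
#' header required).
#'
#' @param protocol A `session_protocol`.
#' @param path Output CSV path.
#' @param session_id Identifier recorded in every row.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(protocol, path, session_id = "session1") {
  stopifnot(inherits(protocol, "session_protocol"))
  ev <- protocol$events
  df <- data.frame(
    session_id = session_id, day = protocol$day, kind = protocol$kind,
    trial = ev$trial, block = ev$block, seq_position = ev$seq_position,
    role = ev$role, orientation_deg = ev$orientation_deg,
    onset_ms = ev$onset_ms, duration_ms = ev$duration_ms
  )
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an event-log CSV back into a protocol
#'
#' Validates the schema and the onset monotonicity, then reconstructs a
#' `session_protocol` whose event fields round-trip exactly. Protocol-level
#' parameters (trial count, block size, stimulus duration, gray and
#' inter-block gaps) are recovered from the events themselves.
#'
#' @param path Event-log CSV path.
#' @return A `session_protocol`.
#' @export
read_event_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(event_log_columns, names(df))
  if (length(missing_cols) > 0L)
    stop_veptime("event log is missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  if (any(diff(df$onset_ms) <= 0))
    stop_veptime("event onsets must be strictly increasing")
  if (length(unique(df$kind)) != 1L || length(unique(df$day)) != 1L)
    stop_veptime("event log must describe a single session")

  events <- tibble::tibble(
    onset_ms = as.numeric(df$onset_ms),
    duration_ms = as.numeric(df$duration_ms),
    orientation_deg = as.numeric(df$orientation_deg),
    role = as.character(df$role),
    seq_position = as.integer(df$seq_position),
    trial = as.integer(df$trial),
    block = as.integer(df$block)
  )
  n_trials <- max(events$trial)
  block_size <- max(events$trial[events$block == 1L])
  first_trial <- events[events$trial == 1L, ]
  # gap between the first two sequences within a block, if any
  gray <- if (n_trials > 1L && block_size > 1L) {
    e1 <- events[events$trial == 1L, ]
    e2 <- events[events$trial == 2L, ]
    e2$onset_ms[1] - (max(e1$onset_ms) + e1$duration_ms[nrow(e1)])
  } else 1500
  ib <- if (max(events$block) > 1L) {
    last1 <- events[events$block == 1L, ]
    first2 <- events[events$block == 2L, ]
    first2$onset_ms[1] - (max(last1$onset_ms) + last1$duration_ms[nrow(last1)])
  } else 30000
  omap <- tapply(events$orientation_deg, events$role, function(x) x[1])

  structure(
    list(
      kind = df$kind[1], day = as.integer(df$day[1]), events = events,
      n_trials = n_trials, block_size = block_size,
      stimulus_duration_ms = events$duration_ms[1],
      gray_ms = gray, interblock_gap_ms = ib,
      lead_in_ms = events$onset_ms[1],
      orientation_map = stats::setNames(as.numeric(omap), names(omap)),
      lead_role = first_trial$role[1], seed = NULL,
      session_id = df$session_id[1]
    ),
    class = "session_protocol"
  )
}

# --- LFP container ---------------------------------------------------------

lfp_magic <- "VEPTIME-LFP1"

#' Write a recording to the self-describing binary LFP container
#'
#' Format: an ASCII magic line, a JSON header line (sample_rate_hz, t0_ms,
#' n_samples, channel names, dtype `float32`, little endian), then the
#' channel series concatenated as little-endian float32. Voltages are
#' stored in microvolts; storage is float32, so one write-read cycle
#' quantises doubles to float32 precision and is lossless thereafter.
#' The protocol travels separately as an event-log CSV.
#'
#' @param recording An `lfp_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(recording, path) {
  stopifnot(inherits(recording, "lfp_recording"))
  ns <- unique(vapply(recording$channels, length, 0L))
  if (length(ns) != 1L)
    stop_veptime("all channels must have the same length")
  header <- jsonlite::toJSON(list(
    sample_rate_hz = recording$sample_rate_hz,
    t0_ms = recording$t0_ms,
    n_samples = ns,
    channels = names(recording$channels),
    dtype = "float32", endian = "little"
  ), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(lfp_magic, "\n", header, "\n"), con, eos = NULL)
  for (ch in names(recording$channels)) {
    writeBin(as.numeric(recording$channels[[ch]]), con,
             size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read an LFP container
#'
#' @param path Container path from [write_lfp()].
#' @param protocol Optional `session_protocol` (or event-log CSV path) to
#'   attach, restoring event-clock alignment.
#' @return An `lfp_recording`.
#' @export
read_lfp <- function(path, protocol = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, lfp_magic))
    stop_veptime("not a veptime LFP container")
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (is.null(header$sample_rate_hz))
    stop_veptime("LFP container header lacks sample_rate_hz")
  n <- as.integer(header$n_samples)
  channels <- list()
  for (ch in header$channels) {
    v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    if (length(v) != n)
      stop_veptime("LFP container truncated in channel '", ch, "'")
    channels[[ch]] <- v
  }
  if (is.character(protocol)) protocol <- read_event_log(protocol)
  structure(
    list(sample_rate_hz = header$sample_rate_hz, t0_ms = header$t0_ms,
         channels = channels, protocol = protocol, meta = list()),
    class = "lfp_recording"
  )
}

#' Export a recording to plain CSV
#'
#' Long-format plain-text export (t_ms plus one column per channel) for
#' small fixtures and interoperability.
#'
#' @param recording An `lfp_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
lfp_to_csv <- function(recording, path) {
  n <- length(recording$channels[[1]])
  df <- data.frame(
    t_ms = recording$t0_ms + (seq_len(n) - 1L) * 1000 / recording$sample_rate_hz
  )
  for (ch in names(recording$channels)) df[[ch]] <- recording$channels[[ch]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
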