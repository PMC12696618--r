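#' Default orientation vocabulary (degrees)
#'
#' Role labels map to grating orientations: the familiar lead stimulus A is
#' 45 degrees; B, C, D and E are the remaining pseudorandom-pool
#' orientations; N is a novel orientation shown only in test sessions.
#'
#' @return Named numeric vector of orientations in degrees, in `[0, 180)`.
#' @export
default_orientation_map <- function() {
  c(A = 45, B = 105, C = 15, D = 75, E = 135, N = 165)
}

protocol_kinds <- c("ABCD", "DCBA", "AXXX", "NXXX", "SINGLE", "PHASE_REVERSAL")

#' Build a stimulus protocol (event log) for one session
#'
#' Generates the ordered stimulus events of one recording session. Six
#' protocol families are supported:
#' * `"ABCD"` / `"DCBA"`: four-element oriented-grating sequences; elements
#'   abut (no gap within a sequence) and sequences are separated by a gray
#'   period.
#' * `"AXXX"` / `"NXXX"`: a fixed lead element (A or the novel N) followed by
#'   three pseudorandomly ordered elements drawn without replacement from the
#'   B/C/D/E pool, so no element repeats within a sequence.
#' * `"SINGLE"`: one stimulus per trial followed by the gray period.
#' * `"PHASE_REVERSAL"`: contrast phase reversals at 2 Hz (one event every
#'   500 ms, no gray between reversals), 400 reversals in 4 blocks of 100.
#'
#' Trial-based kinds default to 200 trials in 4 blocks of 50 with a 30 s gray
#' gap between blocks and a 1.5 s gray period after each sequence.
#'
#' @param kind Protocol family: `"ABCD"`, `"DCBA"`, `"AXXX"`, `"NXXX"`,
#'   `"SINGLE"` or `"PHASE_REVERSAL"`.
#' @param day Training day, integer 1..4.
#' @param stimulus_duration_ms Duration of each stimulus element in ms
#'   (canonically 150, 300 or 1500 for trial-based kinds).
#' @param orientation_map Named vector mapping role labels to orientations in
#'   degrees; see [default_orientation_map()].
#' @param seed Integer seed; required for the pseudorandom `AXXX`/`NXXX`
#'   kinds, ignored otherwise.
#' @param n_trials Number of trials (sequences); 400 reversals for
#'   `PHASE_REVERSAL`.
#' @param block_size Trials per block (reversals per block for
#'   `PHASE_REVERSAL`).
#' @param gray_ms Gray-screen period after each sequence, ms.
#' @param interblock_gap_ms Gray gap separating blocks, ms (replaces the
#'   ordinary gray period after the last sequence of a block).
#' @param lead_in_ms Gray lead-in before the first stimulus, ms.
#' @param lead_role Role label of the lead/single stimulus (default `"A"`;
#'   use `"N"` for novel single-stimulus or phase-reversal test sessions).
#'
#' @return A `session_protocol` object: a list with the event tibble
#'   (`events`: onset_ms, duration_ms, orientation_deg, role, seq_position,
#'   trial, block) plus the protocol parameters.
#' @examples
#' p <- make_protocol("ABCD", day = 1, stimulus_duration_ms = 150)
#' nrow(p$events) # 800 stimulus events
#' @export
make_protocol <- function(kind = protocol_kinds,
                          day = 1L,
                          stimulus_duration_ms = 300,
                          orientation_map = default_orientation_map(),
                          seed = NULL,
                          n_trials = NULL,
                          block_size = NULL,
                          gray_ms = 1500,
                          interblock_gap_ms = 30000,
                          lead_in_ms = 2000,
                          lead_role = "A") {
  kind <- match.arg(kind)
  if (!is.numeric(day) || length(day) != 1L || !(day %in% 1:4))
    stop_veptime("day must be an integer in 1..4")
  day <- as.integer(day)

  if (kind == "PHASE_REVERSAL") {
    n_trials <- as.integer(n_trials %||% 400L)
    block_size <- as.integer(block_size %||% 100L)
    stimulus_duration_ms <- 500  # 2 Hz reversal spacing
  } else {
    n_trials <- as.integer(n_trials %||% 200L)
    block_size <- as.integer(block_size %||% 50L)
  }
  if (n_trials < 1L) stop_veptime("n_trials must be at least 1")
  if (block_size < 1L || n_trials %% block_size != 0L)
    stop_veptime("n_trials must be a positive multiple of block_size")
  assert_scalar_number(stimulus_duration_ms, "stimulus_duration_ms", positive = TRUE)
  assert_scalar_number(gray_ms, "gray_ms", positive = TRUE)
  assert_scalar_number(interblock_gap_ms, "interblock_gap_ms", positive = TRUE)
  if (!lead_role %in% names(orientation_map))
    stop_veptime("lead_role '", lead_role, "' not in orientation_map")

  roles_per_trial <- switch(kind,
    ABCD = c("A", "B", "C", "D"),
    DCBA = c("D", "C", "B", "A"),
    AXXX = ,
    NXXX = NULL,  # drawn below
    SINGLE = lead_role,
    PHASE_REVERSAL = "REVERSAL"
  )

  pseudo <- kind %in% c("AXXX", "NXXX")
  if (pseudo) {
    if (is.null(seed)) stop_veptime(kind, " requires a seed")
    lead <- if (kind == "AXXX") "A" else "N"
    pool <- c("B", "C", "D", "E")
    draws <- with_local_seed(seed, {
      replicate(n_trials, sample(pool, 3L), simplify = FALSE)
    })
  }

  n_elem <- if (kind %in% c("SINGLE", "PHASE_REVERSAL")) 1L else 4L
  dur <- stimulus_duration_ms

  onset <- numeric(n_trials * n_elem)
  role <- character(n_trials * n_elem)
  seq_position <- integer(n_trials * n_elem)
  trial <- integer(n_trials * n_elem)

  t <- lead_in_ms
  k <- 0L
  for (tr in seq_len(n_trials)) {
    trial_roles <- if (pseudo) c(lead, draws[[tr]]) else roles_per_trial
    for (j in seq_len(n_elem)) {
      k <- k + 1L
      onset[k] <- t + (j - 1L) * dur
      role[k] <- trial_roles[j]
      seq_position[k] <- j
      trial[k] <- tr
    }
    t <- t + n_elem * dur
    if (tr < n_trials) {
      at_block_end <- tr %% block_size == 0L
      if (kind == "PHASE_REVERSAL") {
        # reversals abut within a block; gray only between blocks
        t <- t + if (at_block_end) interblock_gap_ms else 0
      } else {
        t <- t + if (at_block_end) interblock_gap_ms else gray_ms
      }
    }
  }

  events <- tibble::tibble(
    onset_ms = onset,
    duration_ms = dur,
    orientation_deg = unname(orientation_map[role]),
    role = role,
    seq_position = seq_position,
    trial = trial,
    block = ((trial - 1L) %/% block_size) + 1L
  )
  if (kind == "PHASE_REVERSAL")
    events$orientation_deg <- unname(orientation_map[lead_role])
  if (anyNA(events$orientation_deg))
    stop_veptime("orientation_map is missing a role used by the protocol")

  structure(
    list(
      kind = kind, day = day, events = events,
      n_trials = n_trials, block_size = block_size,
      stimulus_duration_ms = dur, gray_ms = gray_ms,
      interblock_gap_ms = interblock_gap_ms, lead_in_ms = lead_in_ms,
      orientation_map = orientation_map, lead_role = lead_role,
      seed = seed
    ),
    class = "session_protocol"
  )
}

#' @export
print.session_protocol <- function(x, ...) {
  cat(sprintf(
    "<session_protocol> %s day %d: %d trials x %d element(s) (%g ms), %d blocks\n",
    x$kind, x$day, x$n_trials,
    max(x$events$seq_position), x$stimulus_duration_ms,
    max(x$events$block)
  ))
  invisible(x)
}

#' Validate the structural invariants of a protocol
#'
#' Checks strictly increasing onsets, abutting elements within sequences,
#' the gray period between sequences within a block, and the block count.
#' Called by tests and by [read_event_log()].
#'
#' @param protocol A `session_protocol`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_protocol <- function(protocol) {
  ev <- protocol$events
  if (any(diff(ev$onset_ms) <= 0))
    stop_veptime("event onsets must be strictly increasing")
  by_trial <- split(ev, ev$trial)
  for (tr in by_trial) {
    if (any(diff(tr$onset_ms) != tr$duration_ms[-nrow(tr)]))
      stop_veptime("elements within a sequence must abut")
  }
  n_blocks <- protocol$n_trials / protocol$block_size
  if (max(ev$block) != n_blocks)
    stop_veptime("block structure inconsistent with n_trials/block_size")
  invisible(TRUE)
}
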