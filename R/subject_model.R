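#' Default ACC component kernels for one stimulus
#'
#' Every stimulus drives a fast negativity (N1, trough ~60 ms) and a slow
#' negativity (N2, trough ~170 ms, within the empirically observed
#' 160-190 ms range) followed by a positivity. Amplitudes are configurable
#' conventions; only the latencies have an empirical anchor.
#'
#' @return Named list of [component_kernel_params()] (`N1`, `N2`).
#' @export
default_acc_components <- function() {
  list(
    N1 = component_kernel_params(60, 30, 10),
    N2 = component_kernel_params(170, 25, 12,
                                 pos_latency_ms = 260,
                                 pos_amplitude_uv = 10,
                                 pos_width_ms = 25)
  )
}

#' Default V1 component kernels for one stimulus
#'
#' A single large biphasic deflection (negativity ~75 ms, positivity
#' ~140 ms), the classical V1 VEP whose peak-to-peak magnitude expresses
#' SRP.
#'
#' @return Named list of [component_kernel_params()] (`N1`).
#' @export
default_v1_components <- function() {
  list(
    N1 = component_kernel_params(75, 80, 15,
                                 pos_latency_ms = 140,
                                 pos_amplitude_uv = 40,
                                 pos_width_ms = 25)
  )
}

#' Default per-channel, per-role kernel table
#'
#' @param roles Role labels covered by the model.
#' @return Nested list: channel (ACC, V1L, V1R) -> role -> component kernels.
#' @export
default_region_params <- function(roles = c("A", "B", "C", "D", "E", "N")) {
  acc <- stats::setNames(rep(list(default_acc_components()), length(roles)), roles)
  v1 <- stats::setNames(rep(list(default_v1_components()), length(roles)), roles)
  list(ACC = acc, V1L = v1, V1R = v1)
}

#' Default plasticity schedules for a genotype
#'
#' Wild-type (WT): the familiar-stimulus ACC N2 trough shifts -20 ms between
#' Day 1 and Day 2 and stays there (the largest latency changes occur between
#' the first two sessions); the N2 positivity is unchanged. AS model
#' (Ube3a m-/p+ regime): no latency shift, N2 positivity grows linearly to
#' x2 by Day 4. Both genotypes express V1 SRP: familiar-stimulus V1 kernel
#' amplitudes ramp to x1.5 by Day 4. All effects are restricted to the
#' familiar orientation when `specific` is `TRUE`.
#'
#' @param genotype `"WT"` or `"AS"`.
#' @return List of per-day schedules (`a2_shift_ms_by_day`,
#'   `a2_pos_gain_by_day`, `v1_gain_by_day`, `specific`).
#' @export
default_plasticity <- function(genotype = c("WT", "AS")) {
  genotype <- match.arg(genotype)
  list(
    a2_shift_ms_by_day = if (genotype == "WT") c(0, -20, -20, -20) else rep(0, 4),
    a2_pos_gain_by_day = if (genotype == "AS") c(1, 4 / 3, 5 / 3, 2) else rep(1, 4),
    v1_gain_by_day = c(1, 1.2, 1.35, 1.5),
    specific = TRUE
  )
}

#' Generative model of one simulated subject
#'
#' Bundles the component kernels per channel and role, the plasticity
#' schedules, the genotype, the noise model (white + pink), and the V1
#' stationary-window oscillation. Together with a [make_protocol()] event
#' log this fully determines a simulated recording.
#'
#' @param genotype `"WT"` or `"AS"`.
#' @param region_params Channel -> role -> kernel table; see
#'   [default_region_params()].
#' @param plasticity Per-day schedules; see [default_plasticity()].
#' @param noise List with `white_sd_uv` (Gaussian white noise SD, uV) and
#'   `pink_scale_uv` (1/f noise SD, uV). Defaults 20 and 10 uV make single
#'   trials unquantifiable while 200-trial averages are clean.
#' @param oscillation List describing the decaying oscillation added to V1
#'   channels in the 500-1500 ms post-onset stationary window: `freq_hz`,
#'   `amplitude_uv`, `decay_tau_ms`, and `familiar_gain_by_day` (amplitude
#'   gain applied to familiar-orientation trials, ramping to x3 by Day 4).
#' @param familiar_orientation Trained orientation in degrees (default 45).
#' @param orientation_map Role -> orientation vocabulary shared with the
#'   protocols.
#' @param sample_rate_hz Recording rate (default 1000).
#'
#' @return A `subject_model` (day field initialised to 1).
#' @export
subject_model <- function(genotype = c("WT", "AS"),
                          region_params = default_region_params(),
                          plasticity = default_plasticity(genotype),
                          noise = list(white_sd_uv = 20, pink_scale_uv = 10),
                          oscillation = list(freq_hz = 10, amplitude_uv = 15,
                                             decay_tau_ms = 600,
                                             familiar_gain_by_day = c(1, 5 / 3, 7 / 3, 3)),
                          familiar_orientation = 45,
                          orientation_map = default_orientation_map(),
                          sample_rate_hz = 1000) {
  genotype <- match.arg(genotype)
  stopifnot(all(c("ACC") %in% names(region_params)))
  if (any(plasticity$a2_pos_gain_by_day < 0) || any(plasticity$v1_gain_by_day < 0))
    stop_veptime("plasticity gains must be >= 0")
  structure(
    list(
      genotype = genotype,
      base_region_params = region_params,
      region_params = region_params,
      plasticity = plasticity,
      noise = noise,
      oscillation = oscillation,
      familiar_orientation = familiar_orientation,
      orientation_map = orientation_map,
      sample_rate_hz = sample_rate_hz,
      day = 1L
    ),
    class = "subject_model"
  )
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("<subject_model> %s, day %d, channels: %s\n",
              x$genotype, x$day, paste(names(x$region_params), collapse = ", ")))
  invisible(x)
}

#' Apply the plasticity schedules to obtain a day-specific model
#'
#' Returns the model with kernels evolved from the Day-1 baseline to `day`:
#' the ACC N2 trough latency of the familiar orientation is shifted by the
#' genotype's schedule, its positivity amplitude scaled, and all V1 kernel
#' amplitudes of the familiar orientation scaled by the SRP gain.
#' Non-familiar orientations are untouched when the model is
#' stimulus-specific. Day 1 returns the baseline unchanged. Evolution always
#' starts from the stored baseline, so calls do not compound.
#'
#' @param model A [subject_model()].
#' @param day Integer 1..4.
#' @param familiar_orientation Override of the model's trained orientation.
#' @return The day-specific `subject_model`.
#' @export
evolve_model <- function(model, day, familiar_orientation = NULL) {
  stopifnot(inherits(model, "subject_model"))
  if (!is.numeric(day) || length(day) != 1L || !(day %in% 1:4))
    stop_veptime("day must be an integer in 1..4")
  day <- as.integer(day)
  fam <- familiar_orientation %||% model$familiar_orientation
  pl <- model$plasticity
  rp <- model$base_region_params

  for (ch in names(rp)) {
    is_v1 <- grepl("^V1", ch)
    for (role in names(rp[[ch]])) {
      ori <- unname(model$orientation_map[role])
      if (isTRUE(pl$specific) && (is.na(ori) || ori != fam)) next
      comps <- rp[[ch]][[role]]
      if (is_v1) {
        g <- pl$v1_gain_by_day[day]
        for (cn in names(comps)) {
          comps[[cn]]$neg_amplitude_uv <- comps[[cn]]$neg_amplitude_uv * g
          comps[[cn]]$pos_amplitude_uv <- comps[[cn]]$pos_amplitude_uv * g
        }
      } else {
        if ("N2" %in% names(comps)) {
          comps$N2$neg_latency_ms <-
            comps$N2$neg_latency_ms + pl$a2_shift_ms_by_day[day]
          comps$N2$pos_amplitude_uv <-
            comps$N2$pos_amplitude_uv * pl$a2_pos_gain_by_day[day]
        }
      }
      rp[[ch]][[role]] <- comps
    }
  }
  model$region_params <- rp
  model$day <- day
  model
}
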