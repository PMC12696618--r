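.veptime_env <- new.env(parent = emptyenv())

# Paul Kellet's 3-pole pinking filter (1/f over the LFP band of interest).
pink_b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
pink_a <- c(1, -2.494956002, 2.017265875, -0.522189400)

pink_gain <- function() {
  g <- .veptime_env$pink_gain
  if (is.null(g)) {
    imp <- c(1, numeric(8191))
    h <- apply_arma(imp, pink_b, pink_a)
    g <- sqrt(sum(h^2))
    .veptime_env$pink_gain <- g
  }
  g
}

# direct-form II transposed ARMA filtering (compiled), zero initial state
apply_arma <- function(x, b, a) {
  .arma_filter(as.numeric(x), as.numeric(b), as.numeric(a))
}

#' Unit-variance 1/f ("pink") noise
#'
#' Gaussian white noise shaped by a three-pole pinking filter and scaled to
#' unit standard deviation. Consumes `n + 1000` normal deviates from the
#' current RNG stream (the first 1000 samples are a discarded filter
#' burn-in).
#'
#' @param n Number of samples.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n) {
  burn <- 1000L
  y <- apply_arma(rnorm(n + burn), pink_b, pink_a) / pink_gain()
  y[(burn + 1L):(burn + n)]
}

#' Simulate one continuous LFP recording
#'
#' Forward model: per channel, the voltage is the superposition of the
#' role-appropriate component kernels placed at every stimulus onset, plus
#' (V1 channels only) a decaying stationary-window oscillation
#' 500-1500 ms after each stimulus, plus white and pink noise. Gray periods
#' and inter-block gaps contain noise only. The recording is deterministic
#' given `seed`.
#'
#' Event roles are resolved through the model's orientation vocabulary, so a
#' DCBA event with orientation 45 deg is driven by the same kernels as the
#' familiar "A" stimulus. The oscillation amplitude of familiar-orientation
#' events is multiplied by the model's familiarity gain for the model's
#' current day.
#'
#' @param model A [subject_model()], typically day-evolved with
#'   [evolve_model()].
#' @param protocol A [make_protocol()] event log.
#' @param seed Integer seed for the noise.
#' @param channels Channels to synthesise (subset of the model's channels).
#'   Note the RNG stream is consumed per channel in the given order, so the
#'   same seed with different channel sets yields different noise.
#' @param tail_ms Noise-only tail appended after the last event, ms.
#' @return An `lfp_recording`: named channel list of voltage (uV, double),
#'   `sample_rate_hz`, `t0_ms = 0`, the protocol, and simulation metadata.
#' @export
simulate_session <- function(model, protocol, seed,
                             channels = names(model$region_params),
                             tail_ms = 2000) {
  stopifnot(inherits(model, "subject_model"),
            inherits(protocol, "session_protocol"))
  fs <- model$sample_rate_hz
  if (fs <= 0) stop_veptime("sample rate must be positive")
  ev <- protocol$events
  if (!all(channels %in% names(model$region_params)))
    stop_veptime("unknown channel requested")

  # resolve event orientation -> model role
  map <- model$orientation_map
  role_of <- names(map)[match(ev$orientation_deg, map)]
  if (anyNA(role_of))
    stop_veptime("protocol contains an orientation unknown to the model")

  total_ms <- max(ev$onset_ms + ev$duration_ms) + tail_ms
  n <- ceiling(total_ms * fs / 1000)
  onset_idx <- round(ev$onset_ms * fs / 1000) + 1L

  osc <- model$oscillation
  osc_wave <- NULL
  if (!is.null(osc) && osc$amplitude_uv > 0) {
    t_rel <- seq(0, 1000 - 1000 / fs, by = 1000 / fs)
    osc_wave <- osc$amplitude_uv * exp(-t_rel / osc$decay_tau_ms) *
      sin(2 * pi * osc$freq_hz * t_rel / 1000)
  }
  fam_gain <- if (!is.null(osc)) osc$familiar_gain_by_day[model$day] else 1

  voltage <- list()
  for (ch in channels) {
    v <- numeric(n)
    kt <- model$region_params[[ch]]
    # precompute the summed kernel waveform per role present
    waves <- list()
    for (r in unique(role_of)) {
      comps <- kt[[r]]
      if (is.null(comps)) stop_veptime("model has no kernels for role ", r)
      L <- ceiling(max(vapply(comps, kernel_support_end, 0)) * fs / 1000) + 1L
      tg <- (seq_len(L) - 1L) * 1000 / fs
      w <- numeric(L)
      for (cp in comps) w <- w + component_kernel(cp, tg)
      waves[[r]] <- w
    }
    for (r in names(waves)) {
      sel <- which(role_of == r)
      v <- .add_events(v, waves[[r]], onset_idx[sel], rep(1, length(sel)))
    }
    if (grepl("^V1", ch) && !is.null(osc_wave)) {
      off <- round(500 * fs / 1000)
      keep <- which(onset_idx + off <= n)
      gains <- ifelse(ev$orientation_deg[keep] == model$familiar_orientation,
                      fam_gain, 1)
      v <- .add_events(v, osc_wave, onset_idx[keep] + off, gains)
    }
    voltage[[ch]] <- v
  }

  with_local_seed(seed, {
    for (ch in channels) {
      if (model$noise$white_sd_uv > 0)
        voltage[[ch]] <- voltage[[ch]] + model$noise$white_sd_uv * rnorm(n)
      if (model$noise$pink_scale_uv > 0)
        voltage[[ch]] <- voltage[[ch]] + model$noise$pink_scale_uv * pink_noise(n)
    }
  })

  structure(
    list(
      sample_rate_hz = fs,
      t0_ms = 0,
      channels = voltage,
      protocol = protocol,
      meta = list(genotype = model$genotype, day = model$day, seed = seed)
    ),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<lfp_recording> %d channel(s) [%s], %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              n, x$sample_rate_hz, n / x$sample_rate_hz))
  invisible(x)
}

cohort_scenarios <- c("sequence-150", "sequence-300", "pseudorandom",
                      "single-300", "single-1500", "genotype-contrast")

scenario_design <- function(scenario) {
  switch(scenario,
    "sequence-150" = list(kind = "ABCD", dur = 150, novel_kind = "DCBA",
                          novel_dur = 150, genotypes = "WT", omap = default_orientation_map()),
    "sequence-300" = list(kind = "ABCD", dur = 300, novel_kind = "DCBA",
                          novel_dur = 300, genotypes = "WT", omap = default_orientation_map()),
    "pseudorandom" = list(kind = "AXXX", dur = 300, novel_kind = "NXXX",
                          novel_dur = 300, genotypes = "WT", omap = default_orientation_map()),
    "single-300" = list(kind = "SINGLE", dur = 300, novel_kind = "SINGLE",
                        novel_dur = 300, genotypes = "WT",
                        omap = c(default_orientation_map()[1:5], N = 135)),
    "single-1500" = list(kind = "SINGLE", dur = 1500, novel_kind = "SINGLE",
                         novel_dur = 1500, genotypes = "WT",
                         omap = c(default_orientation_map()[1:5], N = 135)),
    "genotype-contrast" = list(kind = "ABCD", dur = 300, novel_kind = "DCBA",
                               novel_dur = 300, genotypes = c("WT", "AS"),
                               omap = default_orientation_map()),
    stop_veptime("unknown scenario '", scenario, "'")
  )
}

#' Simulate a cohort of subjects across training days
#'
#' Draws one independent [subject_model()] per subject from configured
#' population distributions (kernel latencies and log-amplitudes jittered,
#' the WT latency-shift total jittered across subjects), evolves it per day,
#' and simulates the familiar-protocol session of every training day (plus,
#' optionally, the novel-stimulus session on the final day). A ground-truth
#' table records every kernel parameter per subject, day, channel, role and
#' component.
#'
#' Scenarios: `"sequence-150"`, `"sequence-300"` (ABCD, DCBA novel),
#' `"pseudorandom"` (AXXX, NXXX novel), `"single-300"`, `"single-1500"`
#' (single orientation, novel 135 deg), `"genotype-contrast"` (ABCD 300 ms,
#' WT and AS groups of `n_per_group` each).
#'
#' @param scenario Scenario name (see above).
#' @param n_per_group Subjects per genotype group.
#' @param days Training days simulated (subset of 1..4).
#' @param seed Master seed; all protocol, model and noise randomness derives
#'   from it, so identical calls are bit-identical.
#' @param channels Channels to simulate.
#' @param include_novel_day4 Also simulate the novel-stimulus session on the
#'   last requested day.
#' @param population Population-variability parameters:
#'   `latency_sd_ms` (SD of the ACC N2 trough latency across subjects),
#'   `log_amp_sd` (SD of log amplitude scaling), `shift_sd_ms` (SD of the
#'   per-subject total latency shift), `gain_jitter_sd` (SD of per-day log
#'   jitter on the V1 gain).
#' @param callback Optional `function(recording, meta)`; when supplied each
#'   recording is passed to it right after simulation and *not* retained,
#'   keeping memory flat for large cohorts. The callback's return values are
#'   collected in `$results`.
#' @return A `vep_cohort` list: `recordings` (or `results`), `truth` tibble,
#'   `models`, `meta` tibble (subject, genotype, day, condition, seed), and
#'   the call parameters.
#' @export
simulate_cohort <- function(scenario, n_per_group, days = 1:4, seed = 1,
                            channels = c("ACC", "V1L", "V1R"),
                            include_novel_day4 = FALSE,
                            population = list(latency_sd_ms = 5,
                                              log_amp_sd = 0.15,
                                              shift_sd_ms = 3,
                                              gain_jitter_sd = 0.05),
                            callback = NULL) {
  des <- scenario_design(match.arg(scenario, cohort_scenarios))
  if (n_per_group < 1) stop_veptime("n_per_group must be >= 1")
  stopifnot(all(days %in% 1:4))
  days <- sort(unique(as.integer(days)))

  genotypes <- rep(des$genotypes, each = n_per_group)
  n_sub <- length(genotypes)
  n_cond <- length(days) + as.integer(include_novel_day4)

  draws <- with_local_seed(seed, {
    list(
      session_seeds = matrix(sample.int(.Machine$integer.max - 1L,
                                        n_sub * n_cond), nrow = n_sub),
      protocol_seeds = matrix(sample.int(.Machine$integer.max - 1L,
                                         n_sub * n_cond), nrow = n_sub),
      lat_jit = rnorm(n_sub, 0, population$latency_sd_ms),
      amp_jit = rnorm(n_sub, 0, population$log_amp_sd),
      shift_jit = rnorm(n_sub, 0, population$shift_sd_ms),
      gain_jit = matrix(rnorm(n_sub * 4, 0, population$gain_jitter_sd),
                        nrow = n_sub)
    )
  })

  models <- vector("list", n_sub)
  recordings <- list()
  results <- list()
  meta_rows <- list()
  truth_rows <- list()

  for (s in seq_len(n_sub)) {
    rp <- default_region_params()
    amp_scale <- exp(draws$amp_jit[s])
    for (ch in names(rp)) for (r in names(rp[[ch]])) {
      for (cn in names(rp[[ch]][[r]])) {
        kp <- rp[[ch]][[r]][[cn]]
        kp$neg_amplitude_uv <- kp$neg_amplitude_uv * amp_scale
        kp$pos_amplitude_uv <- kp$pos_amplitude_uv * amp_scale
        if (ch == "ACC" && cn == "N2")
          kp$neg_latency_ms <- kp$neg_latency_ms + draws$lat_jit[s]
        rp[[ch]][[r]][[cn]] <- kp
      }
    }
    pl <- default_plasticity(genotypes[s])
    if (genotypes[s] == "WT") {
      total <- -20 + draws$shift_jit[s]
      pl$a2_shift_ms_by_day <- c(0, rep(total, 3))
    }
    pl$v1_gain_by_day <- pl$v1_gain_by_day * exp(draws$gain_jit[s, ])
    model <- subject_model(genotype = genotypes[s],
                           region_params = rp, plasticity = pl,
                           orientation_map = des$omap)
    models[[s]] <- model

    conds <- data.frame(day = days, condition = "familiar")
    if (include_novel_day4)
      conds <- rbind(conds, data.frame(day = max(days), condition = "novel"))

    for (ci in seq_len(nrow(conds))) {
      d <- conds$day[ci]
      cond <- conds$condition[ci]
      kind <- if (cond == "familiar") des$kind else des$novel_kind
      dur <- if (cond == "familiar") des$dur else des$novel_dur
      lead <- if (cond == "novel" && kind == "SINGLE") "N" else "A"
      prot <- make_protocol(kind, day = d, stimulus_duration_ms = dur,
                            orientation_map = des$omap,
                            seed = draws$protocol_seeds[s, ci],
                            lead_role = lead)
      md <- evolve_model(model, d)
      rec <- simulate_session(md, prot, seed = draws$session_seeds[s, ci],
                              channels = channels)
      meta <- list(subject = s, genotype = genotypes[s], day = d,
                   condition = cond, scenario = scenario,
                   seed = draws$session_seeds[s, ci])
      rec$meta <- utils::modifyList(rec$meta, meta)
      meta_rows[[length(meta_rows) + 1L]] <- tibble::as_tibble(meta)
      if (cond == "familiar") {
        for (ch in channels) for (r in names(md$region_params[[ch]])) {
          for (cn in names(md$region_params[[ch]][[r]])) {
            kp <- md$region_params[[ch]][[r]][[cn]]
            truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
              subject = s, genotype = genotypes[s], day = d, channel = ch,
              role = r, component = cn,
              neg_latency_ms = kp$neg_latency_ms,
              neg_amplitude_uv = kp$neg_amplitude_uv,
              neg_width_ms = kp$neg_width_ms,
              pos_latency_ms = kp$pos_latency_ms,
              pos_amplitude_uv = kp$pos_amplitude_uv,
              pos_width_ms = kp$pos_width_ms
            )
          }
        }
      }
      if (is.null(callback)) {
        recordings[[length(recordings) + 1L]] <- rec
      } else {
        results[[length(results) + 1L]] <- callback(rec, meta)
      }
    }
  }

  structure(
    list(
      scenario = scenario,
      recordings = if (is.null(callback)) recordings else NULL,
      results = if (is.null(callback)) NULL else results,
      truth = dplyr::bind_rows(truth_rows),
      meta = dplyr::bind_rows(meta_rows),
      models = models,
      days = days, seed = seed, channels = channels,
      include_novel_day4 = include_novel_day4
    ),
    class = "vep_cohort"
  )
}

#' @export
print.vep_cohort <- function(x, ...) {
  cat(sprintf("<vep_cohort> scenario %s: %d subjects, days %s, %d session(s)\n",
              x$scenario, length(x$models),
              paste(x$days, collapse = ","), nrow(x$meta)))
  invisible(x)
}
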