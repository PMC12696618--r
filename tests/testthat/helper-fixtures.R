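# Shared fixture builders and independent oracles. The oracles evaluate the
# closed-form kernel model on a dense grid with their own Gaussian code so
# they stay independent of the package's waveform path.

quiet_model <- function(genotype = "WT", ...) {
  subject_model(genotype,
                noise = list(white_sd_uv = 0, pink_scale_uv = 0),
                oscillation = list(freq_hz = 10, amplitude_uv = 0,
                                   decay_tau_ms = 600,
                                   familiar_gain_by_day = rep(1, 4)),
                ...)
}

small_single <- function(day = 1, n_trials = 20, dur = 300, ...) {
  make_protocol("SINGLE", day = day, stimulus_duration_ms = dur,
                n_trials = n_trials, block_size = n_trials %/% 2, ...)
}

# dense-grid brute-force extrema of a sum of truncated Gaussian lobes
# lobes: list of c(latency, amplitude, sigma) (amplitude signed)
oracle_wave <- function(lobes, t) {
  v <- numeric(length(t))
  for (lb in lobes) {
    g <- exp(-(t - lb[1])^2 / (2 * lb[3]^2))
    g[abs(t - lb[1]) > 4 * lb[3]] <- 0
    v <- v + lb[2] * g
  }
  v
}

oracle_extrema <- function(lobes, window, step = 0.1) {
  t <- seq(window[1], window[2] - step, by = step)
  v <- oracle_wave(lobes, t)
  i_min <- which.min(v)
  post <- i_min:length(v)
  list(t_min = t[i_min], v_min = v[i_min],
       p2p = max(v[post]) - v[i_min])
}

# default-model kernel lobes as plain triples for the oracle
acc_lobes <- function(model = subject_model("WT"), role = "A") {
  comps <- model$region_params$ACC[[role]]
  out <- list()
  for (cp in comps) {
    out[[length(out) + 1L]] <- c(cp$neg_latency_ms, -cp$neg_amplitude_uv,
                                 cp$neg_width_ms)
    if (cp$pos_amplitude_uv > 0)
      out[[length(out) + 1L]] <- c(cp$pos_latency_ms, cp$pos_amplitude_uv,
                                   cp$pos_width_ms)
  }
  out
}

v1_lobes <- function(model = subject_model("WT"), role = "A") {
  comps <- model$region_params$V1L[[role]]
  out <- list()
  for (cp in comps) {
    out[[length(out) + 1L]] <- c(cp$neg_latency_ms, -cp$neg_amplitude_uv,
                                 cp$neg_width_ms)
    if (cp$pos_amplitude_uv > 0)
      out[[length(out) + 1L]] <- c(cp$pos_latency_ms, cp$pos_amplitude_uv,
                                   cp$pos_width_ms)
  }
  out
}

# wrap a bare voltage vector as a recording aligned to a protocol
as_recording <- function(v, protocol, fs = 1000, channel = "ACC") {
  structure(
    list(sample_rate_hz = fs, t0_ms = 0,
         channels = stats::setNames(list(v), channel),
         protocol = protocol, meta = list()),
    class = "lfp_recording"
  )
}

# wrap a trials x samples matrix as a trial_matrix
as_trial_matrix <- function(values, window, fs = 1000, channel = "ACC") {
  structure(
    list(values = values, window_ms = window, sample_rate_hz = fs,
         n_trials = nrow(values), channel = channel,
         alignment_role = "A", events = NULL),
    class = "trial_matrix"
  )
}

# wrap a waveform as a vep
as_vep <- function(waveform, window, fs = 1000, n_trials = 200L) {
  structure(
    list(waveform = waveform, window_ms = window, sample_rate_hz = fs,
         n_trials = n_trials, channel = "ACC"),
    class = "vep"
  )
}

# ACC A2 latency of one recording via the standard measurement chain
measure_a2 <- function(rec, window = c(120, 320)) {
  v <- average_vep(extract_epochs(rec, c(-100, 500), channel = "ACC",
                                  seq_positions = 1L))
  vep_latency(v, window, smooth_ms = 13, refine = TRUE)
}

# n x k matrix whose sample covariance is exactly spherical (hence
# compound-symmetric), for Greenhouse-Geisser edge cases
spherical_data <- function(n, k, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  X <- sweep(X, 2, colMeans(X))
  Q <- qr.Q(qr(X))
  sweep(Q, 2, colMeans(Q)) * sqrt(n - 1)
}
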