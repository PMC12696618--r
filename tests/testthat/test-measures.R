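test_that("latency is the earliest minimum and respects invariances", {
  t <- 0:499
  w <- -25 * exp(-(t - 185)^2 / (2 * 12^2))
  v <- as_vep(w, c(0, 500))
  expect_equal(vep_latency(v, c(120, 320)), 185)
  # positive scaling and DC offsets leave latency unchanged
  expect_equal(vep_latency(as_vep(3 * w + 7, c(0, 500)), c(120, 320)), 185)
  # ties break toward the earliest sample
  w2 <- numeric(500); w2[c(151, 201)] <- -10
  expect_equal(vep_latency(as_vep(w2, c(0, 500)), c(100, 300)), 150)
  # flat windows are unquantifiable
  expect_true(is.na(vep_latency(as_vep(numeric(500), c(0, 500)), c(100, 300))))
  # smoothing and parabolic refinement stay within one sample on a
  # symmetric trough
  expect_equal(vep_latency(v, c(120, 320), smooth_ms = 13, refine = TRUE),
               185, tolerance = 1)
})

test_that("magnitude is trough-to-following-peak and scales linearly", {
  t <- 0:499
  w <- -40 * exp(-(t - 170)^2 / (2 * 12^2)) +
    15 * exp(-(t - 260)^2 / (2 * 25^2))
  v <- as_vep(w, c(0, 500))
  m1 <- vep_magnitude(v, c(100, 400))
  orc <- oracle_extrema(list(c(170, -40, 12), c(260, 15, 25)), c(100, 400))
  expect_equal(m1, orc$p2p, tolerance = 0.05)       # one-sample grid error
  expect_equal(vep_magnitude(as_vep(2 * w, c(0, 500)), c(100, 400)), 2 * m1)
  expect_equal(vep_magnitude(as_vep(w + 9, c(0, 500)), c(100, 400)), m1)
  # a trace landing its minimum on the final sample is unquantifiable
  expect_true(is.na(vep_magnitude(as_vep(-t, c(0, 500)), c(100, 400))))
  # simple printed case: min -40 then max +15
  w3 <- numeric(500); w3[200] <- -40; w3[300] <- 15
  expect_equal(vep_magnitude(as_vep(w3, c(0, 500)), c(100, 400)), 55)
})

test_that("noiseless component measures match the programmed kernels", {
  m <- quiet_model()
  p <- make_protocol("ABCD", day = 1, stimulus_duration_ms = 300,
                     n_trials = 4, block_size = 2)
  rec <- simulate_session(m, p, seed = 1, channels = "ACC")
  v <- average_vep(extract_epochs(rec, c(-100, 1700), seq_positions = 1L))
  cm <- component_measures(v, default_component_specs(p))
  expect_equal(cm$component, c("A1", "A2", "B1", "B2"))
  expect_equal(cm$latency_ms, c(60, 170, 60, 170), tolerance = 1)
  # B components are reported relative to their own stimulus onset
  expect_equal(cm$latency_from_align_ms[3], 360, tolerance = 1)
  # magnitudes match the dense-grid oracle within a sample's interpolation
  orc <- oracle_extrema(acc_lobes(m), c(120, 300))
  expect_equal(cm$magnitude_uv[2], orc$p2p, tolerance = 0.1)
  expect_false(any(cm$valid))  # only 4 trials: below the 50-trial floor
})

test_that("zero-amplitude responses are flagged unquantifiable", {
  rp <- default_region_params()
  for (r in names(rp$ACC)) {
    for (cn in names(rp$ACC[[r]])) {
      rp$ACC[[r]][[cn]]$neg_amplitude_uv <- 0
      rp$ACC[[r]][[cn]]$pos_amplitude_uv <- 0
    }
  }
  m <- quiet_model(region_params = rp)
  p <- small_single(n_trials = 4)
  rec <- simulate_session(m, p, seed = 1, channels = "ACC")
  v <- average_vep(extract_epochs(rec, c(-100, 500)))
  cm <- component_measures(v, default_component_specs(p))
  expect_true(all(is.na(cm$latency_ms)))
  expect_false(any(cm$valid))
})

test_that("the 150 ms composite window lands on the brute-force minimum", {
  m <- quiet_model()
  p <- make_protocol("ABCD", day = 1, stimulus_duration_ms = 150,
                     n_trials = 4, block_size = 2)
  rec <- simulate_session(m, p, seed = 1, channels = "ACC")
  v <- average_vep(extract_epochs(rec, c(-100, 1100), seq_positions = 1L))
  specs <- default_component_specs(p)
  expect_equal(vapply(specs, `[[`, "", "name"), c("A1", "B1"))
  cm <- component_measures(v, specs, smooth_ms = 0, refine = FALSE)
  # independent oracle: all four elements' lobes summed on a 0.1 ms grid
  lobes <- list()
  for (off in c(0, 150, 300, 450)) {
    lobes <- c(lobes, lapply(acc_lobes(m), function(lb) lb + c(off, 0, 0)))
  }
  orc <- oracle_extrema(lobes, c(150, 270))
  expect_equal(cm$latency_from_align_ms[2], orc$t_min, tolerance = 1)
})

test_that("A2 positivity is measured from the trough relative to onset", {
  t <- -100:499
  w <- -25 * exp(-(t - 170)^2 / (2 * 12^2)) +
    12 * exp(-(t - 260)^2 / (2 * 25^2))
  v <- as_vep(w, c(-100, 500))
  spec <- component_spec("A2", c(120, 320), measure_positivity = TRUE)
  expect_equal(a2_positivity(v, spec), 12, tolerance = 0.05)
  # DC offsets cancel: onset voltage moves with the trace
  v2 <- as_vep(w + 5, c(-100, 500))
  expect_equal(a2_positivity(v2, spec), a2_positivity(v, spec))
  # epochs not covering time 0 are rejected
  expect_error(a2_positivity(as_vep(w[200:600], c(100, 500)), spec), "onset")
})

test_that("sequence magnitude is the symmetric mean of four elements", {
  expect_equal(sequence_magnitude(c(10, 20, 30, 40)), 25)
  expect_equal(sequence_magnitude(rep(7, 4)), 7)
  expect_equal(sequence_magnitude(c(40, 10, 30, 20)), 25)
  expect_error(sequence_magnitude(c(10, 20, 30)), "four")
  expect_error(sequence_magnitude(c(10, 20, 30, NA)), "missing")
})

test_that("block latencies require whole blocks and track drift", {
  # constructed within-session drift: trough moves -12 ms across blocks
  n <- 200; t <- 0:399
  troughs <- 180 - 4 * ((seq_len(n) - 1) %/% 50)
  vals <- t(vapply(troughs, function(mu) -25 * exp(-(t - mu)^2 / (2 * 12^2)),
                   numeric(400)))
  tm <- as_trial_matrix(vals, c(0, 400))
  spec <- component_spec("A2", c(120, 320))
  bl <- block_latencies(tm, spec)
  expect_equal(bl$block, 1:4)
  expect_true(all(diff(bl$latency_ms) < 0))
  expect_equal(bl$latency_ms[1] - bl$latency_ms[4], 12, tolerance = 1)
  expect_error(block_latencies(as_trial_matrix(vals[1:199, ], c(0, 400)), spec),
               "divisible")
})

test_that("stationary sessions give stable block latencies", {
  m <- subject_model("WT")
  p <- make_protocol("SINGLE", day = 1, stimulus_duration_ms = 300)
  spec <- component_spec("A2", c(120, 320))
  for (s in 1:3) {
    rec <- simulate_session(m, p, seed = 400 + s, channels = "ACC")
    tm <- extract_epochs(rec, c(-100, 500))
    bl <- block_latencies(tm, spec)
    expect_lt(max(bl$latency_ms) - min(bl$latency_ms), 8)
  }
})

test_that("hemisphere averaging respects validity flags", {
  expect_equal(average_hemispheres(100, 80), 90)
  expect_equal(average_hemispheres(100, 80, valid = c(TRUE, FALSE)), 100)
  expect_equal(average_hemispheres(NA_real_, 80), 80)
  expect_error(average_hemispheres(100, 80, valid = c(FALSE, FALSE)),
               "invalid")
  left <- tibble::tibble(component = "A2", latency_ms = 100,
                         magnitude_uv = 50, valid = TRUE)
  right <- tibble::tibble(component = "A2", latency_ms = 80,
                          magnitude_uv = 40, valid = TRUE)
  avg <- average_hemispheres(left, right)
  expect_equal(avg$latency_ms, 90)
  expect_equal(avg$magnitude_uv, 45)
  right$valid <- FALSE
  expect_equal(average_hemispheres(left, right)$latency_ms, 100)
  left$valid <- FALSE
  expect_error(average_hemispheres(left, right), "invalid")
  right$component <- "B1"
  expect_error(average_hemispheres(left, right), "component")
})

test_that("plasticity delta is day4 minus day1 and demands valid input", {
  expect_equal(plasticity_delta(185, 165), -20)
  expect_equal(plasticity_delta(170, 170), 0)
  expect_error(plasticity_delta(NA, 165), "quantifiable")
})

test_that("biphasic detection needs two deep, separated troughs", {
  t <- 0:299
  two <- -20 * exp(-(t - 80)^2 / (2 * 8^2)) - 20 * exp(-(t - 140)^2 / (2 * 8^2))
  res <- detect_biphasic(as_vep(two, c(0, 300)), c(0, 300))
  expect_true(res$biphasic)
  expect_equal(sort(res$minima_ms), c(80, 140), tolerance = 2)
  one <- -20 * exp(-(t - 80)^2 / (2 * 8^2))
  expect_false(detect_biphasic(as_vep(one, c(0, 300)), c(0, 300))$biphasic)
  expect_false(detect_biphasic(as_vep(numeric(300), c(0, 300)),
                               c(0, 300))$biphasic)
  # a shallow secondary dip below the depth fraction does not count
  shallow <- -20 * exp(-(t - 80)^2 / (2 * 8^2)) -
    4 * exp(-(t - 160)^2 / (2 * 8^2))
  expect_false(detect_biphasic(as_vep(shallow, c(0, 300)), c(0, 300))$biphasic)
})
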