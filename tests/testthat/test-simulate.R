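test_that("zero-noise simulation obeys superposition exactly", {
  m <- quiet_model()
  p <- small_single(n_trials = 10)
  rec <- simulate_session(m, p, seed = 1, channels = "ACC")
  tm <- extract_epochs(rec, c(0, 500), channel = "ACC")
  avg <- average_vep(tm)
  t <- seq(0, 499, by = 1)
  kern <- component_kernel(m$region_params$ACC$A$N1, t) +
    component_kernel(m$region_params$ACC$A$N2, t)
  expect_equal(avg$waveform, kern, tolerance = 1e-12)
  # every epoch identical to the kernel sum (epochs do not overlap here)
  expect_true(all(abs(sweep(tm$values, 2, kern)) < 1e-12))
  # gray periods are silent without noise
  ev <- p$events
  gap_idx <- round(ev$onset_ms[1] + 700):round(ev$onset_ms[2] - 50)
  expect_true(all(rec$channels$ACC[gap_idx] == 0))
})

test_that("identical seeds give bit-identical recordings and cohorts", {
  m <- subject_model("WT")
  p <- small_single(n_trials = 10)
  r1 <- simulate_session(m, p, seed = 42, channels = c("ACC", "V1L"))
  r2 <- simulate_session(m, p, seed = 42, channels = c("ACC", "V1L"))
  expect_identical(r1$channels, r2$channels)
  r3 <- simulate_session(m, p, seed = 43, channels = c("ACC", "V1L"))
  expect_false(identical(r1$channels$ACC, r3$channels$ACC))

  c1 <- simulate_cohort("single-300", 2, days = c(1, 2), seed = 5,
                        channels = "ACC")
  c2 <- simulate_cohort("single-300", 2, days = c(1, 2), seed = 5,
                        channels = "ACC")
  expect_identical(lapply(c1$recordings, `[[`, "channels"),
                   lapply(c2$recordings, `[[`, "channels"))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$recordings[[1]]$protocol$events,
                   c2$recordings[[1]]$protocol$events)
})

test_that("trial-average residual SD follows the 1/sqrt(n) law", {
  m <- subject_model("WT",
                     noise = list(white_sd_uv = 20, pink_scale_uv = 0),
                     oscillation = NULL)
  t <- seq(0, 499, by = 1)
  kern <- component_kernel(m$region_params$ACC$A$N1, t) +
    component_kernel(m$region_params$ACC$A$N2, t)
  for (n in c(25, 100, 200)) {
    p <- make_protocol("SINGLE", day = 1, stimulus_duration_ms = 300,
                       n_trials = n, block_size = n %/% 5)
    sds <- vapply(1:12, function(s) {
      rec <- simulate_session(m, p, seed = 1000 + s, channels = "ACC")
      avg <- average_vep(extract_epochs(rec, c(0, 500), channel = "ACC"))
      sd(avg$waveform - kern)
    }, 0)
    expect_lt(abs(mean(sds) - 20 / sqrt(n)) / (20 / sqrt(n)), 0.2)
  }
})

test_that("unknown orientations and channels are rejected", {
  m <- subject_model("WT")
  p <- small_single(n_trials = 4)
  p$events$orientation_deg[2] <- 33
  expect_error(simulate_session(m, p, seed = 1, channels = "ACC"),
               "orientation")
  expect_error(simulate_session(m, small_single(n_trials = 4), seed = 1,
                                channels = "HPC"), "channel")
})

test_that("cohorts honour the counting and ground-truth contracts", {
  co <- simulate_cohort("genotype-contrast", 2, days = c(1, 4), seed = 11,
                        channels = c("ACC", "V1L"))
  # 4 subjects x 2 days of familiar sessions
  expect_length(co$recordings, 8L)
  expect_equal(sort(unique(co$truth$channel)), c("ACC", "V1L"))
  per_channel <- co$truth[co$truth$channel == "ACC", ]
  expect_equal(nrow(unique(per_channel[, c("subject", "day")])), 8L)
  # one row per subject/day/channel/role/component
  expect_equal(nrow(per_channel),
               8L * length(unique(per_channel$role)) * 2L)
  expect_equal(sort(unique(co$truth$genotype)), c("AS", "WT"))

  # novel-day-4 sessions appear when requested
  con <- simulate_cohort("single-300", 2, days = c(1, 4), seed = 11,
                         channels = "ACC", include_novel_day4 = TRUE)
  expect_equal(sum(con$meta$condition == "novel"), 2L)
})

test_that("cohort ground truth encodes the programmed familiar-only shift", {
  co <- simulate_cohort("single-300", 6, days = c(1, 4), seed = 21,
                        channels = "ACC")
  tr <- co$truth[co$truth$component == "N2" & co$truth$role == "A", ]
  wide <- merge(tr[tr$day == 1, c("subject", "neg_latency_ms")],
                tr[tr$day == 4, c("subject", "neg_latency_ms")],
                by = "subject", suffixes = c("_d1", "_d4"))
  expect_true(all(wide$neg_latency_ms_d4 < wide$neg_latency_ms_d1))
  # novel-role kernels are invariant across days
  nov <- co$truth[co$truth$role == "N", ]
  nov1 <- nov[nov$day == 1, ]; nov4 <- nov[nov$day == 4, ]
  expect_equal(nov1$neg_latency_ms, nov4$neg_latency_ms)
  expect_equal(nov1$neg_amplitude_uv, nov4$neg_amplitude_uv)
})
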