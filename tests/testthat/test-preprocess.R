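test_that("running-median subtraction zeroes constants and passes impulses", {
  fs <- 30000
  const <- continuous_recording(matrix(rep(7, 2000), nrow = 1), fs)
  expect_equal(max(abs(median_subtract(const)$samples)), 0)

  imp <- numeric(2001); imp[1001] <- 42
  out <- median_subtract(continuous_recording(matrix(imp, nrow = 1), fs))
  expect_equal(as.numeric(out$samples), imp)

  # 3.33 ms at 30 kS/s is 100 samples, forced odd to 101
  expect_identical(graspflow:::odd_window_samples(3.33, 30000), 101L)
  expect_error(median_subtract(continuous_recording(matrix(0, 1, 50), fs),
                               window_ms = 10),
               class = "graspflow_input_error")
})

test_that("zero-phase Butterworth matches its closed-form magnitude", {
  fs <- 30000; fc <- 5000
  dc <- continuous_recording(matrix(rep(5, 3000), nrow = 1), fs)
  expect_equal(as.numeric(lowpass_filter(dc)$samples), rep(5, 3000),
               tolerance = 1e-9)

  # 12 kHz tone: amplitude scales by the squared 4th-order magnitude,
  # |H|^2 = 1 / (1 + Omega^8) with bilinear-prewarped Omega
  f <- 12000
  x <- sin(2 * pi * f * (1:6000) / fs)
  y <- lowpass_filter(continuous_recording(matrix(x, nrow = 1), fs))$samples[1, ]
  mid <- 2000:4000
  tt <- mid / fs
  fit <- stats::lm(y[mid] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
  measured <- sqrt(sum(coef(fit)[2:3]^2))
  omega <- tan(pi * f / fs) / tan(pi * fc / fs)
  expect_equal(measured, 1 / (1 + omega^8), tolerance = 0.02)

  # centered impulse stays centered and symmetric (zero phase)
  imp <- numeric(3001); imp[1501] <- 1
  yi <- lowpass_filter(continuous_recording(matrix(imp, nrow = 1), fs))$samples[1, ]
  expect_equal(which.max(yi), 1501L)
  expect_equal(yi, rev(yi), tolerance = 1e-10)

  expect_error(lowpass_filter(continuous_recording(matrix(0, 1, 100), fs),
                              cutoff_hz = 16000),
               class = "graspflow_input_error")
})

test_that("PCA cancellation removes a rank-1 common mode and nothing else", {
  set.seed(31)
  n <- 20000
  # a unit-norm loading can exceed 0.36 on at most 7 channels, so with 16
  # independent channels the broad-loading rule can never fire
  indep <- matrix(rnorm(16 * n), nrow = 16)
  res_i <- pca_artifact_cancel(continuous_recording(indep, 30000))
  expect_false(any(res_i$report$removed))
  expect_equal(res_i$rec$samples, indep, tolerance = 1e-8)

  # identical signal on all channels plus tiny noise: rank-1 common mode
  common <- rnorm(n, sd = 5)
  x <- outer(rep(1, 6), common) + matrix(rnorm(6 * n, sd = 0.5), nrow = 6)
  res <- pca_artifact_cancel(continuous_recording(x, 30000))
  expect_true(res$report$removed[1])
  cc <- cor(t(res$rec$samples))
  expect_lt(mean(cc[upper.tri(cc)]), 0.05)

  expect_error(pca_artifact_cancel(continuous_recording(matrix(0, 1, 100), 30000)),
               class = "graspflow_input_error")
})

test_that("cancellation never increases mean absolute cross-correlation", {
  # artifact-bearing small blocks, and a large artifact-free block where the
  # broad-loading rule cannot fire (|loading| > 0.36 on >= 8 of 16 channels
  # is impossible for a unit-norm vector)
  cases <- list(c(nch = 6, sd_a = 2), c(nch = 6, sd_a = 8),
                c(nch = 16, sd_a = 0))
  for (cs in cases) {
    set.seed(100 + cs[["sd_a"]])
    n <- 10000
    nch <- cs[["nch"]]
    x <- matrix(rnorm(nch * n), nrow = nch) +
      outer(rnorm(nch, 1, 0.1), rnorm(n, sd = cs[["sd_a"]]))
    res <- pca_artifact_cancel(continuous_recording(x, 30000))
    before <- cor(t(x)); after <- cor(t(res$rec$samples))
    expect_lte(mean(abs(after[upper.tri(after)])),
               mean(abs(before[upper.tri(before)])) + 1e-9)
  }
})

test_that("threshold detection obeys the refractory lockout and trough timing", {
  fs <- 30000
  expect_equal(nrow(detect_spikes(continuous_recording(matrix(0, 1, 1000), fs))),
               0L)

  # noise floor so sigma_robust > 0, two pulses 0.4 ms apart -> one event
  set.seed(5)
  x <- rnorm(3000, sd = 1)
  x[1000:1002] <- -30
  x[1012:1014] <- -25 # 12 samples = 0.4 ms later, inside the lockout
  ev <- detect_spikes(continuous_recording(matrix(x, nrow = 1), fs))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time_ms, (1000 - 1) / fs * 1000, tolerance = 0.05)

  # pulses 2 ms apart -> two events
  x2 <- rnorm(3000, sd = 1)
  x2[1000] <- -30
  x2[1060] <- -25
  ev2 <- detect_spikes(continuous_recording(matrix(x2, nrow = 1), fs))
  expect_equal(nrow(ev2), 2L)
})

test_that("detection quality degrades monotonically with channel noise", {
  gen <- null_gen(n_units_per_area = c(F5 = 2L))
  cfg <- small_cfg(c(2L, 2L))
  tr <- simulate_behavior_times(generate_schedule(cfg, 1), cfg, gen, 1)
  sp <- simulate_spike_trains(tr, gen, 1, duration_ms = 6000)
  f1_at <- vapply(c(8, 30, 55), function(noise) {
    g <- null_gen(n_units_per_area = c(F5 = 2L), noise_sd_uv = noise,
                  artifact_gain = 0)
    rec <- simulate_continuous(sp, g, 2, duration_ms = 5000)
    band <- lowpass_filter(median_subtract(rec))
    det <- detect_spikes(band)
    mean(vapply(seq_len(nrow(rec$samples)), function(ci) {
      match_events(det$time_ms[det$channel == ci],
                   rec$ground_truth$spike_times_ms[[ci]] + 7 / 30)[["f1"]]
    }, numeric(1)))
  }, numeric(1))
  expect_gte(f1_at[1], 0.95)
  expect_true(all(diff(f1_at) <= 0))
})

test_that("unit QC applies an inclusive 1 Hz boundary and is idempotent", {
  mk <- function(n) tibble::tibble(unit_id = "u1", area = "F5",
                                   spike_time_ms = seq_len(n) * 10)
  expect_false(qc_units(mk(59), 1, 60000)$qc_pass)
  expect_true(qc_units(mk(60), 1, 60000)$qc_pass)

  # silent unit listed explicitly is excluded
  qc <- qc_units(mk(60), 1, 60000, units = c("u1", "u2"))
  expect_equal(qc$qc_pass[qc$unit_id == "u2"], FALSE)
  expect_equal(qc$n_spikes[qc$unit_id == "u2"], 0L)

  # 10 Hz units all pass
  sp10 <- tibble::tibble(unit_id = rep(c("a", "b"), each = 600),
                         area = "M1", spike_time_ms = rep(1:600 * 100, 2))
  expect_true(all(qc_units(sp10, 1, 60000)$qc_pass))

  # idempotence: rerunning QC on the passing subset changes nothing
  qc1 <- qc_units(sp10, 1, 60000)
  keep <- sp10[sp10$unit_id %in% qc1$unit_id[qc1$qc_pass], ]
  expect_equal(qc_units(keep, 1, 60000), qc1)
})

test_that("an isolated spike survives the spike-band chain intact", {
  gen <- null_gen(n_units_per_area = c(F5 = 1L), noise_sd_uv = 2,
                  artifact_gain = 0)
  sp <- tibble::tibble(unit_id = "F5_001", area = "F5", spike_time_ms = 500)
  rec <- simulate_continuous(sp, gen, 1, duration_ms = 1000)
  band <- lowpass_filter(median_subtract(rec))
  det <- detect_spikes(band)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$time_ms - 500), 0.5)
  # trough amplitude close to the injected template amplitude
  expect_equal(min(band$samples), -gen$spike_amp_uv, tolerance = 0.1)
})

test_that("spike-band filtering preserves spike ordering and polarity", {
  gen <- null_gen(n_units_per_area = c(F5 = 2L), noise_sd_uv = 2,
                  artifact_gain = 0)
  sp <- tibble::tibble(unit_id = rep(c("F5_001", "F5_002"), times = c(3, 2)),
                       area = "F5",
                       spike_time_ms = c(100, 900, 1700, 400, 1300))
  rec <- simulate_continuous(sp, gen, 1, duration_ms = 2000)
  band <- lowpass_filter(median_subtract(rec))
  # high threshold: this checks waveform integrity, not detection power
  det <- detect_spikes(band, threshold_sd = 8)
  det <- det[order(det$channel, det$time_ms), ]
  expect_equal(det$channel, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(det$time_ms, c(100, 900, 1700, 400, 1300), tolerance = 0.5)
  expect_true(all(det$amplitude < 0))
})
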