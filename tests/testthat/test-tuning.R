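test_that("window binning counts spikes in overlapping 100 ms windows", {
  tr <- toy_trial(go = 5000)
  sp <- tibble::tibble(unit_id = c("u1", "u2"), area = "F5",
                       spike_time_ms = c(5010, -1)) # u2 fires outside
  attr(sp, "duration_ms") <- 20000
  b <- bin_spikes(sp, tr, align = "go", window_ms = 100, stride_ms = 50,
                  range_ms = c(0, 50))
  # spike at +10 ms falls in [-50, 50) and [0, 100): both windows
  expect_equal(as.vector(b$counts[1, 1, ]), c(1L, 1L))
  # silent unit: all zeros
  expect_equal(as.vector(b$counts[2, 1, ]), c(0L, 0L))
})

test_that("a 20 Hz Poisson unit averages two spikes per 100 ms window", {
  gen <- null_gen(n_units_per_area = c(F5 = 1L),
                  baseline_hz_meanlog = log(20), baseline_hz_sdlog = 0,
                  epoch_gain = c(baseline = 1, cue = 1, early_memory = 1,
                                 late_memory = 1, move = 1, hold = 1, iti = 1))
  cfg <- small_cfg(c(6L, 6L))
  tr <- simulate_behavior_times(generate_schedule(cfg, 2), cfg, gen, 2)
  sp <- simulate_spike_trains(tr, gen, 5)
  b <- bin_spikes(sp, tr, align = "go", window_ms = 100, stride_ms = 100,
                  range_ms = c(-500, 400))
  m <- mean(b$counts)
  n <- length(b$counts)
  expect_lt(abs(m - 2), 3 * sqrt(2 / n))
})

test_that("degenerate and separable tables give p = 1 and p = 0", {
  obj <- rep(rep(c("o1", "o2"), each = 3), 2)
  mod <- rep(c("visual", "tactile"), each = 6)
  counts <- array(0L, c(1, 12, 1))
  # identical counts everywhere -> nothing to test
  counts[1, , 1] <- 5L
  pv <- sliding_anova(toy_binned(counts, obj, mod))
  expect_equal(pv$p, c(1, 1))

  # object effect with zero residual: o1 counts 2, o2 counts 8
  counts[1, , 1] <- rep(rep(c(2L, 8L), each = 3), 2)
  pv2 <- sliding_anova(toy_binned(counts, obj, mod))
  expect_equal(pv2$p[pv2$factor == "object"], 0)
  expect_equal(pv2$statistic[pv2$factor == "object"], Inf)
  expect_equal(pv2$p[pv2$factor == "modality"], 1)
})

test_that("single-window ANOVA equals the explicit sum-of-squares oracle", {
  set.seed(61)
  for (rep_i in 1:10) {
    obj <- rep(rep(paste0("o", 1:6), each = 4), 2)
    mod <- rep(c("visual", "tactile"), each = 24)
    y <- rpois(48, lambda = 3 + 2 * (as.integer(factor(obj)) %% 3))
    counts <- array(as.integer(y), c(1, 48, 1))
    pv <- sliding_anova(toy_binned(counts, obj, mod))
    oracle <- anova2_oracle(y, obj, mod)
    expect_lt(abs(pv$statistic[pv$factor == "object"] - oracle$F_a), 1e-10)
    expect_lt(abs(pv$statistic[pv$factor == "modality"] - oracle$F_b), 1e-10)
    expect_equal(pv$p[pv$factor == "object"], oracle$p_a, tolerance = 1e-12)
  }
})

test_that("uncorrected type-I error sits near the nominal 5%", {
  gen <- null_gen(n_units_per_area = c(F5 = 20L, M1 = 20L))
  s <- generate_session(small_cfg(c(7L, 7L)), gen, seed = 41,
                        components = "spikes")
  b <- bin_spikes(s$spikes, s$trials, align = "go", stride_ms = 100,
                  range_ms = c(-800, 400))
  pv <- sliding_anova(b)
  expect_lt(abs(mean(pv$p < 0.05) - 0.05), 0.02)
})

test_that("tuned fractions respect the Bonferroni family and bounds", {
  pvals <- tibble::tibble(
    unit_id = rep(c("a", "b"), each = 10),
    area = "F5", factor = "object",
    window_center_ms = rep(seq(0, 90, 10), 2),
    statistic = 1, df1 = 5, df2 = 40,
    p = 1
  )
  tf <- tuned_fraction(pvals)
  expect_true(all(tf$fraction == 0))
  expect_equal(attr(tf, "family_size")[["object"]], 10L)

  # p just above / below the corrected threshold
  pvals$p[1] <- 0.05 / 10 * 0.99
  pvals$p[11] <- 0.05 / 10 * 1.01
  tf2 <- tuned_fraction(pvals)
  expect_equal(tf2$fraction[tf2$window_center_ms == 0], 0.5)
  expect_true(all(tf2$fraction >= 0 & tf2$fraction <= 1))
  # fraction times unit count is integral
  expect_equal(tf2$fraction * tf2$n_units, round(tf2$fraction * tf2$n_units))
})

test_that("modality tuning injected in early memory is recovered there", {
  gen <- generator_settings(
    n_units_per_area = c(F5 = 15L), tuned_frac_obj = 0,
    tuned_frac_mod = 1, effect_mod = 1,
    mod_profile = c(baseline = 0, cue = 0, early_memory = 1, late_memory = 0,
                    move = 0, hold = 0, iti = 0))
  s <- generate_session(small_cfg(c(8L, 8L)), gen, seed = 43,
                        components = "spikes")
  b <- bin_spikes(s$spikes, s$trials, align = "memory_start", stride_ms = 50,
                  range_ms = c(-400, 900))
  tf <- tuned_fraction(sliding_anova(b))
  mod <- tf[tf$factor == "modality", ]
  peak <- mod$window_center_ms[which.max(mod$fraction)]
  expect_gte(peak, 0)
  expect_lte(peak, 500)
  expect_gt(max(mod$fraction), 0.8)
  # effect is concentrated: fraction far from the memory window is low
  expect_lt(mean(mod$fraction[mod$window_center_ms < -100]), 0.2)
  expect_lt(mean(mod$fraction[mod$window_center_ms > 700]), 0.2)
})

test_that("tuning detection power grows with effect size and trial count", {
  peak_frac <- function(effect, trials_per_cond, seed = 47) {
    gen <- generator_settings(n_units_per_area = c(F5 = 20L),
                              tuned_frac_obj = 0.5, effect_obj = effect,
                              tuned_frac_mod = 0)
    cfg <- small_cfg(c(trials_per_cond, trials_per_cond))
    s <- generate_session(cfg, gen, seed = seed, components = "spikes")
    b <- bin_spikes(s$spikes, s$trials, align = "movement_onset",
                    stride_ms = 100, range_ms = c(-200, 400))
    tf <- tuned_fraction(sliding_anova(b))
    max(tf$fraction[tf$factor == "object"])
  }
  by_effect <- vapply(c(0.15, 0.5, 1.0), peak_frac, numeric(1),
                      trials_per_cond = 8L)
  expect_true(all(diff(by_effect) >= 0))
  by_trials <- vapply(c(3L, 8L, 14L), function(tp) peak_frac(0.35, tp),
                      numeric(1))
  expect_true(all(diff(by_trials) >= 0))
})

test_that("per-modality object tuning uses one-way tests per modality", {
  gen <- small_gen()
  s <- generate_session(small_cfg(), gen, seed = 49, components = "spikes")
  b <- bin_spikes(s$spikes, s$trials, align = "go", stride_ms = 200,
                  range_ms = c(-400, 200))
  pv <- sliding_anova(b, per_modality = TRUE)
  expect_setequal(unique(pv$factor),
                  c("object_visual", "object_tactile", "modality"))
  tf <- tuned_fraction(pv)
  expect_true(all(tf$fraction >= 0 & tf$fraction <= 1))
})
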