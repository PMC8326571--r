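test_that("identical config, generator and seed reproduce the session exactly", {
  cfg <- small_cfg()
  gen <- small_gen()
  s1 <- generate_session(cfg, gen, seed = 1)
  s2 <- generate_session(cfg, gen, seed = 1)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$kinematics, s2$kinematics)
  s3 <- generate_session(cfg, gen, seed = 2)
  expect_false(identical(s1$trials$go, s3$trials$go))
})

test_that("per-condition trial counts follow the configured range", {
  sched <- generate_schedule(task_config(trials_per_condition_range = c(15L, 15L)),
                             seed = 4)
  expect_equal(nrow(sched), 12L * 15L)
  sched2 <- generate_schedule(task_config(), seed = 4)
  counts <- table(sched2$object, sched2$modality)
  expect_true(all(counts >= 14 & counts <= 18))
  expect_equal(nrow(sched2), sum(counts))
})

test_that("invalid configurations are rejected", {
  expect_error(task_config(trials_per_condition_range = c(0L, 5L)),
               class = "graspflow_config_error")
  expect_error(task_config(baseline_ms = -1), class = "graspflow_config_error")
  expect_error(task_config(memory_ms_range = c(1500, 1000)),
               class = "graspflow_config_error")
  expect_error(generator_settings(tuned_frac_obj = 1.4),
               class = "graspflow_config_error")
})

test_that("trial epochs are ordered and tile the session without overlap", {
  s <- generate_session(small_cfg(), small_gen(), seed = 3)
  tr <- s$trials
  for (i in seq_len(nrow(tr))) {
    ev <- c(tr$trial_start[i], tr$cue_on[i], tr$cue_off[i], tr$memory_start[i],
            tr$go[i], tr$movement_onset[i], tr$object_lifted[i],
            tr$hold_end[i], tr$reward[i])
    expect_true(all(diff(ev) >= 0))
  }
  # epoch table contiguity: each epoch ends where the next begins
  ep <- graspflow:::build_epoch_table(tr, s$ground_truth$duration_ms)
  expect_equal(ep$start[-1], ep$end[-nrow(ep)])
  expect_equal(ep$start[1], 0)
  expect_equal(ep$end[nrow(ep)], s$ground_truth$duration_ms)
  # every spike lies inside the recording interval
  expect_true(all(s$spikes$spike_time_ms >= 0 &
                  s$spikes$spike_time_ms <= s$ground_truth$duration_ms))
})

test_that("homogeneous Poisson units hit their configured rate", {
  # beta fixed at 10 Hz, no tuning, flat epoch gains -> Poisson(10 Hz)
  gen <- null_gen(n_units_per_area = c(F5 = 1L),
                  baseline_hz_meanlog = log(10), baseline_hz_sdlog = 0,
                  epoch_gain = c(baseline = 1, cue = 1, early_memory = 1,
                                 late_memory = 1, move = 1, hold = 1, iti = 1))
  trials <- simulate_behavior_times(generate_schedule(small_cfg(c(2L, 2L)), 1),
                                    small_cfg(c(2L, 2L)), gen, 1)
  sp <- simulate_spike_trains(trials, gen, seed = 8, duration_ms = 100000)
  expect_equal(attr(sp, "duration_ms"), 100000)
  # 100 s at 10 Hz: Poisson mean 1000, SE sqrt(1000)
  expect_lt(abs(nrow(sp) - 1000), 3 * sqrt(1000))

  units0 <- attr(sp, "units")
  units0$baseline_hz <- 0
  sp0 <- simulate_spike_trains(trials, gen, seed = 8, units = units0,
                               duration_ms = 100000)
  expect_equal(nrow(sp0), 0L)
  units_neg <- units0
  units_neg$baseline_hz <- -5
  expect_error(simulate_spike_trains(trials, gen, 8, units = units_neg),
               class = "graspflow_config_error")
})

test_that("untuned units have condition-independent firing", {
  gen <- null_gen(n_units_per_area = c(F5 = 4L))
  s <- generate_session(small_cfg(), gen, seed = 21, components = "spikes")
  f <- epoch_rates(s$spikes, s$trials, "grasp")
  # one-way F-test on object labels should not be extreme for null units
  pvals <- vapply(grep("^F5", names(f), value = TRUE), function(u) {
    stats::anova(stats::lm(f[[u]] ~ f$object))[["Pr(>F)"]][1]
  }, numeric(1))
  expect_gt(min(pvals), 1e-3)
})

test_that("behavioral draws with zero dispersion equal their configured means", {
  gen <- small_gen(timing_sdlog = 0)
  cfg <- small_cfg()
  tr <- simulate_behavior_times(generate_schedule(cfg, 2), cfg, gen, 2)
  expect_equal(unique(tr$movement_onset - tr$go), 259)
  vis <- tr$modality == "visual"
  expect_equal(unique((tr$object_lifted - tr$movement_onset)[vis]), 308)
  expect_equal(unique((tr$object_lifted - tr$movement_onset)[!vis]), 310)
  expect_equal(unique((tr$exploration_onset - tr$cue_on)[!vis]), 323)
  expect_equal(unique((tr$exploration_lift - tr$exploration_onset)[!vis]), 757)
  # memory durations inside the configured interval
  expect_true(all(tr$go - tr$memory_start >= 1000 - 1e-9 &
                  tr$go - tr$memory_start <= 1500 + 1e-9))
})

test_that("pooled grasp reaction times match the configured 259 ms mean", {
  cfg <- small_cfg(c(5L, 5L))
  rts <- unlist(lapply(1:10, function(sd) {
    tr <- simulate_behavior_times(generate_schedule(cfg, sd), cfg,
                                  generator_settings(), sd)
    reaction_time(tr)$rt_ms
  }))
  se <- sd(rts) / sqrt(length(rts))
  expect_lt(abs(mean(rts) - 259), 3 * se)
})

test_that("exploration movements are slower than grasp movements at defaults", {
  cfg <- small_cfg()
  tr <- simulate_behavior_times(generate_schedule(cfg, 6), cfg,
                                generator_settings(), 6)
  expect_gt(mean(movement_time(tr, "exploration")$mt_ms),
            mean(movement_time(tr, "grasp")$mt_ms))
})

test_that("noise-free kinematics settle exactly on the canonical postures", {
  gen <- small_gen(posture_noise_deg = 0, posture_meas_noise_deg = 0,
                   modality_offset_deg = 0)
  s <- generate_session(small_cfg(), gen, seed = 9, components = "kinematics")
  f <- extract_grasp_features(s$kinematics, s$trials)
  post <- s$ground_truth$postures
  for (i in seq_len(nrow(f))) {
    want <- post[as.character(f$object[i]), ]
    got <- as.numeric(f[i, grep("^angle_", names(f))])
    expect_equal(got, unname(want), tolerance = 1e-8)
  }
})

test_that("zero modality offset makes same-object grips exchangeable", {
  gen <- small_gen(modality_offset_deg = 0)
  s <- generate_session(task_config(trials_per_condition_range = c(10L, 10L)),
                        gen, seed = 13, components = "kinematics")
  f <- extract_grasp_features(s$kinematics, s$trials)
  dd <- class_distance_dendrogram(f)$distances
  same_obj <- substr(dd$class_a, 3, 20) == substr(dd$class_b, 3, 20)
  # V/T distance within an object is far below any cross-object distance
  expect_lt(max(dd$distance[same_obj]), min(dd$distance[!same_obj]))
})

test_that("labels are independent of features in the fully null generator", {
  gen <- null_gen(n_units_per_area = c(F5 = 6L), modality_offset_deg = 0)
  s <- generate_session(small_cfg(c(6L, 6L)), gen, seed = 17)
  f <- extract_grasp_features(s$kinematics, s$trials)
  m <- as.matrix(f[, grep("^angle_", names(f))])
  vis <- f$modality == "visual"
  stat <- sum((colMeans(m[vis, ]) - colMeans(m[!vis, ]))^2)
  perm <- vapply(1:199, function(i) {
    set.seed(i)
    v <- sample(vis)
    sum((colMeans(m[v, ]) - colMeans(m[!v, ]))^2)
  }, numeric(1))
  # observed statistic is not in the extreme tail of the permutation null
  expect_gt(mean(perm >= stat), 0.01)
})
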