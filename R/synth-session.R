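#' Draw a randomized trial schedule
#'
#' Draws a per-condition trial count uniformly from
#' `cfg$trials_per_condition_range` for every object x modality cell and
#' interleaves the conditions in random order, mirroring the pseudo-random
#' turntable rotation of the task.
#'
#' @param cfg A [task_config()].
#' @param seed Integer master seed.
#' @return A tibble with `trial_id`, `object`, `modality`.
#' @export
generate_schedule <- function(cfg = task_config(), seed = 1L) {
  objs <- object_labels(cfg$n_objects)
  conds <- tidyr::expand_grid(object = objs, modality = cfg$modalities)
  rng <- substream_seed(seed, 1L)
  withr_seed(rng, {
    vals <- seq.int(cfg$trials_per_condition_range[1],
                    cfg$trials_per_condition_range[2])
    counts <- vals[sample.int(length(vals), nrow(conds), replace = TRUE)]
    sched <- conds[rep(seq_len(nrow(conds)), counts), ]
    sched <- sched[sample.int(nrow(sched)), ]
  })
  tibble::tibble(
    trial_id = seq_len(nrow(sched)),
    object = factor(sched$object, levels = objs),
    modality = factor(sched$modality, levels = cfg$modalities)
  )
}

# Evaluate expr with a local, restored RNG state seeded at `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Log-normal draw with a target arithmetic mean; sdlog 0 degenerates to the
# mean itself.
rlnorm_mean <- function(n, mean, sdlog) {
  if (sdlog <= 0) return(rep(mean, n))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate behavioral event timestamps for a trial schedule
#'
#' Lays the schedule out on a single session clock. Reaction and movement
#' times are drawn from log-normal distributions whose means default to the
#' behavioral results the generator emulates: exploration RT/MT of 323/757 ms
#' and grasp RT of 259 ms with grasp MT of 308 ms (visual) and 310 ms
#' (tactile). Event order within a trial always follows the paradigm:
#' baseline, cue (illumination or tactile exploration), memory, go,
#' movement, hold, reward.
#'
#' @param schedule Tibble with `trial_id`, `object`, `modality`
#'   (see [generate_schedule()]).
#' @param cfg A [task_config()].
#' @param gen A [generator_settings()].
#' @param seed Integer master seed.
#' @return A trials tibble with one row per trial: condition labels, all
#'   event timestamps in ms on the session clock (`NA` where an event does
#'   not occur in that modality), and `outcome`.
#' @export
simulate_behavior_times <- function(schedule, cfg = task_config(),
                                    gen = generator_settings(), seed = 1L) {
  n <- nrow(schedule)
  tactile <- schedule$modality == "tactile"
  withr_seed(substream_seed(seed, 2L), {
    rt_e <- rlnorm_mean(n, gen$rt_explore_ms, gen$timing_sdlog)
    mt_e <- rlnorm_mean(n, gen$mt_explore_ms, gen$timing_sdlog)
    rt_g <- rlnorm_mean(n, gen$rt_grasp_ms, gen$timing_sdlog)
    mt_g <- ifelse(tactile,
                   rlnorm_mean(n, gen$mt_grasp_tactile_ms, gen$timing_sdlog),
                   rlnorm_mean(n, gen$mt_grasp_visual_ms, gen$timing_sdlog))
    mem <- runif(n, cfg$memory_ms_range[1], cfg$memory_ms_range[2])
  })

  trial_start <- cue_on <- cue_off <- numeric(n)
  exploration_onset <- exploration_lift <- handrest_return <- rep(NA_real_, n)
  t0 <- 0
  for (i in seq_len(n)) {
    trial_start[i] <- t0
    cue_on[i] <- t0 + cfg$baseline_ms
    if (tactile[i]) {
      exploration_onset[i] <- cue_on[i] + rt_e[i]
      exploration_lift[i] <- exploration_onset[i] + mt_e[i]
      # hand is back on the rest button after a fixed exploration window, or
      # 300 ms after the exploratory lift if the draw ran long
      handrest_return[i] <- cue_on[i] +
        max(gen$tactile_explore_ms, rt_e[i] + mt_e[i] + 300)
      cue_off[i] <- handrest_return[i]
    } else {
      cue_off[i] <- cue_on[i] + cfg$visual_cue_ms
    }
    t0 <- cue_off[i] + mem[i] # go time; rest of trial laid out below
    t0 <- t0 + rt_g[i] + mt_g[i] + cfg$hold_ms + 50 + gen$iti_ms
  }
  memory_start <- cue_off
  go <- memory_start + mem
  movement_onset <- go + rt_g
  object_lifted <- movement_onset + mt_g
  hold_end <- object_lifted + cfg$hold_ms
  reward <- hold_end + 50

  tibble::tibble(
    trial_id = schedule$trial_id,
    object = schedule$object,
    modality = schedule$modality,
    trial_start = trial_start,
    cue_on = cue_on,
    exploration_onset = exploration_onset,
    exploration_lift = exploration_lift,
    handrest_return = handrest_return,
    cue_off = cue_off,
    memory_start = memory_start,
    go = go,
    movement_onset = movement_onset,
    object_lifted = object_lifted,
    hold_end = hold_end,
    reward = reward,
    outcome = "correct"
  )
}

#' Generate a complete synthetic session
#'
#' Composes the trial scheduler, behavioral timing, inhomogeneous-Poisson
#' spike trains, joint-angle kinematics and (optionally) broadband continuous
#' signals into one session object with its ground truth attached. Identical
#' `(cfg, gen, seed)` always yield the identical session.
#'
#' @param cfg A [task_config()].
#' @param gen A [generator_settings()].
#' @param seed Integer master seed for all randomness.
#' @param components Which data streams to generate; the trial schedule is
#'   always present.
#' @return A list of class `grasp_session` with elements `trials`, `spikes`,
#'   `kinematics`, `continuous` (or `NULL`), and `ground_truth`.
#' @export
#' @examples
#' s <- generate_session(seed = 1, components = "kinematics",
#'                       gen = generator_settings(n_units_per_area = c(F5 = 4L)))
#' nrow(s$trials)
generate_session <- function(cfg = task_config(), gen = generator_settings(),
                             seed = 1L,
                             components = c("spikes", "kinematics")) {
  components <- match.arg(components, c("spikes", "kinematics", "continuous"),
                          several.ok = TRUE)
  schedule <- generate_schedule(cfg, seed)
  trials <- simulate_behavior_times(schedule, cfg, gen, seed)
  units <- make_units(gen, seed)
  duration_ms <- max(trials$reward) + gen$iti_ms

  spikes <- NULL
  kinematics <- NULL
  continuous <- NULL
  if ("spikes" %in% components || "continuous" %in% components) {
    spikes <- simulate_spike_trains(trials, gen, seed, units = units,
                                    duration_ms = duration_ms)
  }
  if ("kinematics" %in% components) {
    kinematics <- simulate_kinematics(trials, cfg, gen, seed)
  }
  gt <- list(
    seed = as.integer(seed),
    units = units,
    postures = attr(kinematics, "postures"),
    modality_offset = attr(kinematics, "modality_offset"),
    timing = list(rt_grasp_ms = gen$rt_grasp_ms,
                  mt_grasp_visual_ms = gen$mt_grasp_visual_ms,
                  mt_grasp_tactile_ms = gen$mt_grasp_tactile_ms,
                  rt_explore_ms = gen$rt_explore_ms,
                  mt_explore_ms = gen$mt_explore_ms,
                  sdlog = gen$timing_sdlog),
    duration_ms = duration_ms
  )
  session <- structure(list(trials = trials, spikes = spikes,
                            kinematics = kinematics, continuous = continuous,
                            ground_truth = gt, cfg = cfg, gen = gen),
                       class = "grasp_session")
  if ("continuous" %in% components) {
    session$continuous <- simulate_continuous(spikes, gen, seed,
                                              rate_hz = cfg$continuous_rate_hz,
                                              duration_ms = min(duration_ms, 20000))
  }
  session
}

#' @export
print.grasp_session <- function(x, ...) {
  cat("<grasp_session>\n")
  cat("  trials:     ", nrow(x$trials), " (",
      length(unique(x$trials$object)), " objects x ",
      length(unique(x$trials$modality)), " modalities)\n", sep = "")
  if (!is.null(x$spikes)) {
    cat("  spikes:     ", nrow(x$spikes), " events from ",
        nrow(x$ground_truth$units), " units\n", sep = "")
  }
  if (!is.null(x$kinematics)) {
    cat("  kinematics: ", nrow(x$kinematics), " samples, D = ",
        sum(grepl("^angle_", names(x$kinematics))), "\n", sep = "")
  }
  if (!is.null(x$continuous)) {
    cat("  continuous: ", nrow(x$continuous$samples), " channels x ",
        ncol(x$continuous$samples), " samples @ ", x$continuous$rate, " Hz\n",
        sep = "")
  }
  invisible(x)
}
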