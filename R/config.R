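#' Task configuration for the delayed-grasping paradigm
#'
#' Defines the five-epoch trial structure: a baseline in the dark, a cue
#' period in which the object is identified visually (brief illumination) or
#' tactually (exploration in the dark), a randomized memory period, a go
#' window in which the object must be lifted, and a hold period. Defaults are
#' the timings of the experiment the package models.
#'
#' @param n_objects Number of graspable objects on the turntable.
#' @param modalities Sensory instruction modalities.
#' @param baseline_ms Baseline epoch duration (ms).
#' @param visual_cue_ms Illumination time of the object in visual trials (ms).
#' @param tactile_cue_max_ms Maximum allowed tactile exploration time (ms).
#' @param memory_ms_range Lower/upper bound of the randomized memory period (ms).
#' @param go_window_ms Time allowed between go cue and completed lift (ms).
#' @param hold_ms Required object hold duration (ms).
#' @param trials_per_condition_range Per-condition trial count range; counts
#'   are drawn uniformly from this range for every object x modality cell.
#' @param continuous_rate_hz Broadband sampling rate (Hz).
#' @param glove_rate_hz_range Data-glove sampling rate range (Hz).
#'
#' @return A list of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$memory_ms_range
task_config <- function(n_objects = 6L,
                        modalities = c("visual", "tactile"),
                        baseline_ms = 500,
                        visual_cue_ms = 700,
                        tactile_cue_max_ms = 3000,
                        memory_ms_range = c(1000, 1500),
                        go_window_ms = 870,
                        hold_ms = 700,
                        trials_per_condition_range = c(14L, 18L),
                        continuous_rate_hz = 30000,
                        glove_rate_hz_range = c(70, 100)) {
  durs <- c(baseline_ms, visual_cue_ms, tactile_cue_max_ms, go_window_ms,
            hold_ms, continuous_rate_hz)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort("all durations and rates must be positive", class = "graspflow_config_error")
  }
  if (n_objects < 1) {
    abort("n_objects must be >= 1", class = "graspflow_config_error")
  }
  if (length(memory_ms_range) != 2 || memory_ms_range[1] > memory_ms_range[2] ||
      memory_ms_range[1] <= 0) {
    abort("memory_ms_range must be a positive (lower, upper) pair",
          class = "graspflow_config_error")
  }
  if (length(trials_per_condition_range) != 2 ||
      any(trials_per_condition_range <= 0) ||
      trials_per_condition_range[1] > trials_per_condition_range[2]) {
    abort("trials_per_condition_range must be a positive nondecreasing pair",
          class = "graspflow_config_error")
  }
  if (glove_rate_hz_range[1] > glove_rate_hz_range[2] || glove_rate_hz_range[1] <= 0) {
    abort("glove_rate_hz_range must be a positive nondecreasing pair",
          class = "graspflow_config_error")
  }
  structure(list(
    n_objects = as.integer(n_objects),
    modalities = modalities,
    baseline_ms = baseline_ms,
    visual_cue_ms = visual_cue_ms,
    tactile_cue_max_ms = tactile_cue_max_ms,
    memory_ms_range = memory_ms_range,
    go_window_ms = go_window_ms,
    hold_ms = hold_ms,
    trials_per_condition_range = as.integer(trials_per_condition_range),
    continuous_rate_hz = continuous_rate_hz,
    glove_rate_hz_range = glove_rate_hz_range
  ), class = "task_config")
}

#' Generator settings for synthetic sessions
#'
#' Controls every stochastic ingredient of the synthetic session: unit counts
#' per area, the fraction of units carrying object or modality information,
#' effect sizes and their epoch profiles, grasp-posture geometry, behavioral
#' timing distributions, and broadband noise/artifact levels. The defaults
#' are the study conditions the package emulates; see the methods vignette
#' for how each was fixed.
#'
#' The firing-rate model for unit u at time t is
#' `lambda_u(t) = beta_u * g(epoch) * (1 + a_u * a(epoch) * f_obj(object)
#'  + b_u * b(epoch) * f_mod(modality))`, clipped at zero. `f_obj` is a
#' per-unit permutation of six equally spaced contrasts in \[-1, 1\] and
#' `f_mod` is +/-1 (tactile/visual), so untuned units (`a_u = b_u = 0`) have
#' identical rate laws across conditions.
#'
#' @param n_units_per_area Named integer vector of unit counts for F5, AIP,
#'   M1 and S1.
#' @param baseline_hz_meanlog,baseline_hz_sdlog Log-normal parameters of the
#'   per-unit baseline rate beta_u (Hz).
#' @param tuned_frac_obj,tuned_frac_mod Fraction of units given a nonzero
#'   object / modality gain (exact count `round(frac * n)` per area).
#' @param effect_obj,effect_mod Gain magnitudes a_u, b_u of tuned units.
#' @param epoch_gain Named multiplicative rate gain g(epoch).
#' @param obj_profile,mod_profile Named epoch profiles a(epoch), b(epoch)
#'   scaling the object / modality effect over the trial.
#' @param posture_dim Joint-angle dimensionality of the hand model.
#' @param posture_spread_deg SD (degrees) of canonical per-object postures.
#' @param posture_noise_deg Per-trial posture noise SD (degrees).
#' @param posture_meas_noise_deg Per-sample glove measurement noise SD.
#' @param modality_offset_deg Euclidean norm of the posture offset between
#'   tactile and visual grasps of the same object; 0 means grip type is
#'   independent of modality.
#' @param rt_grasp_ms,mt_grasp_visual_ms,mt_grasp_tactile_ms Mean grasp
#'   reaction time and movement times (ms).
#' @param rt_explore_ms,mt_explore_ms Mean tactile-exploration reaction and
#'   movement time (ms).
#' @param timing_sdlog Log-normal shape parameter of all RT/MT draws
#'   (0 makes every draw equal its mean).
#' @param tactile_explore_ms Total simulated tactile cue-epoch duration (ms).
#' @param iti_ms Inter-trial interval (ms).
#' @param noise_sd_uv Broadband 1/f channel-noise SD (microvolts).
#' @param spike_amp_uv Peak (negative) spike template amplitude (microvolts).
#' @param artifact_gain Amplitude scale of the shared common-mode artifact;
#'   0 disables it.
#'
#' @return A list of class `generator_settings`.
#' @export
generator_settings <- function(n_units_per_area = c(F5 = 26L, AIP = 9L, M1 = 64L, S1 = 50L),
                               baseline_hz_meanlog = log(10),
                               baseline_hz_sdlog = 0.5,
                               tuned_frac_obj = 0.3,
                               tuned_frac_mod = 0.3,
                               effect_obj = 0.6,
                               effect_mod = 0.6,
                               epoch_gain = c(baseline = 1, cue = 1.2,
                                              early_memory = 1, late_memory = 1,
                                              move = 1.5, hold = 1.2, iti = 1),
                               obj_profile = c(baseline = 0, cue = 1,
                                               early_memory = 0.4, late_memory = 0.5,
                                               move = 1, hold = 0.7, iti = 0),
                               mod_profile = c(baseline = 0, cue = 1,
                                               early_memory = 1, late_memory = 0.3,
                                               move = 0.15, hold = 0.1, iti = 0),
                               posture_dim = 27L,
                               posture_spread_deg = 20,
                               posture_noise_deg = 4,
                               posture_meas_noise_deg = 0.5,
                               modality_offset_deg = 0,
                               rt_grasp_ms = 259,
                               mt_grasp_visual_ms = 308,
                               mt_grasp_tactile_ms = 310,
                               rt_explore_ms = 323,
                               mt_explore_ms = 757,
                               timing_sdlog = 0.25,
                               tactile_explore_ms = 2000,
                               iti_ms = 1500,
                               noise_sd_uv = 10,
                               spike_amp_uv = 80,
                               artifact_gain = 1) {
  if (any(n_units_per_area < 0)) {
    abort("unit counts must be nonnegative", class = "graspflow_config_error")
  }
  if (is.null(names(n_units_per_area)) || !all(nzchar(names(n_units_per_area)))) {
    abort("n_units_per_area must be a named vector", class = "graspflow_config_error")
  }
  epochs <- c("baseline", "cue", "early_memory", "late_memory", "move", "hold", "iti")
  for (p in list(epoch_gain, obj_profile, mod_profile)) {
    if (!all(epochs %in% names(p))) {
      abort("epoch profiles must name all task epochs", class = "graspflow_config_error")
    }
  }
  if (any(epoch_gain < 0) || baseline_hz_meanlog < -20) {
    abort("negative rate gains are not allowed", class = "graspflow_config_error")
  }
  if (tuned_frac_obj < 0 || tuned_frac_obj > 1 || tuned_frac_mod < 0 || tuned_frac_mod > 1) {
    abort("tuned fractions must lie in [0, 1]", class = "graspflow_config_error")
  }
  structure(list(
    n_units_per_area = n_units_per_area,
    baseline_hz_meanlog = baseline_hz_meanlog,
    baseline_hz_sdlog = baseline_hz_sdlog,
    tuned_frac_obj = tuned_frac_obj,
    tuned_frac_mod = tuned_frac_mod,
    effect_obj = effect_obj,
    effect_mod = effect_mod,
    epoch_gain = epoch_gain[epochs],
    obj_profile = obj_profile[epochs],
    mod_profile = mod_profile[epochs],
    posture_dim = as.integer(posture_dim),
    posture_spread_deg = posture_spread_deg,
    posture_noise_deg = posture_noise_deg,
    posture_meas_noise_deg = posture_meas_noise_deg,
    modality_offset_deg = modality_offset_deg,
    rt_grasp_ms = rt_grasp_ms,
    mt_grasp_visual_ms = mt_grasp_visual_ms,
    mt_grasp_tactile_ms = mt_grasp_tactile_ms,
    rt_explore_ms = rt_explore_ms,
    mt_explore_ms = mt_explore_ms,
    timing_sdlog = timing_sdlog,
    tactile_explore_ms = tactile_explore_ms,
    iti_ms = iti_ms,
    noise_sd_uv = noise_sd_uv,
    spike_amp_uv = spike_amp_uv,
    artifact_gain = artifact_gain
  ), class = "generator_settings")
}

object_labels <- function(n) {
  if (n <= length(OBJECTS)) OBJECTS[seq_len(n)] else c(OBJECTS, paste0("object", seq_len(n - length(OBJECTS)) + length(OBJECTS)))
}
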