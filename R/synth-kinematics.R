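#' Simulate joint-angle hand kinematics for a session
#'
#' Each object has a canonical grasp posture in a D-dimensional joint-angle
#' space (default D = 27). The settled posture of a trial is the canonical
#' posture of its object, plus a fixed offset vector of norm
#' `modality_offset_deg` applied on tactile trials, plus isotropic Gaussian
#' noise. The hand travels from the rest posture to the trial posture along a
#' minimum-jerk trajectory during the movement epoch and holds it thereafter.
#' Samples are taken at a glove rate drawn from `cfg$glove_rate_hz_range`
#' with small timing jitter (the glove rate depends on computer load).
#'
#' With `modality_offset_deg = 0`, postures for the same object are
#' exchangeable across modalities: grip type carries no modality signal.
#'
#' @param trials Trials tibble from [simulate_behavior_times()].
#' @param cfg A [task_config()].
#' @param gen A [generator_settings()].
#' @param seed Integer master seed.
#' @return A tibble `trial_id`, `time_ms`, `angle_01`..`angle_DD` (degrees),
#'   covering movement onset through hold for every correct trial. Canonical
#'   postures and the modality offset vector are attached as attributes
#'   `postures` and `modality_offset`.
#' @export
simulate_kinematics <- function(trials, cfg = task_config(),
                                gen = generator_settings(), seed = 1L) {
  D <- gen$posture_dim
  n_obj <- nlevels(trials$object)
  withr_seed(substream_seed(seed, 4L), {
    postures <- matrix(rnorm(n_obj * D, sd = gen$posture_spread_deg),
                       nrow = n_obj, dimnames = list(levels(trials$object), NULL))
    off <- rnorm(D)
    offset <- if (gen$modality_offset_deg > 0) {
      off / sqrt(sum(off^2)) * gen$modality_offset_deg
    } else {
      numeric(D)
    }
  })

  ok <- trials$outcome == "correct"
  rows <- which(ok)
  out <- vector("list", length(rows))
  withr_seed(substream_seed(seed, 5L), {
    glove_hz <- runif(1, cfg$glove_rate_hz_range[1], cfg$glove_rate_hz_range[2])
    dt <- 1000 / glove_hz
    for (k in seq_along(rows)) {
      i <- rows[k]
      target <- postures[as.integer(trials$object[i]), ] +
        offset * (trials$modality[i] == "tactile") +
        rnorm(D, sd = gen$posture_noise_deg)
      t0 <- trials$movement_onset[i]
      t1 <- trials$object_lifted[i]
      t_end <- trials$hold_end[i]
      times <- seq(t0, t_end, by = dt)
      if (length(times) > 1) {
        times[-1] <- times[-1] + runif(length(times) - 1, -0.3 * dt, 0.3 * dt)
      }
      u <- pmin(pmax((times - t0) / (t1 - t0), 0), 1)
      s <- 10 * u^3 - 15 * u^4 + 6 * u^5 # minimum-jerk position profile
      ang <- outer(s, target) +
        matrix(rnorm(length(times) * D, sd = gen$posture_meas_noise_deg),
               nrow = length(times))
      colnames(ang) <- sprintf("angle_%02d", seq_len(D))
      out[[k]] <- dplyr::bind_cols(
        tibble::tibble(trial_id = trials$trial_id[i], time_ms = times),
        tibble::as_tibble(ang)
      )
    }
  })
  kin <- dplyr::bind_rows(out)
  attr(kin, "postures") <- postures
  attr(kin, "modality_offset") <- offset
  attr(kin, "glove_rate_hz") <- glove_hz
  kin
}
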