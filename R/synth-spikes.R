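#' Build the ground-truth unit table
#'
#' Draws per-unit baseline rates and tuning gains for the four recorded
#' areas. An exact count `round(frac * n)` of units per area receives a
#' nonzero object (or modality) gain; the per-object contrast `f_obj` of a
#' unit is a random permutation of equally spaced values in \[-1, 1\], so
#' every tuned unit discriminates the full object set with a known effect
#' geometry. Untuned units have gains exactly 0.
#'
#' @param gen A [generator_settings()].
#' @param seed Integer master seed.
#' @param n_objects Number of objects the contrast vectors span.
#' @return A tibble with one row per unit: `unit_id`, `area`, `baseline_hz`,
#'   `a_obj`, `b_mod`, `f_obj` (list-column of contrasts), `f_mod_sign`.
#' @export
make_units <- function(gen = generator_settings(), seed = 1L, n_objects = 6L) {
  areas <- names(gen$n_units_per_area)
  withr_seed(substream_seed(seed, 3L), {
    per_area <- lapply(areas, function(ar) {
      n <- gen$n_units_per_area[[ar]]
      if (n == 0) return(NULL)
      beta <- rlnorm(n, gen$baseline_hz_meanlog, gen$baseline_hz_sdlog)
      a <- numeric(n)
      b <- numeric(n)
      if (gen$tuned_frac_obj > 0) {
        a[sample.int(n, round(gen$tuned_frac_obj * n))] <- gen$effect_obj
      }
      if (gen$tuned_frac_mod > 0) {
        b[sample.int(n, round(gen$tuned_frac_mod * n))] <- gen$effect_mod
      }
      contrasts <- seq(-1, 1, length.out = n_objects)
      tibble::tibble(
        unit_id = sprintf("%s_%03d", ar, seq_len(n)),
        area = ar,
        baseline_hz = beta,
        a_obj = a,
        b_mod = b,
        f_obj = lapply(seq_len(n), function(i) sample(contrasts)),
        f_mod_sign = sample(c(-1, 1), n, replace = TRUE)
      )
    })
  })
  dplyr::bind_rows(per_area)
}

# Piecewise-constant epoch table covering [0, duration_ms): one row per
# task epoch per trial plus the inter-trial intervals. `obj` is the object
# index (NA outside condition-dependent epochs), `mod` is +1 tactile /
# -1 visual / 0 outside.
build_epoch_table <- function(trials, duration_ms) {
  n <- nrow(trials)
  mod_sign <- ifelse(trials$modality == "tactile", 1, -1)
  obj_idx <- as.integer(trials$object)
  next_start <- c(trials$trial_start[-1], duration_ms)
  em_end <- pmin(trials$memory_start + 500, trials$go)
  per_trial <- function(i) {
    tibble::tibble(
      start = c(trials$trial_start[i], trials$cue_on[i], trials$memory_start[i],
                em_end[i], trials$movement_onset[i], trials$object_lifted[i],
                trials$hold_end[i]),
      epoch = c("baseline", "cue", "early_memory", "late_memory", "move",
                "hold", "iti"),
      obj = c(NA, rep(obj_idx[i], 5L), NA),
      mod = c(0, rep(mod_sign[i], 5L), 0)
    )
  }
  tab <- dplyr::bind_rows(lapply(seq_len(n), per_trial))
  tab$end <- c(tab$start[-1], duration_ms)
  tab
}

#' Simulate inhomogeneous-Poisson spike trains for a session
#'
#' The rate of unit u is piecewise constant over task epochs:
#' `lambda_u(t) = beta_u * g(epoch) * (1 + a_u a(epoch) f_obj(object) +
#' b_u b(epoch) f_mod(modality))`, clipped at zero. Spikes are drawn by
#' thinning a homogeneous Poisson process at the unit's maximal rate. Each
#' unit consumes its own RNG substream derived from the master seed, so
#' adding units never perturbs the spike trains of existing ones.
#'
#' @param trials Trials tibble from [simulate_behavior_times()].
#' @param gen A [generator_settings()].
#' @param seed Integer master seed.
#' @param units Optional unit table from [make_units()]; built from `gen`
#'   when omitted.
#' @param duration_ms Recording duration; defaults to the end of the last
#'   trial plus one inter-trial interval.
#' @return A tibble `unit_id`, `area`, `spike_time_ms` (sorted within unit),
#'   with the unit table and duration attached as attributes `units` and
#'   `duration_ms`.
#' @export
simulate_spike_trains <- function(trials, gen = generator_settings(), seed = 1L,
                                  units = NULL, duration_ms = NULL) {
  if (is.null(units)) units <- make_units(gen, seed, nlevels(trials$object))
  if (any(units$baseline_hz < 0)) {
    abort("negative baseline rates are not allowed", class = "graspflow_config_error")
  }
  if (is.null(duration_ms)) duration_ms <- max(trials$reward) + gen$iti_ms
  ep <- build_epoch_table(trials, duration_ms)
  g <- gen$epoch_gain[ep$epoch]
  ap <- gen$obj_profile[ep$epoch]
  bp <- gen$mod_profile[ep$epoch]
  obj <- ep$obj
  obj[is.na(obj)] <- 1L # profile is 0 there; index only needs to be valid

  out <- vector("list", nrow(units))
  for (u in seq_len(nrow(units))) {
    beta <- units$baseline_hz[u]
    f <- units$f_obj[[u]]
    rates <- beta * g *
      (1 + units$a_obj[u] * ap * f[obj] +
         units$b_mod[u] * bp * units$f_mod_sign[u] * ep$mod)
    rates <- pmax(rates, 0)
    lmax <- max(rates)
    if (lmax <= 0) next
    withr_seed(substream_seed(seed, 1000L + u), {
      n_cand <- rpois(1, lmax * duration_ms / 1000)
      if (n_cand > 0) {
        tt <- runif(n_cand, 0, duration_ms)
        keep <- runif(n_cand) < rates[findInterval(tt, ep$start)] / lmax
        tt <- sort(tt[keep])
      } else {
        tt <- numeric(0)
      }
    })
    if (length(tt)) {
      out[[u]] <- tibble::tibble(unit_id = units$unit_id[u],
                                 area = units$area[u], spike_time_ms = tt)
    }
  }
  spikes <- dplyr::bind_rows(out)
  if (nrow(spikes) == 0) {
    spikes <- tibble::tibble(unit_id = character(), area = character(),
                             spike_time_ms = numeric())
  }
  attr(spikes, "units") <- units
  attr(spikes, "duration_ms") <- duration_ms
  spikes
}
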