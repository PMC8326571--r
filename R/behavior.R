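PARADIGM_ORDER <- c("trial_start", "cue_on", "cue_off", "memory_start", "go",
                    "movement_onset", "object_lifted", "hold_end", "reward")

#' Validate raw trial events against the paradigm
#'
#' Accepts either a wide trials table (one row per trial, one column per
#' event) or a long event table (`trial_id`, `event`, `time_ms`), which is
#' pivoted first. A trial is marked `correct` only if its events are
#' nondecreasing in paradigm order, its memory period lies within the
#' configured range, and the object was lifted within the go window;
#' otherwise it gets `error:<reason>` and is excluded from downstream
#' analyses. Events with no trial id are dropped with a warning.
#'
#' @param events Wide or long event table; `object`/`modality` columns are
#'   carried through when present.
#' @param cfg A [task_config()].
#' @return A trials tibble with a recomputed `outcome` column.
#' @export
validate_trials <- function(events, cfg = task_config()) {
  if (all(c("event", "time_ms") %in% names(events))) {
    orphan <- is.na(events$trial_id)
    if (any(orphan)) {
      warn(sprintf("dropping %d orphan events without a trial id", sum(orphan)))
      events <- events[!orphan, ]
    }
    events <- tidyr::pivot_wider(events, names_from = "event",
                                 values_from = "time_ms")
  }
  trials <- tibble::as_tibble(events)
  present <- intersect(PARADIGM_ORDER, names(trials))

  outcome <- vapply(seq_len(nrow(trials)), function(i) {
    ts <- as.numeric(unlist(trials[i, present]))
    if (anyNA(ts)) return("error:missing-event")
    if (any(diff(ts) < 0)) {
      # premature movement is the commonest order violation worth naming
      if (!is.na(trials$movement_onset[i]) && !is.na(trials$go[i]) &&
          trials$movement_onset[i] < trials$go[i]) {
        return("error:premature")
      }
      return("error:event-order")
    }
    mem <- trials$go[i] - trials$memory_start[i]
    if (mem < cfg$memory_ms_range[1] - 1e-9 ||
        mem > cfg$memory_ms_range[2] + 1e-9) {
      return("error:paradigm-violation")
    }
    if (trials$object_lifted[i] - trials$go[i] > cfg$go_window_ms + 1e-9) {
      return("error:late-lift")
    }
    "correct"
  }, character(1))
  trials$outcome <- outcome
  trials
}

correct_trials <- function(trials) {
  if (!"outcome" %in% names(trials)) return(trials)
  trials[trials$outcome == "correct", ]
}

#' Per-trial reaction times
#'
#' Grasp-phase reaction time is the time between the go cue and movement
#' start (handrest release); exploration-phase reaction time (tactile trials
#' only) is measured analogously from cue onset to handrest release during
#' tactile exploration.
#'
#' @param trials A validated trials tibble.
#' @param phase `"grasp"` or `"exploration"`.
#' @return A tibble `trial_id`, `object`, `modality`, `phase`, `rt_ms`.
#' @export
reaction_time <- function(trials, phase = c("grasp", "exploration")) {
  phase <- match.arg(phase)
  tr <- correct_trials(trials)
  rt <- if (phase == "grasp") {
    tr$movement_onset - tr$go
  } else {
    tr$exploration_onset - tr$cue_on
  }
  out <- tibble::tibble(trial_id = tr$trial_id, object = tr$object,
                        modality = tr$modality, phase = phase, rt_ms = rt)
  out[!is.na(out$rt_ms), ]
}

#' Per-trial movement times
#'
#' Grasp-phase movement time runs from handrest release to the completed
#' object lift; exploration-phase movement time from handrest release to the
#' exploratory lift.
#'
#' @inheritParams reaction_time
#' @return A tibble `trial_id`, `object`, `modality`, `phase`, `mt_ms`.
#' @export
movement_time <- function(trials, phase = c("grasp", "exploration")) {
  phase <- match.arg(phase)
  tr <- correct_trials(trials)
  mt <- if (phase == "grasp") {
    tr$object_lifted - tr$movement_onset
  } else {
    tr$exploration_lift - tr$exploration_onset
  }
  out <- tibble::tibble(trial_id = tr$trial_id, object = tr$object,
                        modality = tr$modality, phase = phase, mt_ms = mt)
  out[!is.na(out$mt_ms), ]
}

#' Timing summary with histogram
#'
#' Pools the requested measure over trials, per modality, and bins it on
#' `[0, cutoff_ms)` with the given bin width. The cutoff truncates the
#' histogram display only: the mean is computed over all values, including
#' those beyond the cutoff.
#'
#' @param trials A validated trials tibble.
#' @param phase `"grasp"` or `"exploration"`.
#' @param measure `"rt"` (reaction time) or `"mt"` (movement time).
#' @param bin_ms Histogram bin width (5 ms is the reaction-time display
#'   convention, 10 ms the movement-time one).
#' @param cutoff_ms Histogram upper display limit (550 ms for RT, 1000 ms
#'   for MT).
#' @return A list of class `timing_summary` with `summary` (phase, modality,
#'   n, mean_ms) and `hist` (modality, bin_left, bin_right, count) tibbles.
#' @export
timing_summary <- function(trials, phase = c("grasp", "exploration"),
                           measure = c("rt", "mt"),
                           bin_ms = if (match.arg(measure) == "rt") 5 else 10,
                           cutoff_ms = if (match.arg(measure) == "rt") 550 else 1000) {
  phase <- match.arg(phase)
  measure <- match.arg(measure)
  vals <- if (measure == "rt") reaction_time(trials, phase) else movement_time(trials, phase)
  names(vals)[names(vals) == paste0(measure, "_ms")] <- "value"
  empty <- nrow(vals) == 0
  if (empty) warn("no correct trials for this phase; empty summary")

  summ <- vals |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(n = dplyr::n(), mean_ms = mean(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(phase = .env$phase, measure = .env$measure,
                  .before = "modality")
  edges <- seq(0, cutoff_ms, by = bin_ms)
  hist_tbl <- vals |>
    dplyr::filter(.data$value < cutoff_ms) |>
    dplyr::mutate(bin = cut(.data$value, breaks = edges, right = FALSE)) |>
    dplyr::count(.data$modality, .data$bin, .drop = FALSE) |>
    dplyr::mutate(bin_left = edges[as.integer(.data$bin)],
                  bin_right = edges[as.integer(.data$bin) + 1L]) |>
    dplyr::select("modality", "bin_left", "bin_right", count = "n")
  structure(list(summary = summ, hist = hist_tbl,
                 phase = phase, measure = measure,
                 bin_ms = bin_ms, cutoff_ms = cutoff_ms, empty = empty),
            class = "timing_summary")
}

#' @export
print.timing_summary <- function(x, ...) {
  cat("<timing_summary> ", x$phase, " ", toupper(x$measure),
      " (bin ", x$bin_ms, " ms, cutoff ", x$cutoff_ms, " ms)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname timing_summary
#' @param x A `timing_summary`.
#' @param ... Unused.
#' @export
tidy.timing_summary <- function(x, ...) x$summary
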