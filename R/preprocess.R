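#' Preprocessing parameters
#'
#' Defaults follow the spike-band extraction chain the package implements: a
#' 3.33 ms running-median subtraction, a 4th-order zero-phase Butterworth
#' low-pass at 5 kHz, PCA common-artifact cancellation with a normalized
#' loading threshold of 0.36, amplitude-threshold detection at 4.5 robust
#' SDs, and exclusion of units below 1 Hz.
#'
#' @param median_window_ms Running-median window (ms).
#' @param butter_order Butterworth filter order (applied forward-backward).
#' @param butter_cutoff_hz Low-pass cutoff (Hz).
#' @param pca_coef_threshold Normalized-loading magnitude above which a
#'   channel counts as loading on a component.
#' @param pca_channel_frac Fraction of channels that must exceed the loading
#'   threshold for a component to be classified as common-mode artifact.
#' @param pca_mode Artifact classification rule; see [pca_artifact_cancel()].
#' @param detect_threshold_sd Detection threshold in units of the robust
#'   noise SD `median(|x|) / 0.6745`.
#' @param refractory_ms Detection lockout after each event (ms).
#' @param min_rate_hz Minimum mean rate for a unit to pass QC.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(median_window_ms = 3.33,
                              butter_order = 4L,
                              butter_cutoff_hz = 5000,
                              pca_coef_threshold = 0.36,
                              pca_channel_frac = 0.5,
                              pca_mode = c("remove_common", "keep_signal"),
                              detect_threshold_sd = 4.5,
                              refractory_ms = 1,
                              min_rate_hz = 1) {
  pca_mode <- match.arg(pca_mode)
  vals <- c(median_window_ms, butter_order, butter_cutoff_hz,
            pca_coef_threshold, pca_channel_frac, detect_threshold_sd,
            refractory_ms, min_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all preprocessing parameters must be positive",
          class = "graspflow_config_error")
  }
  structure(list(median_window_ms = median_window_ms,
                 butter_order = as.integer(butter_order),
                 butter_cutoff_hz = butter_cutoff_hz,
                 pca_coef_threshold = pca_coef_threshold,
                 pca_channel_frac = pca_channel_frac,
                 pca_mode = pca_mode,
                 detect_threshold_sd = detect_threshold_sd,
                 refractory_ms = refractory_ms,
                 min_rate_hz = min_rate_hz),
            class = "preprocess_params")
}

# Convert a window in ms to an odd sample count (a running median needs an
# odd window); 3.33 ms at 30 kS/s gives 100 samples, rounded up to 101.
odd_window_samples <- function(window_ms, rate) {
  w <- round(window_ms / 1000 * rate)
  w <- max(w, 3L)
  if (w %% 2 == 0) w <- w + 1L
  as.integer(w)
}

#' Subtract a running median from every channel
#'
#' The running median tracks slow excursions (movement artifacts, field
#' potentials) while ignoring brief spike waveforms; subtracting it from the
#' raw signal leaves the spike band plus fast noise. Constant segments map
#' to zero.
#'
#' @param rec A [continuous_recording()].
#' @param window_ms Median window; converted to an odd sample count.
#' @return A `continuous_recording` of residuals.
#' @export
median_subtract <- function(rec, window_ms = 3.33) {
  w <- odd_window_samples(window_ms, rec$rate)
  if (w > ncol(rec$samples)) {
    abort("median window longer than the recording",
          class = "graspflow_input_error")
  }
  out <- rec
  for (ci in seq_len(nrow(rec$samples))) {
    out$samples[ci, ] <- rec$samples[ci, ] -
      stats::runmed(rec$samples[ci, ], w, endrule = "median")
  }
  out
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the Butterworth design forward and backward
#' (`signal::filtfilt`), so the filter is non-causal with exactly zero phase:
#' spike timing is preserved and symmetric inputs stay symmetric. The
#' magnitude response is the squared one-pass Butterworth magnitude.
#'
#' @param rec A [continuous_recording()].
#' @param order Filter order of the one-pass design.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @return The filtered `continuous_recording`.
#' @export
lowpass_filter <- function(rec, order = 4L, cutoff_hz = 5000) {
  if (cutoff_hz >= rec$rate / 2) {
    abort("cutoff must be below the Nyquist frequency",
          class = "graspflow_input_error")
  }
  bf <- signal::butter(order, cutoff_hz / (rec$rate / 2), type = "low")
  n <- ncol(rec$samples)
  # odd-reflection padding suppresses the forward/backward edge transients
  np <- min(n - 1L, max(100L, ceiling(6 * order * rec$rate / cutoff_hz)))
  out <- rec
  for (ci in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ci, ]
    padded <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
    y <- signal::filtfilt(bf, padded)
    out$samples[ci, ] <- y[(np + 1L):(np + n)]
  }
  out
}

#' PCA common-mode artifact cancellation
#'
#' Channels are normalized to unit variance and decomposed with PCA. A
#' principal component is classified as common-mode artifact when at least
#' `channel_frac` of the channels load on it with normalized loading
#' magnitude above `coef_threshold` — broad loading is the signature of a
#' signal shared across channels, whereas spikes and channel noise load
#' locally. Artifact components' projections are subtracted and the signal
#' de-normalized.
#'
#' A unit-norm loading vector can exceed 0.36 on at most
#' `floor(1 / 0.36^2) = 7` channels, so the broad-loading rule only
#' discriminates on small channel blocks. For larger blocks use
#' `mode = "keep_signal"`: a component is kept when at least one channel
#' loads on it above `coef_threshold` (localized, spike-carrying), and
#' removed when every loading is small — the signature of noise spread
#' evenly across many channels. Note that subtracting a projection
#' necessarily leaves a slight negative coupling (about `-1/(n - 1)` for n
#' channels) among the residuals.
#'
#' @param rec A [continuous_recording()] with at least two channels.
#' @param coef_threshold Normalized loading magnitude threshold.
#' @param channel_frac Minimum fraction of channels exceeding the threshold
#'   for the `"remove_common"` rule.
#' @param mode Artifact classification rule (see Details).
#' @return A list with elements `rec` (cleaned recording) and `report`
#'   (tibble of components: loading spread, broad-loading fraction, variance
#'   share, removed flag).
#' @export
pca_artifact_cancel <- function(rec, coef_threshold = 0.36,
                                channel_frac = 0.5,
                                mode = c("remove_common", "keep_signal")) {
  mode <- match.arg(mode)
  x <- rec$samples
  if (nrow(x) < 2) {
    abort("artifact cancellation needs at least 2 channels",
          class = "graspflow_input_error")
  }
  sds <- apply(x, 1, stats::sd)
  sds[sds == 0] <- 1
  z <- x / sds # channels x time, unit variance per channel
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  load <- pc$rotation # channels x components, unit-norm columns
  frac_broad <- colMeans(abs(load) > coef_threshold)
  max_loading <- apply(abs(load), 2, max)
  is_artifact <- if (mode == "remove_common") frac_broad >= channel_frac
                 else max_loading <= coef_threshold
  var_share <- pc$sdev^2 / sum(pc$sdev^2)

  out <- rec
  if (any(is_artifact)) {
    A <- load[, is_artifact, drop = FALSE]
    scores <- pc$x[, is_artifact, drop = FALSE] # time x k
    z_clean <- z - t(scores %*% t(A))
    out$samples <- z_clean * sds
  }
  report <- tibble::tibble(
    component = seq_along(frac_broad),
    frac_broad_loading = frac_broad,
    max_loading = max_loading,
    var_share = var_share,
    removed = is_artifact
  )
  list(rec = out, report = report)
}

#' Threshold spike detection on a spike-band signal
#'
#' Events are negative crossings of `-k * sigma_robust` per channel, with
#' `sigma_robust = median(|x|) / 0.6745` (the MAD-based noise estimate that
#' is insensitive to the spikes themselves). A refractory lockout suppresses
#' re-triggering, and the event time is placed at the trough sample.
#'
#' @param rec A spike-band filtered [continuous_recording()].
#' @param threshold_sd Threshold in robust SDs.
#' @param refractory_ms Lockout after each event.
#' @return A tibble `channel`, `time_ms`, `amplitude`.
#' @export
detect_spikes <- function(rec, threshold_sd = 4.5, refractory_ms = 1) {
  lock <- max(1L, round(refractory_ms / 1000 * rec$rate))
  out <- vector("list", nrow(rec$samples))
  for (ci in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ci, ]
    sigma <- median(abs(x)) / 0.6745
    thr <- -threshold_sd * sigma
    below <- which(x < thr)
    times <- integer(0)
    amps <- numeric(0)
    i <- 1L
    while (i <= length(below)) {
      s <- below[i]
      span <- s:min(s + lock - 1L, length(x))
      trough <- span[which.min(x[span])]
      times <- c(times, trough)
      amps <- c(amps, x[trough])
      # skip all crossings inside the lockout window after the trough
      i <- i + 1L
      while (i <= length(below) && below[i] <= trough + lock) i <- i + 1L
    }
    if (length(times)) {
      out[[ci]] <- tibble::tibble(channel = ci,
                                  time_ms = (times - 1L) / rec$rate * 1000,
                                  amplitude = amps)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(channel = integer(), time_ms = numeric(),
                          amplitude = numeric())
  }
  res
}

#' Rate-based unit quality control
#'
#' Marks units whose mean firing rate over the recording falls below
#' `min_rate_hz`; the boundary is inclusive (exactly `min_rate_hz` passes).
#' Idempotent: re-applying QC never changes the result.
#'
#' @param spikes Spike tibble (`unit_id`, `area`, `spike_time_ms`).
#' @param min_rate_hz Exclusion threshold (Hz).
#' @param duration_ms Recording duration; taken from the `duration_ms`
#'   attribute when present.
#' @param units Optional character vector of all recorded unit ids, so that
#'   completely silent units appear (and fail) too; defaults to the units
#'   present in `spikes`.
#' @return A tibble `unit_id`, `area`, `n_spikes`, `rate_hz`, `qc_pass`.
#' @export
qc_units <- function(spikes, min_rate_hz = 1, duration_ms = NULL,
                     units = NULL) {
  if (is.null(duration_ms)) duration_ms <- attr(spikes, "duration_ms")
  if (is.null(duration_ms) || duration_ms <= 0) {
    abort("duration_ms must be supplied and positive",
          class = "graspflow_input_error")
  }
  counts <- spikes |>
    dplyr::group_by(.data$unit_id, .data$area) |>
    dplyr::summarise(n_spikes = dplyr::n(), .groups = "drop")
  if (!is.null(units)) {
    missing <- setdiff(units, counts$unit_id)
    if (length(missing)) {
      counts <- dplyr::bind_rows(counts, tibble::tibble(
        unit_id = missing, area = NA_character_, n_spikes = 0L))
    }
  }
  counts |>
    dplyr::mutate(rate_hz = .data$n_spikes / (duration_ms / 1000),
                  qc_pass = .data$rate_hz >= min_rate_hz) |>
    dplyr::arrange(.data$unit_id)
}

#' Run the full spike-band preprocessing chain
#'
#' Median subtraction, zero-phase low-pass, PCA artifact cancellation and
#' threshold detection, returning detected events as per-channel spike
#' trains (channels map 1:1 to units in simulation mode) together with a QC
#' table.
#'
#' @param rec A raw [continuous_recording()].
#' @param params A [preprocess_params()].
#' @return A list: `spikes` (tibble `unit_id`, `area`, `spike_time_ms`),
#'   `qc` (from [qc_units()]), `artifact_report`, and the cleaned recording.
#' @export
run_preprocessing <- function(rec, params = preprocess_params()) {
  band <- median_subtract(rec, params$median_window_ms)
  band <- lowpass_filter(band, params$butter_order, params$butter_cutoff_hz)
  cancelled <- pca_artifact_cancel(band, params$pca_coef_threshold,
                                   params$pca_channel_frac, params$pca_mode)
  events <- detect_spikes(cancelled$rec, params$detect_threshold_sd,
                          params$refractory_ms)
  meta <- rec$channel_meta
  unit_of <- function(ch) {
    if ("unit_id" %in% names(meta)) meta$unit_id[match(ch, meta$channel)]
    else sprintf("ch_%03d", ch)
  }
  area_of <- function(ch) {
    if ("area" %in% names(meta)) meta$area[match(ch, meta$channel)]
    else NA_character_
  }
  duration_ms <- ncol(rec$samples) / rec$rate * 1000
  spikes <- tibble::tibble(unit_id = unit_of(events$channel),
                           area = area_of(events$channel),
                           spike_time_ms = events$time_ms) |>
    dplyr::arrange(.data$unit_id, .data$spike_time_ms)
  attr(spikes, "duration_ms") <- duration_ms
  qc <- qc_units(spikes, params$min_rate_hz, duration_ms)
  list(spikes = spikes, qc = qc, artifact_report = cancelled$report,
       rec = cancelled$rec)
}
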