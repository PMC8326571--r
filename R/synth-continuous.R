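# Fixed biphasic extracellular spike template on a unit scale (trough = -1),
# 1 ms long at 30 kS/s.
spike_template <- function(n = 30L) {
  x <- seq(0, 1, length.out = n)
  w <- -exp(-((x - 0.25) / 0.10)^2) + 0.35 * exp(-((x - 0.60) / 0.18)^2)
  w / abs(min(w))
}

# 1/f ("pink") noise of length n at sampling rate `rate`, scaled to sd `sd`.
# Built by amplitude-shaping white Gaussian noise in the frequency domain.
pink_noise <- function(n, rate, sd) {
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  f[f > rate / 2] <- rate - f[f > rate / 2] # two-sided spectrum
  scale <- 1 / sqrt(pmax(f, 1))
  scale[1] <- 0
  x <- Re(stats::fft(stats::fft(rnorm(n)) * scale, inverse = TRUE)) / n
  x / stats::sd(x) * sd
}

#' Construct a continuous-recording container
#'
#' @param samples Channels x time numeric matrix (microvolts).
#' @param rate Sampling rate in Hz.
#' @param channel_meta Optional tibble of per-channel metadata (area labels,
#'   noise flags); defaults to bare channel numbers.
#' @return A list of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, rate = 30000,
                                 channel_meta = NULL) {
  samples <- as.matrix(samples)
  if (rate <= 0) abort("sampling rate must be positive",
                       class = "graspflow_config_error")
  if (is.null(channel_meta)) {
    channel_meta <- tibble::tibble(channel = seq_len(nrow(samples)))
  }
  structure(list(samples = samples, rate = rate, channel_meta = channel_meta),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording> ", nrow(x$samples), " channels x ",
      ncol(x$samples), " samples @ ", x$rate, " Hz\n", sep = "")
  invisible(x)
}

#' Simulate a multichannel broadband recording from spike trains
#'
#' Builds, per channel, the sum of a spike-waveform train (one unit per
#' channel), 1/f channel noise, and a shared common-mode artifact (slow
#' sinusoidal drift plus broadband bursts) applied to all channels up to a
#' per-channel gain. Ground-truth spike sample indices and the artifact
#' component are stored with the recording so that detection and artifact
#' cancellation can be scored exactly.
#'
#' @param spikes Spike tibble from [simulate_spike_trains()] (units are
#'   mapped 1:1 onto channels).
#' @param gen A [generator_settings()].
#' @param seed Integer master seed.
#' @param rate_hz Sampling rate; must match the task configuration when the
#'   recording is attached to a session.
#' @param duration_ms Portion of the session to synthesize.
#' @param channels Unit ids to turn into channels; defaults to the first
#'   `min(6, n_units)` units. Blocks are kept small because a unit-norm
#'   loading vector can exceed the 0.36 broad-loading threshold on at most
#'   `floor(1 / 0.36^2) = 7` channels, so common-mode cancellation operates
#'   on channel blocks of at most that size.
#' @return A `continuous_recording` with a `ground_truth` element listing
#'   per-channel spike sample indices, the artifact trace and channel gains.
#' @export
simulate_continuous <- function(spikes, gen = generator_settings(), seed = 1L,
                                rate_hz = 30000, duration_ms = 10000,
                                channels = NULL) {
  if (rate_hz <= 0) abort("sampling rate must be positive",
                          class = "graspflow_config_error")
  units <- unique(spikes$unit_id)
  if (is.null(channels)) channels <- head(units, 6L)
  n_ch <- length(channels)
  n <- ceiling(duration_ms / 1000 * rate_hz)
  tmpl <- spike_template(max(3L, round(0.001 * rate_hz)))
  amp <- gen$spike_amp_uv

  sig <- matrix(0, nrow = n_ch, ncol = n)
  gt_spk <- vector("list", n_ch)
  for (ci in seq_len(n_ch)) {
    st <- spikes$spike_time_ms[spikes$unit_id == channels[ci]]
    st <- st[st >= 0 & st < duration_ms - 1000 * length(tmpl) / rate_hz]
    idx <- round(st / 1000 * rate_hz) + 1L
    gt_spk[[ci]] <- idx
    for (i in idx) {
      span <- i:(i + length(tmpl) - 1L)
      sig[ci, span] <- sig[ci, span] + amp * tmpl
    }
  }

  withr_seed(substream_seed(seed, 6L), {
    noise <- t(vapply(seq_len(n_ch),
                      function(ci) pink_noise(n, rate_hz, gen$noise_sd_uv),
                      numeric(n)))
    tt <- seq_len(n) / rate_hz
    artifact <- numeric(n)
    if (gen$artifact_gain > 0) {
      for (fr in c(0.7, 1.3, 2.9)) {
        artifact <- artifact +
          gen$artifact_gain * 40 * sin(2 * pi * fr * tt + runif(1, 0, 2 * pi))
      }
      n_burst <- max(1L, round(duration_ms / 2000))
      burst_len <- round(0.05 * rate_hz)
      starts <- sample.int(n - burst_len, n_burst)
      for (b in starts) {
        artifact[b:(b + burst_len - 1L)] <- artifact[b:(b + burst_len - 1L)] +
          gen$artifact_gain * 60 * rnorm(burst_len)
      }
    }
    ch_gain <- rnorm(n_ch, mean = 1, sd = 0.1)
  })
  samples <- sig + noise + outer(ch_gain, artifact)

  rec <- continuous_recording(
    samples, rate_hz,
    channel_meta = tibble::tibble(
      channel = seq_len(n_ch),
      unit_id = channels,
      area = spikes$area[match(channels, spikes$unit_id)]
    )
  )
  rec$ground_truth <- list(spike_samples = gt_spk, artifact = artifact,
                           channel_gain = ch_gain,
                           spike_times_ms = lapply(gt_spk, function(i) (i - 1L) / rate_hz * 1000))
  rec
}
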