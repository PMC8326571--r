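#' Write a session to a directory
#'
#' Serializes a session as plain interchange files: `events.csv` (one row
#' per trial with all event timestamps), `spikes.csv` (`unit_id`, `area`,
#' `spike_time_ms`), `kinematics.csv` (`trial_id`, `time_ms`, `angle_*`),
#' `config.json`, `ground_truth.json`, and — when continuous data is
#' present — `continuous.bin` (int16 channels x samples, channel-major) with
#' a `continuous.json` sidecar (rate, channel count, microvolt gain).
#' Serialization is deterministic: the same session writes byte-identical
#' files.
#'
#' @param session A `grasp_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trials
  tr$object <- as.character(tr$object)
  tr$modality <- as.character(tr$modality)
  write.csv(tr, file.path(dir, "events.csv"), row.names = FALSE)
  if (!is.null(session$spikes)) {
    write.csv(session$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  }
  if (!is.null(session$kinematics)) {
    write.csv(session$kinematics, file.path(dir, "kinematics.csv"),
              row.names = FALSE)
  }
  # named atomic vectors lose their names as JSON arrays; store as objects
  keep_names <- function(x) {
    lapply(x, function(el) {
      if (is.atomic(el) && !is.null(names(el))) as.list(el) else el
    })
  }
  cfg_gen <- list(cfg = keep_names(unclass(session$cfg)),
                  gen = keep_names(unclass(session$gen)))
  jsonlite::write_json(cfg_gen, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  gt <- session$ground_truth
  if (!is.null(gt)) {
    gt_out <- gt
    if (!is.null(gt$units)) {
      gt_out$units <- as.list(gt$units)
    }
    if (!is.null(gt$postures)) {
      gt_out$postures <- apply(gt$postures, 1, identity, simplify = FALSE)
      names(gt_out$postures) <- rownames(gt$postures)
    }
    jsonlite::write_json(gt_out, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(session$continuous)) {
    write_continuous(session$continuous, dir)
  }
  invisible(dir)
}

write_continuous <- function(rec, dir) {
  gain <- max(abs(rec$samples)) / 32000
  if (gain == 0) gain <- 1
  ints <- as.integer(round(rec$samples / gain)) # channel-major (column of t())
  con <- file(file.path(dir, "continuous.bin"), "wb")
  on.exit(close(con))
  writeBin(ints, con, size = 2L, endian = "little")
  jsonlite::write_json(
    list(rate_hz = rec$rate, n_channels = nrow(rec$samples),
         n_samples = ncol(rec$samples), gain_uv_per_lsb = gain,
         layout = "channel_interleaved_int16_le",
         channel_meta = as.list(rec$channel_meta)),
    file.path(dir, "continuous.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read a session directory
#'
#' Inverse of [write_session()]; also the entry point for real recordings
#' laid out in the same on-disk format. Missing optional files yield `NULL`
#' components.
#'
#' @param dir Session directory.
#' @return A `grasp_session` (without ground truth if none was stored).
#' @export
read_session <- function(dir) {
  cfgp <- file.path(dir, "config.json")
  cfg <- NULL; gen <- NULL
  if (file.exists(cfgp)) {
    cj <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
    cfg <- do.call(task_config, cj$cfg[names(formals(task_config))[
      names(formals(task_config)) %in% names(cj$cfg)]])
    genargs <- cj$gen[names(cj$gen) %in% names(formals(generator_settings))]
    genargs$n_units_per_area <- unlist(genargs$n_units_per_area)
    for (nm in c("epoch_gain", "obj_profile", "mod_profile")) {
      genargs[[nm]] <- unlist(genargs[[nm]])
    }
    gen <- do.call(generator_settings, genargs)
  }
  if (is.null(cfg)) cfg <- task_config()

  trials <- tibble::as_tibble(read.csv(file.path(dir, "events.csv")))
  trials$object <- factor(trials$object, levels = object_labels(cfg$n_objects))
  trials$modality <- factor(trials$modality, levels = cfg$modalities)

  spikes <- NULL
  if (file.exists(file.path(dir, "spikes.csv"))) {
    spikes <- tibble::as_tibble(read.csv(file.path(dir, "spikes.csv")))
  }
  kin <- NULL
  if (file.exists(file.path(dir, "kinematics.csv"))) {
    kin <- tibble::as_tibble(read.csv(file.path(dir, "kinematics.csv")))
  }
  gt <- NULL
  if (file.exists(file.path(dir, "ground_truth.json"))) {
    gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
    if (!is.null(gt$units)) gt$units <- tibble::as_tibble(gt$units)
    if (!is.null(gt$postures)) {
      gt$postures <- do.call(rbind, gt$postures)
    }
    if (!is.null(gt$duration_ms) && !is.null(spikes)) {
      attr(spikes, "duration_ms") <- gt$duration_ms
    }
  }
  continuous <- NULL
  if (file.exists(file.path(dir, "continuous.json"))) {
    continuous <- read_continuous(dir)
  }
  structure(list(trials = trials, spikes = spikes, kinematics = kin,
                 continuous = continuous, ground_truth = gt,
                 cfg = cfg, gen = gen),
            class = "grasp_session")
}

#' Read a flat-binary continuous recording
#'
#' Reads an int16 channel-major binary signal file with its JSON sidecar
#' (sampling rate, channel count, microvolt gain), the package's container
#' for broadband data.
#'
#' @param dir Directory containing `continuous.bin` and `continuous.json`.
#' @return A [continuous_recording()].
#' @export
read_continuous <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "continuous.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, "continuous.bin"), "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = meta$n_channels * meta$n_samples,
                  size = 2L, signed = TRUE, endian = "little")
  samples <- matrix(ints * meta$gain_uv_per_lsb, nrow = meta$n_channels)
  cm <- if (!is.null(meta$channel_meta)) tibble::as_tibble(meta$channel_meta) else NULL
  continuous_recording(samples, meta$rate_hz, cm)
}
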