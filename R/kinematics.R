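#' Extract settled-grasp posture features
#'
#' The grip-type feature of a trial is the per-joint arithmetic mean of all
#' glove samples falling in a window after the completed object lift
#' (default 450-550 ms post-lift), when the hand has settled into its final
#' grasp but has not yet released the object. Irregular sampling is handled
#' by the time-windowed mean directly, without interpolation.
#'
#' @param kinematics Tibble `trial_id`, `time_ms`, `angle_*` (degrees).
#' @param trials Validated trials tibble (supplies lift times and labels).
#' @param window Two-element offset window (ms) relative to `object_lifted`;
#'   must lie inside the hold period.
#' @return A tibble `trial_id`, `object`, `modality`, `angle_*` with one row
#'   per trial retained; trials with fewer than 2 samples in the window are
#'   dropped with a warning.
#' @export
extract_grasp_features <- function(kinematics, trials, window = c(450, 550)) {
  tr <- correct_trials(trials)
  hold_ms <- min(tr$hold_end - tr$object_lifted)
  if (window[2] > hold_ms + 1e-9) {
    abort("feature window extends beyond the hold period",
          class = "graspflow_input_error")
  }
  ang_cols <- grep("^angle_", names(kinematics), value = TRUE)
  joined <- dplyr::inner_join(
    kinematics,
    dplyr::select(tr, "trial_id", "object", "modality", "object_lifted"),
    by = "trial_id"
  )
  joined <- joined |>
    dplyr::mutate(rel = .data$time_ms - .data$object_lifted) |>
    dplyr::filter(.data$rel >= window[1], .data$rel <= window[2])
  feats <- joined |>
    dplyr::group_by(.data$trial_id, .data$object, .data$modality) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     dplyr::across(dplyr::all_of(ang_cols), mean),
                     .groups = "drop")
  thin <- feats$n_samples < 2
  if (any(thin)) {
    warn(sprintf("dropping %d trials with < 2 samples in the feature window",
                 sum(thin)))
    feats <- feats[!thin, ]
  }
  dplyr::select(feats, -"n_samples")
}

#' Grip-similarity dendrogram over condition classes
#'
#' Computes pairwise Euclidean distances between class-mean postures (class
#' = object x modality, 12 in the standard task) and clusters them
#' agglomeratively (average linkage by default). Low merge heights between
#' the visual and tactile class of the same object indicate that grip type
#' is independent of the instruction modality.
#'
#' @param features Feature tibble from [extract_grasp_features()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param zscore Standardize each joint angle across classes before
#'   computing distances.
#' @return A list of class `grasp_dendrogram`: `hclust` (tree over class
#'   labels like `"V-sphere"`), `distances` (long tibble of pairwise class
#'   distances), `class_means`.
#' @export
class_distance_dendrogram <- function(features, linkage = "average",
                                      zscore = FALSE) {
  ang_cols <- grep("^angle_", names(features), value = TRUE)
  cls <- paste0(ifelse(features$modality == "visual", "V-", "T-"),
                as.character(features$object))
  counts <- table(cls)
  if (any(counts == 0)) warn("empty classes excluded from the dendrogram")
  if (length(counts) < 2) {
    abort("need at least 2 classes", class = "graspflow_input_error")
  }
  m <- as.matrix(features[, ang_cols])
  means <- rowsum(m, cls) / as.vector(counts[sort(unique(cls))])
  if (zscore) means <- scale(means)
  d <- dist(means)
  hc <- hclust(d, method = linkage)
  dm <- as.matrix(d)
  long <- tibble::as_tibble(as.data.frame.table(dm, responseName = "distance")) |>
    dplyr::rename(class_a = "Var1", class_b = "Var2") |>
    dplyr::filter(as.integer(.data$class_a) < as.integer(.data$class_b)) |>
    dplyr::mutate(class_a = as.character(.data$class_a),
                  class_b = as.character(.data$class_b))
  structure(list(hclust = hc, distances = long, class_means = means),
            class = "grasp_dendrogram")
}

#' @export
print.grasp_dendrogram <- function(x, ...) {
  cat("<grasp_dendrogram> ", nrow(x$class_means), " classes, ",
      x$hclust$method, " linkage\n", sep = "")
  invisible(x)
}

#' @rdname class_distance_dendrogram
#' @param x A `grasp_dendrogram`.
#' @param ... Passed to [plot.hclust()].
#' @export
plot.grasp_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "condition class", sub = "",
                 ylab = "Euclidean distance (deg)", ...)
}

#' @rdname class_distance_dendrogram
#' @export
tidy.grasp_dendrogram <- function(x, ...) x$distances

#' Decode condition labels from grasp kinematics
#'
#' Trial-balanced leave-one-out LDA (see [balanced_loo()]) on settled-grasp
#' posture features, under the full object x modality scheme or either
#' marginal scheme. When grasp postures are identical across modalities,
#' modality-only decoding sits at the 2-class chance level while
#' object-only decoding stays high — the signature that grip type carries
#' object but not modality information.
#'
#' @param features Feature tibble from [extract_grasp_features()].
#' @param scheme `"full"` (object x modality), `"object"`, or `"modality"`.
#' @param seed Integer seed for the per-fold balancing subsample.
#' @param lambda_frac Diagonal-loading fraction for the LDA covariance.
#' @return A `confusion` object (see [balanced_loo()]).
#' @export
kinematic_decoding <- function(features, scheme = c("full", "object", "modality"),
                               seed = 1L, lambda_frac = 0.1) {
  balanced_loo(features, scheme = match.arg(scheme), seed = seed,
               lambda_frac = lambda_frac)
}
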