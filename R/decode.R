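#' Chance level for K-class classification
#'
#' Expected accuracy of uniform random guessing: `100 / k` percent
#' (8.33% for the 12 object-x-modality classes, 16.66% for 6 objects,
#' 50% for the 2 modalities).
#'
#' @param k Number of classes.
#' @return Chance accuracy in percent.
#' @export
chance_level <- function(k) {
  if (any(k < 1)) abort("k must be >= 1", class = "graspflow_input_error")
  100 / k
}

#' Epoch specifications for neural decoding
#'
#' Named 500 ms analysis epochs: `early_memory` is the first 500 ms of the
#' memory period, `late_memory` the last 500 ms before the go cue, and
#' `grasp` the 500 ms from movement onset.
#'
#' @param name Epoch name.
#' @return A list `name`, `align` (event column), `window` (ms offsets).
#' @export
epoch_spec <- function(name = c("early_memory", "late_memory", "grasp")) {
  name <- match.arg(name)
  switch(name,
    early_memory = list(name = name, align = "memory_start", window = c(0, 500)),
    late_memory  = list(name = name, align = "go", window = c(-500, 0)),
    grasp        = list(name = name, align = "movement_onset", window = c(0, 500))
  )
}

#' Epoch-mean firing-rate features
#'
#' One row per correct trial, one column per unit, entries in Hz: spike
#' count inside the trial's epoch window divided by the window length.
#'
#' @param spikes Spike tibble (`unit_id`, `spike_time_ms`).
#' @param trials Validated trials tibble.
#' @param epoch An [epoch_spec()] or its name.
#' @param units Optional character vector restricting (and ordering) the
#'   unit columns, e.g. the QC-passing units.
#' @return A feature tibble `trial_id`, `object`, `modality`, then one
#'   numeric column per unit.
#' @export
epoch_rates <- function(spikes, trials, epoch = "grasp", units = NULL) {
  if (is.character(epoch)) epoch <- epoch_spec(epoch)
  tr <- correct_trials(trials)
  align <- tr[[epoch$align]]
  lo <- align + epoch$window[1]
  hi <- align + epoch$window[2]
  width_s <- (epoch$window[2] - epoch$window[1]) / 1000
  if (is.null(units)) units <- sort(unique(spikes$unit_id))
  by_unit <- split(spikes$spike_time_ms, spikes$unit_id)
  feat <- vapply(units, function(u) {
    st <- sort(by_unit[[u]] %||% numeric(0))
    (findInterval(hi, st) - findInterval(lo, st)) / width_s
  }, numeric(nrow(tr)))
  feat <- matrix(feat, nrow = nrow(tr), dimnames = list(NULL, units))
  dplyr::bind_cols(
    dplyr::select(tr, "trial_id", "object", "modality"),
    tibble::as_tibble(feat)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("trial_id", "object", "modality"))
  m <- as.matrix(features[, cols])
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("features must not contain missing values",
                      class = "graspflow_input_error")
  m
}

scheme_labels <- function(features, scheme = c("full", "object", "modality")) {
  scheme <- match.arg(scheme)
  obj_lv <- levels(droplevels(factor(features$object)))
  lv <- switch(scheme,
    full = c(paste0("V-", obj_lv), paste0("T-", obj_lv)),
    object = obj_lv,
    modality = c("visual", "tactile")
  )
  lab <- switch(scheme,
    full = paste0(ifelse(features$modality == "visual", "V-", "T-"),
                  as.character(features$object)),
    object = as.character(features$object),
    modality = as.character(features$modality)
  )
  factor(lab, levels = lv)
}

#' Fit a regularized linear discriminant model
#'
#' Class means with a pooled within-class covariance, diagonally loaded with
#' `lambda = lambda_frac * mean(diag(Sigma))` so the fit remains well-posed
#' when features outnumber (balanced) training trials. Priors are equal
#' (training is balanced upstream). Prediction is the argmax of the linear
#' discriminant score, which equals the nearest class mean under the pooled
#' Mahalanobis metric; ties break to the lowest class index.
#'
#' When decoding a marginal label (e.g. modality only), the known finer
#' condition structure (object x modality) can be passed as `strata`: the
#' pooled covariance is then computed within strata, so variance between
#' conditions of the same class is treated as signal structure rather than
#' noise.
#'
#' @param x Numeric feature matrix (trials x features).
#' @param labels Factor of class labels, one per row.
#' @param lambda_frac Diagonal-loading fraction.
#' @param strata Optional factor of nuisance strata for the covariance pool;
#'   defaults to `labels`.
#' @return A list of class `grasp_lda`.
#' @export
lda_fit <- function(x, labels, lambda_frac = 0.1, strata = NULL) {
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  if (k < 2) abort("need at least 2 classes", class = "graspflow_input_error")
  n_k <- table(labels)
  if (any(n_k < 1)) abort("every class needs at least one training trial",
                          class = "graspflow_input_error")
  x <- as.matrix(x)
  means <- rowsum(x, labels) / as.vector(n_k)
  strata <- if (is.null(strata)) labels else droplevels(as.factor(strata))
  mu_s <- rowsum(x, strata) / as.vector(table(strata))
  centered <- x - mu_s[as.integer(strata), , drop = FALSE]
  df <- max(nrow(x) - nlevels(strata), 1L)
  sigma <- crossprod(centered) / df
  lambda <- lambda_frac * mean(diag(sigma))
  if (lambda <= 0) lambda <- 1e-8 # degenerate all-zero features
  sigma_inv <- chol2inv(chol(sigma + diag(lambda, ncol(x))))
  structure(list(means = means, sigma_inv = sigma_inv, lambda = lambda,
                 lambda_frac = lambda_frac, classes = levels(labels),
                 n_per_class = as.vector(n_k)),
            class = "grasp_lda")
}

#' @rdname lda_fit
#' @param object A `grasp_lda` model.
#' @param newdata Feature matrix to classify.
#' @param ... Unused.
#' @return `predict()`: factor of predicted classes.
#' @export
predict.grasp_lda <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = ncol(object$means))
  w <- object$sigma_inv %*% t(object$means)          # features x K
  b <- -0.5 * colSums(t(object$means) * w)           # -(1/2) mu' S^-1 mu
  scores <- sweep(newdata %*% w, 2, b, `+`)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.grasp_lda <- function(x, ...) {
  cat("<grasp_lda> ", length(x$classes), " classes, ",
      ncol(x$means), " features, lambda = ", signif(x$lambda, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname lda_fit
#' @param x A `grasp_lda` model (for `tidy()`).
#' @export
tidy.grasp_lda <- function(x, ...) {
  tibble::tibble(class = x$classes, n_train = x$n_per_class,
                 mean = lapply(seq_along(x$classes),
                               function(i) unname(x$means[i, ])))
}

#' Trial-balanced leave-one-out decoding
#'
#' For every trial: hold it out, randomly subsample the remaining trials so
#' that every condition contributes the same number (so no condition or
#' modality is over-represented in training), fit the regularized LDA, and
#' classify the held-out trial. Results accumulate into a row-normalized
#' confusion matrix (rows = instructed class, columns = decoded class,
#' entries in percent); overall accuracy is the mean of the diagonal, i.e.
#' balanced accuracy.
#'
#' Balancing operates at the finest condition level (object x modality) when
#' those columns are present, even under a marginal scheme, and the same
#' condition factor stratifies the LDA covariance pool (see [lda_fit()]).
#' With explicit `labels`, balancing and covariance pooling use the labels
#' themselves.
#'
#' @param features Feature tibble (`trial_id`, `object`, `modality`, numeric
#'   feature columns) or a numeric matrix (then supply `labels`).
#' @param scheme Label scheme: `"full"` (object x modality), `"object"`, or
#'   `"modality"`; ignored when `labels` is given.
#' @param labels Optional explicit factor of class labels.
#' @param seed Integer seed for the balancing subsamples (one draw per fold).
#' @param lambda_frac Diagonal-loading fraction for [lda_fit()].
#' @param log_folds Record per-fold training class counts in a `fold_log`
#'   element (for auditing the balancing).
#' @return A list of class `confusion`: `matrix` (percent), `counts`,
#'   `n_per_class`, `accuracy`, `chance`, `scheme`, `seed`.
#' @export
balanced_loo <- function(features, scheme = c("full", "object", "modality"),
                         labels = NULL, seed = 1L, lambda_frac = 0.1,
                         log_folds = FALSE) {
  if (is.null(labels)) {
    scheme <- match.arg(scheme)
    labels <- scheme_labels(features, scheme)
    x <- feature_matrix(features)
    cond <- interaction(features$object, features$modality, drop = TRUE)
  } else {
    scheme <- "custom"
    labels <- as.factor(labels)
    x <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
    cond <- labels
  }
  labels <- droplevels(labels)
  cond <- droplevels(cond)
  k <- nlevels(labels)
  n <- nrow(x)
  if (any(table(labels) < 2)) {
    abort("every class needs at least 2 trials", class = "graspflow_input_error")
  }
  counts <- matrix(0L, k, k, dimnames = list(instructed = levels(labels),
                                             decoded = levels(labels)))
  skipped <- 0L
  fold_log <- if (log_folds) vector("list", n) else NULL
  withr_seed(substream_seed(seed, 9L), {
    for (i in seq_len(n)) {
      train_lab <- labels[-i]
      if (nlevels(droplevels(train_lab)) < k) { skipped <- skipped + 1L; next }
      train_cond <- cond[-i]
      m <- min(table(train_cond))
      keep <- unlist(lapply(levels(cond), function(cl) {
        idx <- which(train_cond == cl)
        if (length(idx) > m) sample(idx, m) else idx
      }))
      train_idx <- seq_len(n)[-i][keep]
      if (log_folds) {
        fold_log[[i]] <- tibble::tibble(
          fold = i, class = levels(labels),
          n_train = as.vector(table(labels[train_idx])))
      }
      fit <- lda_fit(x[train_idx, , drop = FALSE], labels[train_idx],
                     lambda_frac, strata = cond[train_idx])
      pred <- predict(fit, x[i, , drop = FALSE])
      counts[as.integer(labels[i]), as.integer(pred)] <-
        counts[as.integer(labels[i]), as.integer(pred)] + 1L
    }
  })
  row_n <- rowSums(counts)
  pct <- counts / ifelse(row_n == 0, 1, row_n) * 100
  structure(list(matrix = pct, counts = counts, n_per_class = row_n,
                 accuracy = mean(diag(pct)), chance = chance_level(k),
                 scheme = scheme, seed = as.integer(seed),
                 lambda_frac = lambda_frac, n_skipped = skipped,
                 fold_log = if (log_folds) dplyr::bind_rows(fold_log) else NULL),
            class = "confusion")
}

#' Decode a marginal label scheme
#'
#' Collapses the labels to the requested marginal (object identity or
#' sensory modality) before running [balanced_loo()]. Collapsing 12 balanced
#' object-x-modality classes to modality yields 2 classes of six-fold size.
#'
#' @inheritParams balanced_loo
#' @param scheme `"object"` or `"modality"`.
#' @return A `confusion` object.
#' @export
marginal_decode <- function(features, scheme = c("object", "modality"),
                            seed = 1L, lambda_frac = 0.1) {
  balanced_loo(features, scheme = match.arg(scheme), seed = seed,
               lambda_frac = lambda_frac)
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion> ", nrow(x$matrix), " classes (", x$scheme, "), accuracy ",
      sprintf("%.1f%%", x$accuracy), " (chance ",
      sprintf("%.2f%%", x$chance), ")\n", sep = "")
  invisible(x)
}

#' @rdname balanced_loo
#' @param x A `confusion` object.
#' @param ... Unused.
#' @export
tidy.confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$matrix, responseName = "percent")) |>
    dplyr::mutate(instructed = factor(.data$instructed, rownames(x$matrix)),
                  decoded = factor(.data$decoded, colnames(x$matrix)))
}

#' @rdname balanced_loo
#' @export
glance.confusion <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, chance = x$chance,
                 k = nrow(x$matrix), n_trials = sum(x$counts),
                 scheme = x$scheme, seed = x$seed)
}
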