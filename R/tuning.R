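#' Bin spike counts in sliding windows
#'
#' Counts spikes per unit, trial and window, with windows of `window_ms`
#' centered on a grid of `stride_ms` steps relative to an alignment event
#' (window w covers `[center - window/2, center + window/2)` ms). Windows
#' that would extend beyond the recorded data in any trial are trimmed off
#' the grid with a message.
#'
#' @param spikes Spike tibble (`unit_id`, `area`, `spike_time_ms`).
#' @param trials Validated trials tibble.
#' @param align Event column to align windows to.
#' @param window_ms Window length (ms).
#' @param stride_ms Step between window centers (ms).
#' @param range_ms Center grid limits relative to the alignment event.
#' @param units Optional unit id vector restricting/ordering the units
#'   (e.g. QC-passing units only).
#' @return A list of class `binned_counts`: `counts` (units x trials x
#'   windows integer array), `centers_ms`, `window_ms`, `stride_ms`,
#'   `align`, `trials`, `units`.
#' @export
bin_spikes <- function(spikes, trials, align = "go", window_ms = 100,
                       stride_ms = 10, range_ms = c(-1000, 500),
                       units = NULL) {
  tr <- correct_trials(trials)
  if (!align %in% names(tr) || anyNA(tr[[align]])) {
    abort("alignment event must be present in every included trial",
          class = "graspflow_input_error")
  }
  centers <- seq(range_ms[1], range_ms[2], by = stride_ms)
  duration_ms <- attr(spikes, "duration_ms")
  if (!is.null(duration_ms)) {
    at <- tr[[align]]
    ok <- vapply(centers, function(ce) {
      all(at + ce - window_ms / 2 >= 0) && all(at + ce + window_ms / 2 <= duration_ms)
    }, logical(1))
    if (!all(ok)) {
      message(sprintf("trimming %d windows extending beyond the recording",
                      sum(!ok)))
      centers <- centers[ok]
    }
  }
  if (is.null(units)) units <- sort(unique(spikes$unit_id))
  unit_tbl <- tibble::tibble(
    unit_id = units,
    area = spikes$area[match(units, spikes$unit_id)]
  )
  by_unit <- split(spikes$spike_time_ms, spikes$unit_id)
  n_t <- nrow(tr)
  n_w <- length(centers)
  counts <- array(0L, dim = c(length(units), n_t, n_w))
  abs_centers <- outer(tr[[align]], centers, `+`)
  lo <- abs_centers - window_ms / 2
  hi <- abs_centers + window_ms / 2
  for (u in seq_along(units)) {
    st <- sort(by_unit[[units[u]]] %||% numeric(0))
    counts[u, , ] <- findInterval(hi, st) - findInterval(lo, st)
  }
  structure(list(counts = counts, centers_ms = centers, window_ms = window_ms,
                 stride_ms = stride_ms, align = align,
                 trials = dplyr::select(tr, "trial_id", "object", "modality"),
                 units = unit_tbl),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  d <- dim(x$counts)
  cat("<binned_counts> ", d[1], " units x ", d[2], " trials x ", d[3],
      " windows (", x$window_ms, " ms window, ", x$stride_ms,
      " ms stride, aligned to ", x$align, ")\n", sep = "")
  invisible(x)
}

# Residual sum of squares of every column of Y under the projection with
# orthonormal basis Q (columns).
rss_under <- function(Y, Q) {
  pmax(colSums(Y^2) - colSums(crossprod(Q, Y)^2), 0)
}

# F and p from an RSS comparison; degenerate fits (zero residual) give p = 1
# when the effect sum of squares is also zero, p = 0 otherwise.
f_test_cols <- function(rss_null, rss_full, df1, df2, total_ss) {
  eps <- 1e-10 * (total_ss + 1)
  num <- pmax(rss_null - rss_full, 0)
  f <- (num / df1) / (rss_full / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  degenerate <- rss_full < eps
  p[degenerate & num < eps] <- 1
  p[degenerate & num >= eps] <- 0
  f[degenerate & num < eps] <- 0
  f[degenerate & num >= eps] <- Inf
  list(f = f, p = p)
}

#' Sliding two-way ANOVA over binned spike counts
#'
#' For every unit and window, a fixed-effects two-way ANOVA of the spike
#' count on object (six levels) and sensory modality (two levels),
#' main effects only by default. Effects are tested by model comparison
#' (partial, type-II sums of squares): the object effect compares the
#' additive model against modality-only, and vice versa, which reduces to
#' the classical balanced-design sums of squares when cell counts are equal.
#' Windows where all counts are identical are not significant (p = 1).
#'
#' @param binned A [bin_spikes()] result.
#' @param interaction Also test the object x modality interaction (the main
#'   effects stay additive-model comparisons).
#' @param per_modality Replace the two-way object effect by one-way object
#'   ANOVAs restricted to each modality's trials (factors
#'   `"object_visual"`, `"object_tactile"`), matching per-modality tuning
#'   displays.
#' @return A tibble `unit_id`, `area`, `factor`, `window_center_ms`,
#'   `statistic` (F), `df1`, `df2`, `p`.
#' @export
sliding_anova <- function(binned, interaction = FALSE, per_modality = FALSE) {
  tr <- binned$trials
  obj <- droplevels(factor(tr$object))
  mod <- droplevels(factor(tr$modality))
  if (any(table(obj, mod) < 2)) {
    abort("need at least 2 trials per object x modality cell",
          class = "graspflow_input_error")
  }
  d <- dim(binned$counts)
  n_u <- d[1]; n_t <- d[2]; n_w <- d[3]
  Y <- matrix(aperm(binned$counts, c(2, 1, 3)), nrow = n_t) # trials x (units*windows)
  total_ss <- colSums(Y^2)

  res <- list()
  # Y columns vary unit fastest within window; expand_grid varies its last
  # column fastest, so list the window grid first
  grid <- tidyr::expand_grid(window_center_ms = binned$centers_ms,
                             unit_id = binned$units$unit_id)[, c(2, 1)]
  grid$area <- binned$units$area[match(grid$unit_id, binned$units$unit_id)]

  if (!per_modality) {
    q_add <- qr.Q(qr(stats::model.matrix(~ obj + mod)))
    q_obj <- qr.Q(qr(stats::model.matrix(~ obj)))
    q_mod <- qr.Q(qr(stats::model.matrix(~ mod)))
    rss_add <- rss_under(Y, q_add)
    df2 <- n_t - ncol(q_add)
    t_obj <- f_test_cols(rss_under(Y, q_mod), rss_add,
                         nlevels(obj) - 1, df2, total_ss)
    t_mod <- f_test_cols(rss_under(Y, q_obj), rss_add,
                         nlevels(mod) - 1, df2, total_ss)
    res$object <- t_obj
    res$modality <- t_mod
    dfs <- list(object = c(nlevels(obj) - 1, df2),
                modality = c(nlevels(mod) - 1, df2))
    if (interaction) {
      q_int <- qr.Q(qr(stats::model.matrix(~ obj * mod)))
      df2i <- n_t - ncol(q_int)
      df1i <- ncol(q_int) - ncol(q_add)
      res$interaction <- f_test_cols(rss_add, rss_under(Y, q_int),
                                     df1i, df2i, total_ss)
      dfs$interaction <- c(df1i, df2i)
    }
  } else {
    res <- list()
    dfs <- list()
    for (mlev in levels(mod)) {
      sel <- mod == mlev
      Ym <- Y[sel, , drop = FALSE]
      objm <- droplevels(obj[sel])
      q1 <- qr.Q(qr(stats::model.matrix(~ objm)))
      q0 <- matrix(1 / sqrt(sum(sel)), sum(sel), 1)
      nm <- paste0("object_", mlev)
      res[[nm]] <- f_test_cols(rss_under(Ym, q0), rss_under(Ym, q1),
                               nlevels(objm) - 1, sum(sel) - nlevels(objm),
                               colSums(Ym^2))
      dfs[[nm]] <- c(nlevels(objm) - 1, sum(sel) - nlevels(objm))
    }
    res$modality <- {
      q1 <- qr.Q(qr(stats::model.matrix(~ mod)))
      q0 <- matrix(1 / sqrt(n_t), n_t, 1)
      f_test_cols(rss_under(Y, q0), rss_under(Y, q1),
                  nlevels(mod) - 1, n_t - nlevels(mod), total_ss)
    }
    dfs$modality <- c(nlevels(mod) - 1, n_t - nlevels(mod))
  }

  dplyr::bind_rows(lapply(names(res), function(fac) {
    tibble::tibble(unit_id = grid$unit_id, area = grid$area,
                   factor = fac, window_center_ms = grid$window_center_ms,
                   statistic = res[[fac]]$f, df1 = dfs[[fac]][1],
                   df2 = dfs[[fac]][2], p = res[[fac]]$p)
  }))
}

#' Fraction of tuned units over time
#'
#' A unit is tuned at a window when its ANOVA p-value survives the
#' multiple-comparison correction: with Bonferroni, `p < alpha / m`, where
#' the family size m is the number of windows tested per unit and factor.
#' The fraction per area, factor and window is the number of tuned units
#' over the number of analyzed (QC-passing) units in that area.
#'
#' @param pvals Tibble from [sliding_anova()].
#' @param alpha Significance level before correction.
#' @param correction `"bonferroni"` or `"none"`.
#' @return A tibble of class `tuning_timecourse`: `area`, `factor`,
#'   `window_center_ms`, `n_tuned`, `n_units`, `fraction`, with `alpha`,
#'   `correction` and the per-factor family size as attributes.
#' @export
tuned_fraction <- function(pvals, alpha = 0.05,
                           correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  fam <- pvals |>
    dplyr::distinct(.data$factor, .data$window_center_ms) |>
    dplyr::count(.data$factor, name = "m")
  pv <- dplyr::left_join(pvals, fam, by = "factor") |>
    dplyr::mutate(threshold = if (correction == "bonferroni") alpha / .data$m
                  else alpha,
                  tuned = !is.na(.data$p) & .data$p < .data$threshold)
  out <- pv |>
    dplyr::group_by(.data$area, .data$factor, .data$window_center_ms) |>
    dplyr::summarise(n_tuned = sum(.data$tuned), n_units = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_tuned / .data$n_units)
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  attr(out, "family_size") <- setNames(fam$m, fam$factor)
  class(out) <- c("tuning_timecourse", class(out))
  out
}
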