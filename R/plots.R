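#' Plot a timing histogram
#'
#' Reaction- or movement-time distribution per modality, with the display
#' cutoff of the summary (values beyond it contribute to the mean but not
#' the bars).
#'
#' @param object A [timing_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.timing_summary <- function(object, ...) {
  lab <- if (object$measure == "rt") "reaction time (ms)" else "movement time (ms)"
  ggplot2::ggplot(object$hist,
                  ggplot2::aes(x = .data$bin_left + object$bin_ms / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = object$bin_ms, fill = "grey30") +
    ggplot2::facet_wrap(~modality, ncol = 1) +
    ggplot2::labs(x = lab, y = "trials",
                  title = paste0(object$phase, " phase")) +
    ggplot2::theme_minimal()
}

#' Plot tuning time courses
#'
#' Fraction of significantly tuned units over window centers, one line per
#' area, faceted by factor.
#'
#' @param object A [tuned_fraction()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tuning_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_center_ms,
                                       y = 100 * .data$fraction,
                                       colour = .data$area)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~factor) +
    ggplot2::labs(x = "time from alignment event (ms)",
                  y = "tuned units (%)", colour = "area") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Instructed condition on the x-axis, decoded condition on the y-axis,
#' cell shading in percent of the instructed class.
#'
#' @param object A `confusion` object from [balanced_loo()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$instructed, y = .data$decoded,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "instructed condition", y = "decoded condition",
                  fill = "%",
                  subtitle = sprintf("accuracy %.1f%% (chance %.2f%%)",
                                     object$accuracy, object$chance)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
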