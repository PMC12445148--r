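#' Plot a PLV spectrum
#'
#' @param object a [plv_spectrum()].
#' @param max_freq_hz upper frequency limit for the plot.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plv_spectrum <- function(object, max_freq_hz = NULL, ...) {
  df <- tidy(object)
  df <- df[df$freq_hz > 0, ]
  if (!is.null(max_freq_hz)) df <- df[df$freq_hz <= max_freq_hz, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$plv)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "Phase-locking value",
      subtitle = sprintf("%s windows, %d epochs", object$window, object$n_epochs)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sustained response time course
#'
#' @param object a `sustained_result` from [sustained_timecourse()].
#' @param transition_s optional transition time to mark.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sustained_result <- function(object, transition_s = NULL, ...) {
  p <- ggplot2::ggplot(object$timecourse,
                       ggplot2::aes(x = .data$time_s, y = .data$rms)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Time from stimulus onset (s)",
                  y = expression(RMS ~ amplitude ~ (mu * V))) +
    ggplot2::theme_minimal()
  if (!is.null(transition_s)) {
    p <- p + ggplot2::geom_vline(xintercept = transition_s, linetype = 2)
  }
  p
}

#' Plot envelope-change PLV by AM-rate jump
#'
#' @param delta_table output of [ecfr_by_delta()].
#' @return a ggplot.
#' @export
plot_ecfr_by_delta <- function(delta_table) {
  df <- delta_table
  df$delta <- factor(df$delta_nominal_hz, levels = sort(df$delta_nominal_hz))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$plv)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "AM-rate difference (Hz, signed)",
                  y = "PLV at the envelope-change rate") +
    ggplot2::theme_minimal()
}

#' Plot asymmetry indices by component
#'
#' @param ai_table output of [asymmetry_table()]; only included rows are
#'   drawn.
#' @return a ggplot.
#' @export
plot_asymmetry <- function(ai_table) {
  df <- ai_table[ai_table$included, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$ai)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3, colour = "red") +
    ggplot2::labs(x = NULL, y = "Asymmetry index (C - I)/(C + I)") +
    ggplot2::theme_minimal()
}
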