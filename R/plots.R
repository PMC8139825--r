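# ggplot2 graphics for the main result types.

#' Plot a PSTH
#'
#' @param psth A [compute_psth()] tibble (or several row-bound together
#'   with a grouping column mapped via `colour`).
#' @param colour Optional column name to colour traces by.
#' @return A ggplot.
#' @export
plot_psth <- function(psth, colour = NULL) {
  p <- ggplot2::ggplot(psth, ggplot2::aes(x = .data$time_ms,
                                          y = .data$rate_hz))
  if (!is.null(colour))
    p <- p + ggplot2::geom_line(ggplot2::aes(
      colour = .data[[colour]]))
  else p <- p + ggplot2::geom_line()
  p + ggplot2::labs(x = "Time (ms)", y = "Firing rate (Hz)")
}

#' @rdname autoplot-gustate
#' @method autoplot classifier_result
#' @export
autoplot.classifier_result <- function(object, ...) {
  df <- as_tibble(as.data.frame(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Overall accuracy %.1f%% (chance 25%%)",
                                  100 * object$overall_accuracy),
                  x = "Predicted taste", y = "Delivered taste")
}

#' ggplot2 autoplot methods for gustate objects
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name autoplot-gustate
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' @rdname autoplot-gustate
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, ...) {
  h <- object$histogram
  df <- h %>% mutate(predicted = object$predicted_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_ms)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "Laser impact latency (ms)", y = "Count",
                  title = sprintf("Mixture fit: peaks %.0f / %.0f ms",
                                  object$means_ms[1], object$means_ms[2]))
}

#' @rdname autoplot-gustate
#' @method autoplot hmm_model
#' @export
autoplot.hmm_model <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$unit),
                                 y = .data$rate_hz,
                                 fill = factor(.data$state))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Unit", y = "State firing rate (Hz)",
                  fill = "State")
}

#' Plot posterior state probabilities for one trial
#'
#' @param posterior `bins x states` matrix from [decode_hmm()].
#' @param bin_ms,window_start_ms Time axis of the posteriors.
#' @return A ggplot.
#' @export
plot_state_posterior <- function(posterior, bin_ms = 10,
                                 window_start_ms = 0) {
  df <- as_tibble(posterior, .name_repair = ~ paste0("S", seq_along(.x)))
  df$time_ms <- window_start_ms + (seq_len(nrow(df)) - 1) * bin_ms
  tidyr::pivot_longer(df, -"time_ms", names_to = "state",
                      values_to = "probability") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$time_ms,
                                 y = .data$probability,
                                 colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "Time (ms)", y = "State posterior probability")
}

#' @rdname autoplot-gustate
#' @method autoplot slope_comparison
#' @export
autoplot.slope_comparison <- function(object, ...) {
  j <- object$records
  ggplot2::ggplot(j, ggplot2::aes(x = .data$max_slope_hz_ms_off,
                                  y = .data$max_slope_hz_ms_on)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(
      x = "Control max PSTH slope (Hz/ms)",
      y = "Perturbed max PSTH slope (Hz/ms)",
      title = sprintf("On ~ Off regression slope %.2f",
                      object$regression$slope))
}

#' Plot a palatability-correlation trace
#'
#' @param trace A [palatability_correlation()] or aggregate trace tibble
#'   (columns `time_ms` and `rho` or `mean_abs_rho`).
#' @return A ggplot.
#' @export
plot_palatability_trace <- function(trace) {
  y <- intersect(c("mean_abs_rho", "rho"), names(trace))[1]
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_ms,
                                      y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Time (ms)", y = "Spearman rho")
}
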