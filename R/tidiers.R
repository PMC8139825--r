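# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = 1:2, weight = x$weights, mean_ms = x$means_ms,
         sd_ms = x$sds_ms)
}

#' @rdname tidiers
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(log_lik = x$log_lik, r_squared = x$r_squared, n = x$n,
         n_iter = length(x$loglik_trace), degenerate = x$degenerate)
}

#' @rdname tidiers
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = c("amplitude", "decay_per_ms"),
         estimate = c(x$amplitude, x$decay_per_ms))
}

#' @rdname tidiers
#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n)
}

#' Tidiers for gustate model objects
#'
#' [tidy()] returns per-term (or per-component / per-state) estimates;
#' [glance()] returns one-row fit summaries.
#'
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  dplyr::rename(x$estimates, estimate = "mean", conf_low = "lower",
                conf_high = "upper")
}

#' @rdname tidiers
#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  s <- x$estimates[x$estimates$parameter == "slope", ]
  tibble(slope = s$mean, slope_low = s$lower, slope_high = s$upper,
         max_rhat = x$max_rhat, converged = x$converged)
}

#' @rdname tidiers
#' @method tidy hmm_model
#' @export
tidy.hmm_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_states), function(s)
    tibble(state = s, unit = seq_len(x$n_units),
           rate_hz = x$rates_hz[, s]))
}

#' @rdname tidiers
#' @method glance hmm_model
#' @export
glance.hmm_model <- function(x, ...) {
  tibble(n_states = x$n_states, n_units = x$n_units,
         n_trials = length(x$trials), log_lik = x$loglik,
         n_iter = x$n_iter, converged = x$converged,
         restart = x$restart)
}

#' @rdname tidiers
#' @method tidy classifier_result
#' @export
tidy.classifier_result <- function(x, ...) x$per_taste_accuracy

#' @rdname tidiers
#' @method glance classifier_result
#' @export
glance.classifier_result <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy, n_tested = x$n_tested,
         n_ties = x$n_ties, train = x$train_condition,
         test = x$test_condition)
}

#' @rdname tidiers
#' @method tidy slope_comparison
#' @export
tidy.slope_comparison <- function(x, ...) x$regression

#' @rdname tidiers
#' @method glance slope_comparison
#' @export
glance.slope_comparison <- function(x, ...) {
  tibble(regression_slope = x$regression$slope,
         p_vs_1 = x$regression$p_vs_1,
         latency_chisq_p = x$latency_chisq$p_value,
         latency_t_p = x$latency_t$p_value,
         n_units = x$regression$n_units)
}
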