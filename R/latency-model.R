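# Models of the laser-impact latency distribution: a 2-component Gaussian
# mixture fitted to the raw latencies by EM (best of several random
# restarts), and an exponential decay fitted by least squares to the
# 100 ms-binned histogram. Goodness of fit for both is summarised as a
# coefficient of determination against the same histogram, and the models
# are compared by a paired t-test on per-bin absolute errors (25 bins,
# df = 24).

latency_histogram <- function(latencies_ms, bin_ms = 100, span = c(0, 2500)) {
  breaks <- seq(span[1], span[2], by = bin_ms)
  counts <- graphics::hist(latencies_ms[latencies_ms >= span[1] &
                                          latencies_ms < span[2]],
                           breaks = breaks, plot = FALSE, right = FALSE)$counts
  tibble(mid_ms = breaks[-length(breaks)] + bin_ms / 2, count = counts)
}

#' Fit a two-component Gaussian mixture to latency samples
#'
#' Maximum-likelihood EM fit on the raw samples (not the histogram), best
#' of `restarts` random initializations; components are returned sorted by
#' mean. The log-likelihood trace of the winning run is retained and is
#' non-decreasing. If the two components collapse onto one point the fit
#' is flagged degenerate. R-squared is computed against the 100 ms-binned
#' histogram of the data.
#'
#' @param latencies_ms Numeric latency sample (ms), at least 10 values.
#' @param restarts Number of EM restarts.
#' @param seed Integer seed controlling the restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return A `mixture_fit` object: `weights`, `means_ms`, `sds_ms`,
#'   `log_lik`, `loglik_trace`, `r_squared`, `degenerate`, `n`.
#' @export
fit_mixture <- function(latencies_ms, restarts = 10, seed = 1,
                        max_iter = 500, tol = 1e-8) {
  x <- as.numeric(latencies_ms)
  if (length(x) < 10) stop("need at least 10 latencies", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    q <- sort(runif(2, 0.1, 0.9))
    init <- list(w = c(0.5, 0.5),
                 mu = unname(quantile(x, q)),
                 sd = rep(max(sd(x) / 2, 1e-3), 2))
    fit <- em_gauss2(x, init, max_iter, tol)
    if (is.null(best) || fit$log_lik > best$log_lik) best <- fit
  }
  o <- order(best$mu)
  hist_tbl <- latency_histogram(x)
  dens <- function(t) best$w[1] * dnorm(t, best$mu[1], best$sd[1]) +
    best$w[2] * dnorm(t, best$mu[2], best$sd[2])
  pred <- dens(hist_tbl$mid_ms) * length(x) * 100
  out <- structure(list(
    weights = best$w[o], means_ms = best$mu[o], sds_ms = best$sd[o],
    log_lik = best$log_lik, loglik_trace = best$trace,
    r_squared = r_squared(hist_tbl$count, pred),
    degenerate = abs(diff(best$mu)) < 1e-6 || any(best$sd < 1e-6),
    n = length(x), predicted_counts = pred, histogram = hist_tbl),
    class = "mixture_fit")
  out
}

# EM for a 2-component univariate Gaussian mixture.
em_gauss2 <- function(x, init, max_iter, tol) {
  w <- init$w; mu <- init$mu; s <- pmax(init$sd, 1e-4)
  n <- length(x)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    s <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                sum((1 - g1) * (x - mu[2])^2) / n2))
    s <- pmax(s, 1e-4)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = s, log_lik = trace[length(trace)],
       trace = trace)
}

r_squared <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> means:", sprintf("%.1f", x$means_ms),
      "ms; sds:", sprintf("%.1f", x$sds_ms),
      "; weights:", sprintf("%.2f", x$weights),
      "; R^2 =", sprintf("%.3f", x$r_squared),
      if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' Fit an exponential decay to the latency histogram
#'
#' Least-squares fit of `A * exp(-lambda * t)` to the 100 ms-binned
#' latency histogram over `[0, 2500)` ms.
#'
#' @param latencies_ms Numeric latency sample (ms), at least 10 values.
#' @return An `exp_fit` object: `amplitude`, `decay_per_ms`, `r_squared`,
#'   `predicted_counts`, `histogram`.
#' @export
fit_exponential <- function(latencies_ms) {
  x <- as.numeric(latencies_ms)
  if (length(x) < 10) stop("need at least 10 latencies", call. = FALSE)
  h <- latency_histogram(x)
  if (all(h$count == 0)) stop("all-zero histogram", call. = FALSE)
  lam0 <- 1 / max(mean(x), 1)
  fit <- minpack.lm::nlsLM(
    count ~ A * exp(-lambda * mid_ms), data = h,
    start = list(A = max(h$count), lambda = lam0),
    lower = c(A = 0, lambda = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  pred <- predict(fit)
  cf <- coef(fit)
  structure(list(amplitude = unname(cf["A"]),
                 decay_per_ms = unname(cf["lambda"]),
                 r_squared = r_squared(h$count, pred),
                 predicted_counts = pred, histogram = h, n = length(x)),
            class = "exp_fit")
}

#' Compare mixture and exponential fits of a latency distribution
#'
#' Fits both models and compares them on the 25 x 100 ms histogram: the
#' coefficients of determination, and a paired t-test across the 25 bins
#' of the absolute per-bin errors |model - observed| (df = 24). A negative
#' t favours the mixture (smaller errors).
#'
#' @inheritParams fit_mixture
#' @return A list: `mixture`, `exponential` (the two fits),
#'   `r2_mixture`, `r2_exp`, `t`, `df`, `p_value`.
#' @export
compare_fits <- function(latencies_ms, restarts = 10, seed = 1) {
  mf <- fit_mixture(latencies_ms, restarts = restarts, seed = seed)
  ef <- fit_exponential(latencies_ms)
  obs <- mf$histogram$count
  err_m <- abs(mf$predicted_counts - obs)
  err_e <- abs(ef$predicted_counts - obs)
  if (all(err_m == err_e)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(obs) - 1),
               p.value = 1)
  } else {
    tt <- t.test(err_m, err_e, paired = TRUE)
  }
  list(mixture = mf, exponential = ef,
       r2_mixture = mf$r_squared, r2_exp = ef$r_squared,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
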