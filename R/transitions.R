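# Peri-transition dynamics on realigned trials: moving-window palatability
# correlation about the transition, Bayesian 4-parameter logistic fits of
# correlation vs time (conditions differ significantly when their 95%
# slope credible intervals do not overlap), per-unit peri-transition PSTH
# slopes and max-slope latencies, and Off-vs-On comparisons.

# Per-trial mean rate (Hz) of `unit` in [from, to) ms of realigned time;
# NA-padded bins are excluded; trials with fewer than half the window
# observed give NA.
realigned_window_rates <- function(re, unit, from, to) {
  cols <- which(re$time_ms >= from & re$time_ms < to)
  m <- matrix(re$rasters[, unit, cols], nrow = dim(re$rasters)[1])
  n_ok <- rowSums(!is.na(m))
  rate <- rowSums(m, na.rm = TRUE) / (n_ok / 1000)
  rate[n_ok < length(cols) / 2] <- NA_real_
  rate
}

#' Palatability-correlation time-course about the state transition
#'
#' Moving-window Spearman correlation between single-trial firing rates
#' and palatability ranks, computed on trials re-aligned to their
#' state-transition onsets (time 0 = transition). Returned per unit,
#' together with an across-unit aggregate (mean |rho| per window).
#'
#' @param re A [realign()]ed ensemble.
#' @param window_ms,step_ms Moving-window geometry (default 250/25 ms).
#' @param alpha Per-window significance level.
#' @return A tibble `unit`, `time_ms` (window centre relative to the
#'   transition), `rho`, `p_value`; attribute `aggregate` holds the mean
#'   |rho| trace.
#' @export
aligned_palatability_trace <- function(re, window_ms = 250, step_ms = 25,
                                       alpha = 0.05) {
  rk <- palatability_map()
  ranks <- rk$rank[match(re$trial_table$taste, rk$taste)]
  span <- re$span
  starts <- seq(span[1], span[2] - window_ms, by = step_ms)
  n_units <- dim(re$rasters)[2]
  out <- purrr::map_dfr(seq_len(n_units), function(u) {
    purrr::map_dfr(starts, function(s) {
      rate <- realigned_window_rates(re, u, s, s + window_ms)
      ok <- !is.na(rate)
      if (sum(ok) < 8 || var(rate[ok]) == 0)
        return(tibble(unit = u, time_ms = s + window_ms / 2,
                      rho = NA_real_, p_value = NA_real_))
      ct <- suppressWarnings(cor.test(rate[ok], ranks[ok],
                                      method = "spearman", exact = FALSE))
      tibble(unit = u, time_ms = s + window_ms / 2,
             rho = unname(ct$estimate), p_value = ct$p.value)
    })
  })
  agg <- out %>%
    group_by(.data$time_ms) %>%
    summarise(mean_abs_rho = mean(abs(.data$rho), na.rm = TRUE),
              .groups = "drop")
  attr(out, "aggregate") <- agg
  out
}

sigmoid_model_string <- "
model {
  for (i in 1:N) {
    mu[i] <- lower + (upper - lower) / (1 + exp(-slope * (t[i] - t0)))
    y[i] ~ dnorm(mu[i], tau)
  }
  lower ~ dnorm(0, 1)
  upper ~ dnorm(0, 1)
  slope ~ dnorm(0, 100) T(0,)
  t0 ~ dunif(t_min, t_max)
  sigma ~ dnorm(0, 1) T(0,)
  tau <- 1 / (sigma * sigma + 1e-10)
}"

#' Bayesian 4-parameter logistic fit of a correlation time-course
#'
#' Fits `y(t) = lower + (upper - lower) / (1 + exp(-slope (t - t0)))`
#' with Gaussian observation noise by MCMC: normal priors on the
#' asymptotes, half-normal on the logistic growth rate (`slope`, 1/ms)
#' and noise SD, uniform over the observed span on the inflection time.
#' Two fits are deemed significantly different when their 95% slope
#' credible intervals do not overlap.
#'
#' @param trace A tibble with `time_ms` and the response in `value`
#'   (or the column named by `response`).
#' @param response Name of the response column (default `"value"`, with
#'   fallbacks `mean_abs_rho` / `rho`).
#' @param n_iter,n_warmup,n_chains MCMC settings.
#' @param seed Integer seed.
#' @return A `sigmoid_fit`: `estimates` tibble (posterior mean and 95%
#'   credible interval per parameter), `draws` matrix, `converged`
#'   diagnostic flag.
#' @export
fit_sigmoid <- function(trace, response = NULL, n_iter = 2000,
                        n_warmup = 1000, n_chains = 2, seed = 1) {
  if (is.null(response))
    response <- intersect(c("value", "mean_abs_rho", "rho"),
                          names(trace))[1]
  y <- trace[[response]]
  t <- trace$time_ms
  ok <- is.finite(y)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 20) stop("need at least 20 windows", call. = FALSE)
  dat <- list(y = y, t = t, N = length(y),
              t_min = min(t), t_max = max(t))
  inits <- lapply(seq_len(n_chains), function(k)
    list(t0 = unname(quantile(t, 0.5)), lower = min(y), upper = max(y),
         slope = 0.02, sigma = max(sd(y) / 2, 1e-3),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = seed * 1000 + k))
  jm <- rjags::jags.model(textConnection(sigmoid_model_string), data = dat,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_warmup, quiet = TRUE)
  samp <- rjags::coda.samples(jm, c("lower", "upper", "slope", "t0",
                                    "sigma"),
                              n.iter = n_iter, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  est <- purrr::map_dfr(c("lower", "upper", "slope", "t0", "sigma"),
                        function(p) {
    ci <- unname(quantile(draws[, p], c(0.025, 0.975)))
    tibble(parameter = p, mean = mean(draws[, p]),
           lower = ci[1], upper = ci[2])
  })
  rhat <- tryCatch(
    max(coda::gelman.diag(samp, autoburnin = FALSE,
                          multivariate = FALSE)$psrf[, 1]),
    error = function(e) NA_real_)
  structure(list(estimates = est, draws = draws,
                 max_rhat = rhat,
                 converged = !is.finite(rhat) || rhat < 1.1),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  s <- x$estimates[x$estimates$parameter == "slope", ]
  cat(sprintf("<sigmoid_fit> slope %.4f [%.4f, %.4f] /ms%s\n", s$mean,
              s$lower, s$upper,
              if (!x$converged) " (convergence warning)" else ""))
  invisible(x)
}

#' Do two sigmoid fits differ significantly in slope?
#'
#' @param fit_a,fit_b [fit_sigmoid()] objects.
#' @return TRUE when the 95% slope credible intervals do not overlap.
#' @export
slopes_differ <- function(fit_a, fit_b) {
  a <- fit_a$estimates[fit_a$estimates$parameter == "slope", ]
  b <- fit_b$estimates[fit_b$estimates$parameter == "slope", ]
  a$upper < b$lower || b$upper < a$lower
}

#' Per-unit peri-transition PSTH slopes
#'
#' For each unit, the realigned-trial PSTH is scanned with a moving
#' window (100 ms window, 20 ms step); within each window the firing
#' rate is regressed on time, and the maximum |slope| among windows whose
#' centres fall within the peri-transition period (default +/-160 ms
#' about the transition) is recorded along with its latency.
#'
#' @param re A [realign()]ed ensemble.
#' @param window_ms,step_ms Moving-window geometry.
#' @param period_ms Half-width of the peri-transition period (ms).
#' @param per_taste If TRUE (default) one record per unit x taste
#'   response (the PSTH of each taste separately); FALSE pools all
#'   realigned trials per unit.
#' @return A tibble per record: `unit` (and `taste` when `per_taste`),
#'   `max_slope_hz_ms` (|slope|, Hz/ms), `signed_slope_hz_ms`,
#'   `latency_ms` (window centre of the max).
#' @export
peri_transition_slopes <- function(re, window_ms = 100, step_ms = 20,
                                   period_ms = 160, per_taste = TRUE) {
  if (!dim(re$rasters)[1]) stop("no valid trials", call. = FALSE)
  n_units <- dim(re$rasters)[2]
  span <- re$span
  starts <- seq(span[1], span[2] - window_ms, by = step_ms)
  centers <- starts + window_ms / 2
  keep <- centers >= -period_ms & centers <= period_ms
  starts <- starts[keep]; centers <- centers[keep]
  groups <- if (per_taste) {
    lapply(TASTES, function(tst) which(re$trial_table$taste == tst))
  } else list(seq_len(dim(re$rasters)[1]))
  names(groups) <- if (per_taste) TASTES else "all"
  purrr::map_dfr(seq_len(n_units), function(u) {
    purrr::map_dfr(names(groups), function(gname) {
      rows <- groups[[gname]]
      if (!length(rows))
        return(tibble(unit = u, taste = gname,
                      max_slope_hz_ms = NA_real_,
                      signed_slope_hz_ms = NA_real_,
                      latency_ms = NA_real_))
      psth <- colMeans(matrix(re$rasters[rows, u, ],
                              nrow = length(rows)),
                       na.rm = TRUE) * 1000  # Hz per 1-ms bin
      slopes <- vapply(starts, function(s) {
        cols <- which(re$time_ms >= s & re$time_ms < s + window_ms)
        y <- psth[cols]
        x <- re$time_ms[cols]
        ok <- is.finite(y)
        if (sum(ok) < 3) return(NA_real_)
        unname(coef(lm(y[ok] ~ x[ok]))[2])
      }, numeric(1))
      k <- which.max(abs(slopes))
      tibble(unit = u, taste = gname,
             max_slope_hz_ms = abs(slopes[k]),
             signed_slope_hz_ms = slopes[k], latency_ms = centers[k])
    })
  })
}

#' Compare peri-transition slopes between laser conditions
#'
#' Given paired per-unit slope records from control (Off) and perturbed
#' (On) trials: (1) ordinary least squares of On slopes on Off slopes
#' with a t-test of the fitted slope against 1 (a sub-unity slope means
#' perturbation shallows firing-rate changes); (2) units grouped into
#' quintiles of the Off slope, with a paired Off-vs-On test per group;
#' (3) a chi-squared comparison of the max-slope latency histograms
#' (20 ms bins); (4) a paired t-test of per-unit latencies.
#'
#' @param records_off,records_on [peri_transition_slopes()] tibbles for
#'   the two conditions (matched units).
#' @param latency_bin_ms Histogram bin width for the latency comparison.
#' @return A `slope_comparison` list: `regression` (slope, intercept, se,
#'   `t_vs_1`, `p_vs_1`), `groups` tibble (or NULL if < 5 units, flagged
#'   by `groups_skipped`), `latency_chisq` (statistic, df, p), and
#'   `latency_t` (paired t on latencies).
#' @export
compare_slope_conditions <- function(records_off, records_on,
                                     latency_bin_ms = 20) {
  keys <- intersect(c("unit", "taste"),
                    intersect(names(records_off), names(records_on)))
  j <- dplyr::inner_join(records_off, records_on, by = keys,
                         suffix = c("_off", "_on")) %>%
    filter(is.finite(.data$max_slope_hz_ms_off),
           is.finite(.data$max_slope_hz_ms_on))
  if (!nrow(j)) stop("no matched units", call. = FALSE)
  fit <- lm(max_slope_hz_ms_on ~ max_slope_hz_ms_off, data = j)
  sm <- suppressWarnings(summary(fit))$coefficients
  b <- sm[2, 1]; se <- sm[2, 2]
  if (se < 1e-12) {  # exact fit (e.g. On records identical to Off)
    t1 <- if (abs(b - 1) < 1e-9) 0 else sign(b - 1) * Inf
    p1 <- if (abs(b - 1) < 1e-9) 1 else 0
  } else {
    t1 <- (b - 1) / se
    p1 <- 2 * pt(-abs(t1), df = nrow(j) - 2)
  }
  regression <- tibble(slope = b, intercept = sm[1, 1], se = se,
                       t_vs_1 = t1, p_vs_1 = p1, n_units = nrow(j))

  groups_skipped <- nrow(j) < 5
  groups <- NULL
  if (!groups_skipped) {
    qs <- quantile(j$max_slope_hz_ms_off, seq(0, 1, 0.2))
    grp <- cut(j$max_slope_hz_ms_off, unique(qs), include.lowest = TRUE)
    groups <- j %>%
      mutate(group = grp) %>%
      group_by(.data$group) %>%
      summarise(
        n = dplyr::n(),
        mean_off = mean(.data$max_slope_hz_ms_off),
        mean_on = mean(.data$max_slope_hz_ms_on),
        p_value = if (dplyr::n() >= 2 &&
                      sd(.data$max_slope_hz_ms_off -
                         .data$max_slope_hz_ms_on) > 0)
          t.test(.data$max_slope_hz_ms_off, .data$max_slope_hz_ms_on,
                 paired = TRUE)$p.value else NA_real_,
        .groups = "drop")
  }

  breaks <- seq(-160 - latency_bin_ms, 160 + latency_bin_ms,
                by = latency_bin_ms)
  h_off <- graphics::hist(j$latency_ms_off, breaks = breaks,
                          plot = FALSE)$counts
  h_on <- graphics::hist(j$latency_ms_on, breaks = breaks,
                         plot = FALSE)$counts
  keep <- h_off + h_on > 0
  chi <- if (sum(keep) >= 2) {
    suppressWarnings(chisq.test(rbind(h_off[keep], h_on[keep])))
  } else list(statistic = c(X = 0), parameter = c(df = 0), p.value = 1)
  dl <- j$latency_ms_off - j$latency_ms_on
  lt <- if (nrow(j) >= 2 && sd(dl) > 0) {
    t.test(j$latency_ms_off, j$latency_ms_on, paired = TRUE)
  } else list(statistic = c(t = 0), parameter = c(df = nrow(j) - 1),
              p.value = 1, estimate = c(mean = mean(dl)))
  structure(list(
    regression = regression, groups = groups,
    groups_skipped = groups_skipped,
    latency_chisq = tibble(statistic = unname(chi$statistic),
                           df = unname(chi$parameter),
                           p_value = chi$p.value),
    latency_t = tibble(statistic = unname(lt$statistic),
                       df = unname(lt$parameter),
                       p_value = lt$p.value,
                       mean_diff_ms = unname(lt$estimate[1])),
    records = j), class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  r <- x$regression
  cat(sprintf("<slope_comparison> On~Off slope %.2f (p vs 1: %.3g), %d units\n",
              r$slope, r$p_vs_1, r$n_units))
  invisible(x)
}

#' Full state-transition analysis for one ensemble
#'
#' For each taste and laser condition: fits a Poisson ensemble HMM,
#' identifies the target state as the one dominating `state_window`
#' (500-1500 ms for the palatability state; 100-600 ms for the identity
#' state), extracts per-trial 0.5-threshold onsets, and re-aligns trials.
#' Pooled across tastes per condition it then computes the aligned
#' palatability-correlation trace, its Bayesian sigmoid fit, per-unit
#' peri-transition slopes, and the Off-vs-On slope/latency comparison.
#'
#' @param dataset An [ensemble_dataset()].
#' @param state_window `c(from, to)` ms window defining the target state.
#' @param n_states,bin_ms,restarts,hmm_max_iter [fit_hmm()] settings.
#' @param span Realignment span about the onset (ms).
#' @param period_ms Peri-transition period half-width for slopes (ms).
#' @param seed Integer seed.
#' @param sigmoid Whether to run the Bayesian sigmoid fits (slowest
#'   stage).
#' @param shared_fit If TRUE, fit HMMs on Off trials only and decode On
#'   trials with the same model (default FALSE: separate fit per
#'   condition).
#' @return A `transition_analysis` list: per-condition `alignment`,
#'   `realigned`, `trace`, `slopes`, `sigmoid`; plus `comparison`
#'   ([compare_slope_conditions()]), `sigmoid_differs`, and the settings.
#' @export
transition_analysis <- function(dataset, state_window = c(500, 1500),
                                n_states = 4, bin_ms = 10, restarts = 10,
                                hmm_max_iter = 100, span = c(-700, 700),
                                period_ms = 160, seed = 1,
                                sigmoid = TRUE, shared_fit = FALSE) {
  conds <- c("off", "on")
  res <- list()
  for (cd in conds) res[[cd]] <- list(alignment = NULL)
  for (ti in seq_along(TASTES)) {
    tst <- TASTES[ti]
    m_off <- fit_hmm(dataset, taste = tst, laser = "off",
                     n_states = n_states, bin_ms = bin_ms,
                     restarts = restarts, seed = seed + 17 * ti,
                     max_iter = hmm_max_iter)
    st_off <- identify_state(m_off, decode_trials(m_off, dataset),
                             window = state_window)
    al_off <- align_trials(m_off, dataset, st_off)
    res$off$alignment <- bind_rows(res$off$alignment, al_off)
    if (shared_fit) {
      on_trials <- intersect(condition_trials(dataset, "on"),
                             which(dataset$trial_table$taste == tst))
      al_on <- align_trials(m_off, dataset, st_off, trials = on_trials)
    } else {
      m_on <- fit_hmm(dataset, taste = tst, laser = "on",
                      n_states = n_states, bin_ms = bin_ms,
                      restarts = restarts, seed = seed + 17 * ti + 1,
                      max_iter = hmm_max_iter)
      st_on <- identify_state(m_on, decode_trials(m_on, dataset),
                              window = state_window)
      al_on <- align_trials(m_on, dataset, st_on)
    }
    res$on$alignment <- bind_rows(res$on$alignment, al_on)
  }
  for (cd in conds) {
    re <- realign(dataset, res[[cd]]$alignment, span = span)
    res[[cd]]$realigned <- re
    res[[cd]]$trace <- aligned_palatability_trace(re)
    res[[cd]]$slopes <- peri_transition_slopes(re, period_ms = period_ms)
    if (sigmoid) {
      agg <- attr(res[[cd]]$trace, "aggregate")
      res[[cd]]$sigmoid <- fit_sigmoid(agg, response = "mean_abs_rho",
                                       seed = seed + match(cd, conds))
    }
  }
  cmp <- compare_slope_conditions(res$off$slopes, res$on$slopes)
  structure(list(
    off = res$off, on = res$on, comparison = cmp,
    sigmoid_differs = if (sigmoid)
      slopes_differ(res$off$sigmoid, res$on$sigmoid) else NA,
    state_window = state_window, span = span, seed = seed),
    class = "transition_analysis")
}
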