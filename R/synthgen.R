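# Ground-truth-labelled synthetic ensembles. Each trial runs through an
# epoch sequence (baseline -> detection at 0 -> identity at identity_onset
# -> palatability at a per-trial Gaussian-drawn switch); laser trials apply
# a per-unit multiplicative rate factor from the unit's laser onset and,
# optionally, blur the late switch into a linear ramp or jitter it per unit.

#' Configuration for the synthetic ensemble generator
#'
#' Defaults encode the response structure the downstream analyses assume:
#' 30 trials per taste with half of them laser-perturbed; a nonspecific
#' detection epoch over 0-200 ms; taste-specific identity firing from
#' 200 ms with each unit preferring one taste (round-robin, +8 Hz); a
#' palatability epoch whose rate is the unit baseline plus a signed
#' per-rank gain, entered at a per-trial switch drawn from
#' `N(transition_mean_ms, transition_sd_ms)` truncated to
#' `(identity_onset_ms + 50, 2400)`; and a unimodal laser effect per unit
#' (here: every other unit suppressed to x0.5, onsets alternating 350 and
#' 750 ms, matching the two latency modes the package models).
#'
#' @param n_units Number of simultaneously recorded units.
#' @param n_trials_per_taste Trials per taste (default 30).
#' @param laser_fraction Fraction of trials per taste that are laser-On.
#' @param baseline_rate_hz Per-unit baseline rate (Hz), recycled to
#'   `n_units`.
#' @param detection_rate_hz Per-unit nonspecific rate over
#'   `[0, identity_onset_ms)`.
#' @param identity_rates_hz `n_units x 4` matrix of identity-epoch rates
#'   (columns in canonical taste order Sucrose, NaCl, Acid, QHCl).
#' @param palatability_gain_hz Signed per-unit gain: palatability-epoch
#'   rate is `max(0, baseline + gain * (rank - 2.5))`.
#' @param transition_mean_ms,transition_sd_ms Gaussian parameters of the
#'   per-trial identity-to-palatability switch.
#' @param identity_onset_ms Fixed onset of the identity epoch (ms).
#' @param laser_effect Per-unit multiplicative rate factor on laser trials
#'   (suppression < 1 or enhancement > 1; unimodal per unit).
#' @param laser_onset_ms Per-unit laser-impact onset (ms).
#' @param blur_ms On laser trials, duration of the linear rate ramp
#'   replacing the step at the late switch (0 = sharp step).
#' @param blur_identity_ms As `blur_ms` but applied to the identity-epoch
#'   onset (default 0: the early transition is untouched).
#' @param decouple_sd_ms On laser trials, SD of an independent per-unit
#'   jitter of the switch time (the "decoupled transitions" alternative to
#'   rate blurring; 0 disables it).
#' @param half_width_ms Per-unit spike half-widths for the unit table.
#' @param session_id Session label.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_units = 10,
                             n_trials_per_taste = 30,
                             laser_fraction = 0.5,
                             baseline_rate_hz =
                               exp(seq(log(1.5), log(15),
                                       length.out = n_units)),
                             detection_rate_hz = baseline_rate_hz + 4,
                             identity_rates_hz = NULL,
                             palatability_gain_hz =
                               rep_len(c(1, -1), n_units) *
                               seq(1.5, 6, length.out = n_units),
                             transition_mean_ms = 700,
                             transition_sd_ms = 150,
                             identity_onset_ms = 200,
                             laser_effect = rep_len(c(0.5, 1), n_units),
                             laser_onset_ms = rep_len(c(350, 750), n_units),
                             blur_ms = 0,
                             blur_identity_ms = 0,
                             decouple_sd_ms = 0,
                             half_width_ms = rep_len(c(0.25, 0.45), n_units),
                             session_id = "synthetic-01") {
  baseline_rate_hz <- rep_len(baseline_rate_hz, n_units)
  detection_rate_hz <- rep_len(detection_rate_hz, n_units)
  if (is.null(identity_rates_hz)) {
    # broadly tuned units: a graded, per-unit-scaled boost over a
    # preference order rotated across units, on top of baseline + 1
    pref <- ((seq_len(n_units) - 1L) %% 4L) + 1L
    boost <- seq(5, 20, length.out = n_units)
    tuning <- c(1, 0.4, 0.15, 0)  # preferred -> least-preferred
    identity_rates_hz <- matrix(baseline_rate_hz + 1, n_units, 4)
    for (u in seq_len(n_units)) {
      ord <- ((pref[u] + 0:3 - 1L) %% 4L) + 1L
      identity_rates_hz[u, ord] <- identity_rates_hz[u, ord] +
        boost[u] * tuning
    }
  }
  identity_rates_hz <- as.matrix(identity_rates_hz)
  stopifnot(nrow(identity_rates_hz) == n_units,
            ncol(identity_rates_hz) == 4,
            laser_fraction >= 0, laser_fraction <= 1,
            transition_sd_ms >= 0, blur_ms >= 0, blur_identity_ms >= 0,
            all(baseline_rate_hz >= 0), all(detection_rate_hz >= 0),
            all(identity_rates_hz >= 0), all(laser_effect >= 0))
  structure(list(
    n_units = n_units, n_trials_per_taste = n_trials_per_taste,
    laser_fraction = laser_fraction,
    baseline_rate_hz = baseline_rate_hz,
    detection_rate_hz = detection_rate_hz,
    identity_rates_hz = identity_rates_hz,
    palatability_gain_hz = rep_len(palatability_gain_hz, n_units),
    transition_mean_ms = transition_mean_ms,
    transition_sd_ms = transition_sd_ms,
    identity_onset_ms = identity_onset_ms,
    laser_effect = rep_len(laser_effect, n_units),
    laser_onset_ms = rep_len(laser_onset_ms, n_units),
    blur_ms = blur_ms, blur_identity_ms = blur_identity_ms,
    decouple_sd_ms = decouple_sd_ms,
    half_width_ms = rep_len(half_width_ms, n_units),
    session_id = session_id), class = "generator_config")
}

#' Generate a synthetic ensemble with ground truth
#'
#' Spikes are drawn as inhomogeneous Bernoulli events per 1-ms bin with
#' probability `rate/1000`, the discrete-time equivalent of an
#' inhomogeneous Poisson process at these rates. The per-trial rate profile
#' of each unit follows the epoch sequence described in
#' [generator_config()]; on laser trials the profile is multiplied by the
#' unit's laser factor from its laser onset onwards, and the late switch
#' can be blurred (linear ramp) or decoupled (per-unit jitter).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `dataset` (an [ensemble_dataset()]) and `truth`, a
#'   list of tibbles: `trials` (per-trial true switch time) and `units`
#'   (per-unit laser direction/onset, taste-specificity flag and
#'   palatability slope sign).
#' @export
generate_ensemble <- function(config, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  cf <- config
  n_tr <- cf$n_trials_per_taste * 4L
  n_time <- 4500L
  t0 <- -2000L
  t_ms <- seq.int(t0, t0 + n_time - 1L)  # bin start times
  post <- t_ms >= 0

  ranks <- setNames(palatability_map()$rank, palatability_map()$taste)
  n_on <- round(cf$n_trials_per_taste * cf$laser_fraction)
  trial_table <- purrr::map_dfr(TASTES, function(tst) {
    tibble(taste = tst,
           laser_on = rep(c(TRUE, FALSE),
                          c(n_on, cf$n_trials_per_taste - n_on)))
  })
  trial_table <- trial_table %>%
    mutate(trial = seq_len(n()), .before = 1)

  lo <- cf$identity_onset_ms + 50
  hi <- 2400
  trans <- rnorm(n_tr, cf$transition_mean_ms, cf$transition_sd_ms)
  for (k in 1:100) {  # rejection truncation to (lo, hi)
    bad <- trans <= lo | trans >= hi
    if (!any(bad)) break
    trans[bad] <- rnorm(sum(bad), cf$transition_mean_ms,
                        cf$transition_sd_ms)
  }
  trans <- pmin(pmax(trans, lo + 1), hi - 1)

  pal_rate <- function(u, rank)
    max(0, cf$baseline_rate_hz[u] + cf$palatability_gain_hz[u] * (rank - 2.5))

  ras <- array(0L, dim = c(n_tr, cf$n_units, n_time))
  for (i in seq_len(n_tr)) {
    tst <- trial_table$taste[i]
    on <- trial_table$laser_on[i]
    rk <- ranks[[tst]]
    for (u in seq_len(cf$n_units)) {
      tr_u <- trans[i]
      if (on && cf$decouple_sd_ms > 0)
        tr_u <- min(max(tr_u + rnorm(1, 0, cf$decouple_sd_ms), lo), hi)
      r_id <- cf$identity_rates_hz[u, match(tst, TASTES)]
      r_pal <- pal_rate(u, rk)
      rate <- rep(cf$baseline_rate_hz[u], n_time)
      rate[post & t_ms < cf$identity_onset_ms] <- cf$detection_rate_hz[u]
      blur_id <- if (on) cf$blur_identity_ms else 0
      rate <- apply_switch(rate, t_ms, cf$identity_onset_ms,
                           cf$detection_rate_hz[u], r_id, blur_id,
                           from = cf$identity_onset_ms, to = 2500)
      blur_late <- if (on) cf$blur_ms else 0
      rate <- apply_switch(rate, t_ms, tr_u, r_id, r_pal, blur_late,
                           from = cf$identity_onset_ms, to = 2500)
      if (on && cf$laser_effect[u] != 1) {
        w <- t_ms >= cf$laser_onset_ms[u] & t_ms < 2500
        rate[w] <- rate[w] * cf$laser_effect[u]
      }
      p <- rate / 1000
      if (any(p > 1))
        stop("per-bin spike probability exceeds 1; reduce rates",
             call. = FALSE)
      ras[i, u, ] <- as.integer(runif(n_time) < p)
    }
  }

  unit_table <- tibble(
    unit = seq_len(cf$n_units),
    half_width_ms = cf$half_width_ms,
    session_id = cf$session_id)
  ds <- ensemble_dataset(ras, trial_table, unit_table, t0_ms = t0)

  id_spread <- apply(cf$identity_rates_hz, 1, function(r) diff(range(r)))
  truth <- list(
    trials = trial_table %>% mutate(transition_ms = trans),
    units = unit_table %>% mutate(
      laser_effect = cf$laser_effect,
      laser_direction = dplyr::case_when(
        cf$laser_effect < 1 ~ "suppressed",
        cf$laser_effect > 1 ~ "enhanced",
        TRUE ~ "none"),
      laser_onset_ms = cf$laser_onset_ms,
      taste_specific = id_spread > 0 | cf$palatability_gain_hz != 0,
      palatability_sign = sign(cf$palatability_gain_hz)))
  list(dataset = ds, truth = truth)
}

# Overwrite `rate` for t >= switch with rate `after`; with blur > 0 the
# before->after change becomes a linear ramp of that duration centred on
# the switch time, restricted to [from, to).
apply_switch <- function(rate, t_ms, switch_ms, before, after, blur,
                         from, to) {
  win <- t_ms >= from & t_ms < to
  if (blur <= 0) {
    w <- win & t_ms >= switch_ms
    rate[w] <- after
  } else {
    ramp0 <- switch_ms - blur / 2
    ramp1 <- switch_ms + blur / 2
    w <- win & t_ms >= ramp0 & t_ms < ramp1
    frac <- (t_ms[w] - ramp0) / blur
    rate[w] <- before + frac * (after - before)
    w2 <- win & t_ms >= ramp1
    rate[w2] <- after
  }
  pmax(rate, 0)
}

#' Draw laser-impact latencies from a two-component Gaussian mixture
#'
#' Samples latencies from a 2-component Gaussian mixture truncated to
#' `[0, 2500]` ms, for calibrating the latency-distribution fits.
#'
#' @param weights Length-2 mixture weights summing to 1.
#' @param means_ms,sds_ms Length-2 component means and SDs (ms), `sds > 0`.
#' @param n Number of draws (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of `n` latencies (ms).
#' @export
generate_latencies <- function(weights = c(0.5, 0.5),
                               means_ms = c(347.28, 754.39),
                               sds_ms = c(110, 179),
                               n = 2000, seed = 1) {
  stopifnot(length(weights) == 2, length(means_ms) == 2,
            length(sds_ms) == 2, all(sds_ms > 0),
            abs(sum(weights) - 1) < 1e-8)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    comp <- 1L + (runif(m) >= weights[1])
    x <- rnorm(m, means_ms[comp], sds_ms[comp])
    out <- c(out, x[x >= 0 & x <= 2500])
  }
  out[seq_len(n)]
}
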