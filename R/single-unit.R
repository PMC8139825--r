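# Per-unit statistics: responsivity (paired t vs baseline), taste
# specificity (two-way repeated-measures ANOVA), spike-width cell typing,
# moving-window palatability correlation, laser-impact latency and
# per-bin direction profiles.

#' Taste responsivity of each unit
#'
#' A unit is taste-responsive if its evoked firing rate (0-2000 ms
#' post-delivery) differs from the pre-stimulus baseline (-2000-0 ms) by a
#' paired t-test across trials, collapsed over all tastes. A unit whose
#' rate rises to some tastes and falls equally to others can fail this
#' test while still being taste-specific.
#'
#' @param dataset An [ensemble_dataset()].
#' @param condition Trials to use: `"off"`, `"on"` or `"both"`.
#' @param alpha Two-sided significance level.
#' @return A tibble, one row per unit: `unit`, `statistic` (t), `p_value`,
#'   `responsive`.
#' @export
taste_responsivity <- function(dataset, condition = "both", alpha = 0.05) {
  trials <- condition_trials(dataset, condition)
  if (!length(trials)) stop("no trials in condition", call. = FALSE)
  purrr::map_dfr(seq_len(dim(dataset$rasters)[2]), function(u) {
    base <- unit_window_counts(dataset, u, -2000, 0, trials) / 2
    evok <- unit_window_counts(dataset, u, 0, 2000, trials) / 2
    tt <- t.test(evok, base, paired = TRUE)
    tibble(unit = u, statistic = unname(tt$statistic),
           p_value = tt$p.value, responsive = tt$p.value < alpha)
  })
}

condition_trials <- function(dataset, condition) {
  condition <- match.arg(tolower(condition), c("off", "on", "both"))
  switch(condition,
         off = which(!dataset$trial_table$laser_on),
         on = which(dataset$trial_table$laser_on),
         both = seq_len(nrow(dataset$trial_table)))
}

#' Taste specificity of each unit
#'
#' Two-way repeated-measures ANOVA with Taste and Time as factors on the
#' first 2 s of evoked firing broken into four 500 ms bins (trials nested
#' within taste, time a within-trial factor). A unit is taste-specific if
#' the taste main effect or the taste-by-time interaction is significant.
#'
#' @inheritParams taste_responsivity
#' @return A tibble per unit: `p_taste`, `p_interaction`, `specific`.
#' @export
taste_specificity <- function(dataset, condition = "both", alpha = 0.05) {
  trials <- condition_trials(dataset, condition)
  tt <- dataset$trial_table[trials, ]
  if (any(table(factor(tt$taste, TASTES)) < 2))
    stop("need at least 2 trials of every taste", call. = FALSE)
  purrr::map_dfr(seq_len(dim(dataset$rasters)[2]), function(u) {
    long <- purrr::map_dfr(1:4, function(b) {
      from <- (b - 1L) * 500L
      tibble(trial = trials,
             taste = tt$taste,
             time_bin = b,
             rate = unit_window_counts(dataset, u, from, from + 500L,
                                       trials) / 0.5)
    })
    long$taste <- factor(long$taste, TASTES)
    long$time_bin <- factor(long$time_bin)
    long$trial <- factor(long$trial)
    fit <- aov(rate ~ taste * time_bin + Error(trial), data = long)
    sm <- summary(fit)
    between <- sm[["Error: trial"]][[1]]
    within <- sm[["Error: Within"]][[1]]
    p_taste <- between["taste", "Pr(>F)"]
    p_int <- within["taste:time_bin", "Pr(>F)"]
    tibble(unit = u, p_taste = p_taste, p_interaction = p_int,
           specific = p_taste < alpha | p_int < alpha)
  })
}

#' Classify units as putative interneurons or pyramidal cells
#'
#' Spike half-width (valley to post-valley peak) below 0.35 ms marks a
#' putative interneuron (IN); otherwise the unit is a putative pyramidal
#' cell (PC). The boundary value 0.35 ms is assigned to PC.
#'
#' @param half_width_ms Positive spike half-width(s) in ms.
#' @return Character vector, `"IN"` or `"PC"`.
#' @export
#' @examples
#' classify_unit_type(c(0.30, 0.50))
classify_unit_type <- function(half_width_ms) {
  if (any(half_width_ms <= 0))
    stop("half-width must be positive", call. = FALSE)
  ifelse(half_width_ms < 0.35, "IN", "PC")
}

#' Moving-window palatability correlation for one unit
#'
#' Extracts 250 ms segments of the evoked response stepped 25 ms apart
#' over `[0, 2500)` ms and correlates single-trial firing rates with the
#' palatability ranks of the delivered tastes (Spearman's rho,
#' average-rank ties). The unit is flagged palatability-related if the
#' correlation is significant (p < alpha) in 3 or more consecutive
#' windows; windows with zero rate variance have undefined rho and are
#' recorded as missing (never significant).
#'
#' @param dataset An [ensemble_dataset()].
#' @param unit Unit index.
#' @param condition `"off"`, `"on"` or `"both"`.
#' @param window_ms,step_ms Moving-window geometry.
#' @param span `c(from, to)` ms interval analysed.
#' @param alpha Per-window significance level.
#' @param min_run Consecutive significant windows required for the flag.
#' @return A `palatability_trace` tibble: `time_ms` (window centre),
#'   `rho`, `p_value`, `significant`, `in_run`; attribute `flagged` gives
#'   the unit-level decision.
#' @export
palatability_correlation <- function(dataset, unit, condition = "both",
                                     window_ms = 250, step_ms = 25,
                                     span = c(0, 2500), alpha = 0.05,
                                     min_run = 3) {
  trials <- condition_trials(dataset, condition)
  tt <- dataset$trial_table[trials, ]
  if (length(unique(tt$taste)) < 4)
    stop("all four tastes are required", call. = FALSE)
  rk <- palatability_map()
  ranks <- rk$rank[match(tt$taste, rk$taste)]
  starts <- seq(span[1], span[2] - window_ms, by = step_ms)
  res <- purrr::map_dfr(starts, function(s) {
    rate <- unit_window_counts(dataset, unit, s, s + window_ms, trials) /
      (window_ms / 1000)
    spearman_window(rate, ranks, s + window_ms / 2)
  })
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res$in_run <- flag_runs(res$significant, min_run)
  attr(res, "flagged") <- any(res$in_run)
  attr(res, "unit") <- unit
  class(res) <- c("palatability_trace", class(res))
  res
}

spearman_window <- function(rate, ranks, center) {
  if (var(rate) == 0 || var(ranks) == 0)
    return(tibble(time_ms = center, rho = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(cor.test(rate, ranks, method = "spearman",
                                  exact = FALSE))
  tibble(time_ms = center, rho = unname(ct$estimate),
         p_value = ct$p.value)
}

# TRUE for positions belonging to a run of >= min_run consecutive TRUEs.
flag_runs <- function(x, min_run) {
  r <- rle(x)
  keep <- r$values & r$lengths >= min_run
  inverse.rle(list(values = keep, lengths = r$lengths))
}

#' Palatability flags for every unit
#'
#' Applies [palatability_correlation()] to each unit and returns the
#' per-unit flag and peak |rho|.
#'
#' @inheritParams palatability_correlation
#' @return A tibble per unit: `unit`, `flagged`, `peak_abs_rho`.
#' @export
palatability_units <- function(dataset, condition = "both", ...) {
  purrr::map_dfr(seq_len(dim(dataset$rasters)[2]), function(u) {
    tr <- palatability_correlation(dataset, u, condition, ...)
    tibble(unit = u, flagged = attr(tr, "flagged"),
           peak_abs_rho = suppressWarnings(max(abs(tr$rho), na.rm = TRUE)))
  })
}

#' Laser-impact onset latency for one unit
#'
#' Scans 100 ms bins over `[0, 2500)` and returns the start (ms) of the
#' first bin at which laser-Off and laser-On firing differ (Welch
#' two-sample t-test, p < alpha) for at least `min_run` consecutive bins;
#' `NA` if no such run exists. Intended for units already deemed impacted
#' by [laser_impact_glm()].
#'
#' @param dataset An [ensemble_dataset()].
#' @param unit Unit index.
#' @param bin_ms Scan bin width (ms).
#' @param alpha Per-bin significance level.
#' @param min_run Consecutive significant bins required.
#' @return Latency in ms, or `NA_real_`.
#' @export
impact_latency <- function(dataset, unit, bin_ms = 100, alpha = 0.05,
                           min_run = 2) {
  off <- which(!dataset$trial_table$laser_on)
  on <- which(dataset$trial_table$laser_on)
  starts <- seq(0, 2500 - bin_ms, by = bin_ms)
  sig <- vapply(starts, function(s) {
    a <- unit_window_counts(dataset, unit, s, s + bin_ms, off)
    b <- unit_window_counts(dataset, unit, s, s + bin_ms, on)
    if (var(a) == 0 && var(b) == 0) return(FALSE)
    t.test(a, b)$p.value < alpha
  }, logical(1))
  run <- flag_runs(sig, min_run)
  if (!any(run)) return(NA_real_)
  starts[which(run)[1]]
}

#' Per-bin laser impact direction profile for one unit
#'
#' Mean On - Off firing-rate difference in ten 250 ms bins over the
#' 2.5 s post-delivery period, with a per-bin Welch t-test. The
#' `consistent` attribute is TRUE when all significant bins share one
#' sign (the impact is unimodal for the unit).
#'
#' @param dataset An [ensemble_dataset()].
#' @param unit Unit index.
#' @param alpha Per-bin significance level.
#' @return A tibble of 10 rows: `time_ms` (bin centre), `diff_hz`
#'   (On - Off), `t`, `p_value`, `significant`; attribute `consistent`.
#' @export
direction_profile <- function(dataset, unit, alpha = 0.05) {
  off <- which(!dataset$trial_table$laser_on)
  on <- which(dataset$trial_table$laser_on)
  starts <- seq(0, 2250, by = 250)
  res <- purrr::map_dfr(starts, function(s) {
    a <- unit_window_counts(dataset, unit, s, s + 250, off) / 0.25
    b <- unit_window_counts(dataset, unit, s, s + 250, on) / 0.25
    if (var(a) == 0 && var(b) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else tt <- t.test(b, a)
    tibble(time_ms = s + 125, diff_hz = mean(b) - mean(a),
           t = unname(tt$statistic), p_value = tt$p.value)
  })
  res$significant <- res$p_value < alpha
  sig_signs <- sign(res$diff_hz[res$significant])
  attr(res, "consistent") <- length(unique(sig_signs)) <= 1
  res
}
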