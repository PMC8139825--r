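test_that("strong evoked responses are detected as taste-responsive", {
  step_fn <- function(u, taste, on, t) ifelse(t >= 0, 12, 2)
  ds <- rate_fn_dataset(step_fn, n_trials_per_taste = 15, seed = 31)
  r <- taste_responsivity(ds)
  expect_true(r$responsive[1])
  expect_gt(r$statistic[1], 0)
})

test_that("a push-pull unit can be taste-specific without responsivity", {
  # two tastes +5 Hz, two tastes -5 Hz: net evoked equals baseline
  fn <- function(u, taste, on, t) {
    delta <- ifelse(taste %in% c("Sucrose", "NaCl"), 5, -5)
    ifelse(t >= 0, 7 + delta, 7)
  }
  ds <- rate_fn_dataset(fn, n_trials_per_taste = 30, seed = 32)
  expect_false(taste_responsivity(ds)$responsive[1])
  expect_true(taste_specificity(ds)$specific[1])
})

test_that("taste specificity detects rate and time-course differences", {
  # one taste elevated
  fn <- function(u, taste, on, t)
    ifelse(t >= 0, ifelse(taste == "Acid", 15, 5), 5)
  ds <- rate_fn_dataset(fn, n_trials_per_taste = 30, seed = 33)
  res <- taste_specificity(ds)
  expect_true(res$specific[1])
  expect_lt(res$p_taste[1], 0.001)

  # same 2-s mean, crossing time-courses -> interaction only
  fn2 <- function(u, taste, on, t) {
    up <- taste %in% c("Sucrose", "NaCl")
    ifelse(t < 0, 8, ifelse(t < 1000, ifelse(up, 14, 2),
                            ifelse(up, 2, 14)))
  }
  ds2 <- rate_fn_dataset(fn2, n_trials_per_taste = 30, seed = 34)
  res2 <- taste_specificity(ds2)
  expect_lt(res2$p_interaction[1], 0.05)
  expect_true(res2$specific[1])

  expect_error(
    taste_specificity(const_rate_dataset(n_trials_per_taste = 1)),
    "at least 2 trials")
})

test_that("spike half-width classifies IN vs PC with boundary at PC", {
  expect_equal(classify_unit_type(c(0.30, 0.50, 0.35)),
               c("IN", "PC", "PC"))
  expect_error(classify_unit_type(0), "positive")
})

test_that("palatability correlation flags rank-ordered firing", {
  cf <- generator_config(n_units = 2, n_trials_per_taste = 30,
                         laser_fraction = 0, baseline_rate_hz = 8,
                         palatability_gain_hz = c(4, -4),
                         transition_mean_ms = 700)
  g <- generate_ensemble(cf, seed = 35)
  tr1 <- palatability_correlation(g$dataset, 1, condition = "off")
  expect_true(attr(tr1, "flagged"))
  late <- tr1$rho[tr1$time_ms > 1400]
  expect_gt(mean(late, na.rm = TRUE), 0.5)

  # anti-ordered firing is flagged too (sign-agnostic), rho -> -1
  tr2 <- palatability_correlation(g$dataset, 2, condition = "off")
  expect_true(attr(tr2, "flagged"))
  expect_lt(mean(tr2$rho[tr2$time_ms > 1400], na.rm = TRUE), -0.5)

  # zero-variance windows give missing rho and are never significant
  zero <- const_rate_dataset(n_trials_per_taste = 4, rate_hz = 0,
                             seed = 36)
  trz <- palatability_correlation(zero, 1)
  expect_true(all(is.na(trz$rho)))
  expect_false(attr(trz, "flagged"))
})

test_that("Spearman trace equals brute-force rank correlation", {
  g <- generate_ensemble(generator_config(n_units = 1,
                                          n_trials_per_taste = 8),
                         seed = 37)
  tr <- palatability_correlation(g$dataset, 1, condition = "both")
  ranks <- c(Sucrose = 4, NaCl = 3, Acid = 2, QHCl = 1)
  rk_tr <- ranks[g$dataset$trial_table$taste]
  set.seed(38)
  for (w in sample(nrow(tr), 5)) {
    s <- tr$time_ms[w] - 125
    cols <- (s - g$dataset$t0_ms + 1):(s + 250 - g$dataset$t0_ms)
    rate <- rowSums(g$dataset$rasters[, 1, cols])
    rho_bf <- suppressWarnings(
      cor(rank(rate), rank(rk_tr), method = "pearson"))
    if (is.na(tr$rho[w])) {
      expect_true(sd(rate) == 0)
    } else {
      expect_equal(tr$rho[w], rho_bf, tolerance = 1e-12)
    }
  }
})

test_that("impact latency recovers the true laser onset", {
  mk <- function(onset, f, seed) {
    cf <- generator_config(n_units = 1, n_trials_per_taste = 15,
                           baseline_rate_hz = 10,
                           detection_rate_hz = 10,
                           identity_rates_hz = matrix(10, 1, 4),
                           palatability_gain_hz = 0,
                           laser_effect = f, laser_onset_ms = onset)
    generate_ensemble(cf, seed = seed)$dataset
  }
  expect_true(abs(impact_latency(mk(750, 0.2, 41), 1) - 750) <= 100)
  expect_true(is.na(impact_latency(mk(750, 1, 42), 1)))
  expect_lte(impact_latency(mk(0, 0.2, 43), 1), 100)
})

test_that("direction profiles are unimodal for pure suppression", {
  cf <- generator_config(n_units = 1, n_trials_per_taste = 15,
                         baseline_rate_hz = 10, detection_rate_hz = 10,
                         identity_rates_hz = matrix(10, 1, 4),
                         palatability_gain_hz = 0,
                         laser_effect = 0.4, laser_onset_ms = 0)
  g <- generate_ensemble(cf, seed = 44)
  dp <- direction_profile(g$dataset, 1)
  expect_equal(nrow(dp), 10L)
  expect_true(all(dp$diff_hz < 0))
  expect_true(attr(dp, "consistent"))

  # null unit: no consistent significant effect
  nullds <- const_rate_dataset(n_trials_per_taste = 15, n_units = 1,
                               rate_hz = 10, seed = 45)
  dp0 <- direction_profile(nullds, 1)
  expect_lt(sum(dp0$significant), 3)

  # late-onset suppression: early bins null, late bins negative
  cf2 <- generator_config(n_units = 1, n_trials_per_taste = 30,
                          baseline_rate_hz = 12, detection_rate_hz = 12,
                          identity_rates_hz = matrix(12, 1, 4),
                          palatability_gain_hz = 0,
                          laser_effect = 0.3, laser_onset_ms = 750)
  g2 <- generate_ensemble(cf2, seed = 46)
  dp2 <- direction_profile(g2$dataset, 1)
  expect_false(any(dp2$significant[1:3]))
  expect_true(all(dp2$diff_hz[4:10] < 0))
})
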