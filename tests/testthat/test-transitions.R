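# Deterministic "realigned" fixture whose rasters hold per-ms expected
# rates (so PSTHs are exact): oracle for the slope estimator.
mk_fake_realigned <- function(psth_fn, n_units = 1, span = c(-500, 500)) {
  t <- seq.int(span[1], span[2] - 1L)
  ras <- array(0, dim = c(4, n_units, length(t)))
  for (u in seq_len(n_units))
    for (i in 1:4) ras[i, u, ] <- psth_fn(u, t) / 1000
  structure(list(
    rasters = ras, time_ms = t,
    trial_table = tibble::tibble(
      trial = 1:4, taste = c("Sucrose", "NaCl", "Acid", "QHCl"),
      laser_on = FALSE, onset_ms = 700, padded = FALSE),
    span = span), class = "realigned_ensemble")
}

test_that("slope estimator matches analytic values for ramps and steps", {
  # linear PSTH with slope 0.05 Hz/ms: every window recovers it exactly
  lin <- mk_fake_realigned(function(u, t) 50 + 0.05 * t)
  rec <- peri_transition_slopes(lin, per_taste = FALSE)
  expect_equal(rec$max_slope_hz_ms, 0.05, tolerance = 1e-10)

  # step of 10 Hz at t = 0: max slope sits within one step of zero
  stp <- mk_fake_realigned(function(u, t) ifelse(t < 0, 5, 15))
  rec2 <- peri_transition_slopes(stp, per_taste = FALSE)
  expect_lte(abs(rec2$latency_ms), 20)
  # LS slope of a centred step over a 100 ms window is ~1.5 h / w
  expect_equal(rec2$max_slope_hz_ms, 1.5 * 10 / 100, tolerance = 0.05)
})

test_that("sigmoid fits recover exact logistic parameters", {
  t <- seq(-875, 575, by = 25)
  truth <- c(lower = 0.1, upper = 0.6, slope = 0.02, t0 = 50)
  y <- truth["lower"] + (truth["upper"] - truth["lower"]) /
    (1 + exp(-truth["slope"] * (t - truth["t0"])))
  f <- fit_sigmoid(tibble::tibble(time_ms = t, value = y), seed = 91)
  est <- f$estimates
  for (p in names(truth)) {
    row <- est[est$parameter == p, ]
    expect_lt(abs(row$mean - truth[[p]]) / abs(truth[[p]]), 0.01)
    expect_true(row$lower <= truth[[p]] && truth[[p]] <= row$upper)
  }
})

test_that("a linear ramp fits with a shallower slope than a step", {
  t <- seq(-875, 575, by = 25)
  y_step <- ifelse(t < 0, 0.1, 0.6)
  y_ramp <- pmin(pmax(0.1 + (t + 400) / 800 * 0.5, 0.1), 0.6)
  fs <- fit_sigmoid(tibble::tibble(time_ms = t, value = y_step),
                    seed = 92)
  fr <- fit_sigmoid(tibble::tibble(time_ms = t, value = y_ramp),
                    seed = 93)
  expect_gt(glance(fs)$slope, glance(fr)$slope)
  expect_true(slopes_differ(fs, fr))
})

test_that("sigmoid credible intervals calibrate under noise", {
  t <- seq(-875, 575, by = 25)
  truth <- c(lower = 0.05, upper = 0.55, slope = 0.015, t0 = 0)
  mu <- truth["lower"] + (truth["upper"] - truth["lower"]) /
    (1 + exp(-truth["slope"] * (t - truth["t0"])))
  covered <- matrix(FALSE, 20, 4,
                    dimnames = list(NULL, names(truth)))
  for (k in 1:20) {
    set.seed(900 + k)
    y <- mu + rnorm(length(t), 0, 0.05)
    f <- fit_sigmoid(tibble::tibble(time_ms = t, value = y),
                     n_iter = 1500, seed = k)
    for (p in names(truth)) {
      row <- f$estimates[f$estimates$parameter == p, ]
      covered[k, p] <- row$lower <= truth[[p]] &&
        truth[[p]] <= row$upper
    }
  }
  expect_gte(mean(covered), 0.9)
})

test_that("slope comparison identifies identity and scaled conditions", {
  set.seed(95)
  off <- tibble::tibble(unit = 1:40,
                        max_slope_hz_ms = runif(40, 0.02, 0.5),
                        latency_ms = sample(seq(-160, 160, 20), 40,
                                            replace = TRUE))
  same <- compare_slope_conditions(off, off)
  expect_equal(same$regression$slope, 1, tolerance = 1e-9)
  expect_equal(same$latency_t$statistic, 0)
  expect_gt(same$regression$p_vs_1, 0.99)

  on <- off
  on$max_slope_hz_ms <- 0.4 * off$max_slope_hz_ms +
    rnorm(40, 0, 0.01)
  sc <- compare_slope_conditions(off, on)
  expect_lt(abs(sc$regression$slope - 0.4), 0.1)
  expect_lt(sc$regression$p_vs_1, 0.001)
  expect_false(sc$groups_skipped)

  expect_true(compare_slope_conditions(off[1:3, ], off[1:3, ])
              $groups_skipped)
})

test_that("aligned palatability traces rise at the transition", {
  cf <- generator_config(n_units = 6, n_trials_per_taste = 30,
                         laser_fraction = 0)
  g <- generate_ensemble(cf, seed = 96)
  al <- tibble::tibble(trial = g$truth$trials$trial, state = 1L,
                       onset_ms = round(g$truth$trials$transition_ms),
                       valid = TRUE)
  re <- realign(g$dataset, al, span = c(-700, 700))
  tr <- aligned_palatability_trace(re)
  agg <- attr(tr, "aggregate")
  pre <- agg$mean_abs_rho[agg$time_ms < -300]
  post <- agg$mean_abs_rho[agg$time_ms > 300]
  expect_gt(mean(post, na.rm = TRUE), mean(pre, na.rm = TRUE) + 0.15)

  # shuffled taste labels flatten the trace
  re_null <- re
  set.seed(97)
  re_null$trial_table$taste <- sample(re_null$trial_table$taste)
  agg0 <- attr(aligned_palatability_trace(re_null), "aggregate")
  expect_lt(mean(agg0$mean_abs_rho[agg0$time_ms > 300], na.rm = TRUE),
            mean(post, na.rm = TRUE) - 0.1)
})
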