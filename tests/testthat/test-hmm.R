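# Build a simple 2-state switching ensemble directly: all units at
# `r1` Hz until a per-trial Gaussian switch, then `r2` Hz.
mk_switch_dataset <- function(n_trials = 30, n_units = 4, r1 = 2,
                              r2 = 12, mean_ms = 700, sd_ms = 100,
                              seed = 1, n_time = 4500) {
  set.seed(seed)
  sw <- pmin(pmax(rnorm(n_trials, mean_ms, sd_ms), 300), 2300)
  ras <- array(0L, dim = c(n_trials, n_units, n_time))
  t_ms <- seq.int(-2000L, -2000L + n_time - 1L)
  for (i in seq_len(n_trials)) {
    r <- ifelse(t_ms < 0, r1, ifelse(t_ms < sw[i], r1, r2))
    for (u in seq_len(n_units))
      ras[i, u, ] <- as.integer(runif(n_time) < r / 1000)
  }
  tastes <- rep(c("Sucrose", "NaCl", "Acid", "QHCl"),
                length.out = n_trials)
  ds <- ensemble_dataset(
    ras,
    tibble::tibble(trial = seq_len(n_trials), taste = tastes,
                   laser_on = rep(FALSE, n_trials)),
    tibble::tibble(unit = seq_len(n_units), half_width_ms = 0.4,
                   session_id = "s"))
  list(dataset = ds, switch_ms = sw)
}

test_that("EM recovers 2-state rates and the winner dominates restarts", {
  d <- mk_switch_dataset(seed = 71)
  m <- fit_hmm(d$dataset, laser = "off", n_states = 2, restarts = 5,
               seed = 71, max_iter = 100)
  expect_true(all(diff(m$loglik_trace) >= -1e-6))
  expect_gte(m$loglik, max(m$restart_logliks) - 1e-9)
  expect_equal(rowSums(m$trans), c(1, 1), tolerance = 1e-8)
  # sorted state rates (Hz) near 2 and 12 for every unit
  for (u in 1:4) {
    r <- sort(m$rates_hz[u, ])
    expect_lt(abs(r[1] - 2) / 2, 0.2)
    expect_lt(abs(r[2] - 12) / 12, 0.2)
  }
})

test_that("posteriors are normalized and concentrate on the true state", {
  d <- mk_switch_dataset(seed = 72)
  m <- fit_hmm(d$dataset, laser = "off", n_states = 2, restarts = 3,
               seed = 72, max_iter = 100)
  post <- decode_trials(m, d$dataset)
  expect_lt(max(abs(rowSums(post[[1]]) - 1)), 1e-10)
  # a constant-rate trial generated purely from one state's rates
  hi_state <- which.max(m$rates_hz[1, ])
  set.seed(73)
  counts <- matrix(rpois(4 * 250, m$rates[, hi_state]), 4, 250)
  g <- decode_hmm(m, counts)
  expect_gt(mean(g[, hi_state] > 0.9), 0.8)
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(74)
  for (S in 2:3) {
    rates <- matrix(runif(3 * S, 0.1, 4), 3, S)
    A <- matrix(runif(S * S), S, S)
    A <- A / rowSums(A)
    pi0 <- rep(1 / S, S)
    counts <- matrix(rpois(3 * 6, 1.5), 3, 6)
    model <- structure(list(rates = rates, trans = A, init = pi0),
                       class = "hmm_model")
    g <- decode_hmm(model, counts)
    g_oracle <- enumerate_posterior(counts, rates, A, pi0)
    expect_lt(max(abs(g - g_oracle)), 1e-10)
  }
})

test_that("state identification picks the dominant state per window", {
  d <- mk_switch_dataset(seed = 75)
  m <- fit_hmm(d$dataset, laser = "off", n_states = 2, restarts = 3,
               seed = 75, max_iter = 100)
  post <- decode_trials(m, d$dataset)
  late <- identify_state(m, post, window = c(1500, 2500))
  early <- identify_state(m, post, window = c(0, 200))
  expect_equal(unname(which.max(m$rates_hz[1, ])), late)
  expect_equal(unname(which.min(m$rates_hz[1, ])), early)
  expect_false(late == early)
})

test_that("transition onsets follow the 0.5-threshold convention", {
  post <- matrix(0, 250, 2)
  post[, 1] <- 1
  post[71:250, ] <- rep(c(0, 1), each = 180)
  expect_equal(transition_onset(post, 2, bin_ms = 10), 700)
  never <- cbind(rep(1, 250), rep(0, 250))
  expect_true(is.na(transition_onset(never, 2)))
})

test_that("recovered onsets track the true switch times", {
  errs <- c()
  est <- truth <- c()
  for (k in 1:6) {
    d <- mk_switch_dataset(n_trials = 20, seed = 80 + k)
    m <- fit_hmm(d$dataset, laser = "off", n_states = 2, restarts = 5,
                 seed = k, max_iter = 80)
    post <- decode_trials(m, d$dataset)
    st <- identify_state(m, post, window = c(1500, 2500))
    al <- align_trials(m, d$dataset, st)
    errs <- c(errs, abs(al$onset_ms - d$switch_ms)[al$valid])
    est <- c(est, al$onset_ms[al$valid])
    truth <- c(truth, d$switch_ms[al$valid])
  }
  expect_gt(cor(est, truth), 0.8)
  expect_lt(median(errs), 50)
})

test_that("realignment re-zeroes trials and recovers state rates", {
  d <- mk_switch_dataset(n_trials = 20, seed = 77)
  # constant alignment equals a plain shift
  al <- tibble::tibble(trial = 1:20, state = 2L, onset_ms = 700,
                       valid = TRUE)
  class(al) <- c("trial_alignment", class(al))
  re <- realign(d$dataset, al, span = c(-500, 500))
  expect_identical(
    re$rasters[1, 1, ],
    d$dataset$rasters[1, 1, (700 - 500 + 2000 + 1):(700 + 500 + 2000)])

  # ground-truth alignment: post-zero rate matches the high state
  al2 <- tibble::tibble(trial = 1:20, state = 2L,
                        onset_ms = round(d$switch_ms),
                        valid = rep(c(TRUE, FALSE), c(18, 2)))
  re2 <- realign(d$dataset, al2, span = c(-500, 500))
  expect_equal(dim(re2$rasters)[1], 18L)
  post_rate <- mean(re2$rasters[, , 501:1000], na.rm = TRUE) * 1000
  pre_rate <- mean(re2$rasters[, , 1:500], na.rm = TRUE) * 1000
  expect_lt(abs(post_rate - 12) / 12, 0.1)
  expect_lt(abs(pre_rate - 2) / 2, 0.25)

  al3 <- al2
  al3$valid <- FALSE
  expect_error(realign(d$dataset, al3), "no valid trials")
})
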