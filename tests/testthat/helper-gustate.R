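# Shared fixture builders. Everything is generated in code at test time.

# Dataset where every unit fires at a constant Bernoulli rate regardless
# of taste, condition or time: the null for calibration checks.
const_rate_dataset <- function(n_trials_per_taste = 4, n_units = 2,
                               rate_hz = 8, seed = 1, n_time = 4500,
                               t0_ms = -2000) {
  set.seed(seed)
  n_tr <- 4L * n_trials_per_taste
  ras <- array(as.integer(runif(n_tr * n_units * n_time) <
                            rate_hz / 1000),
               dim = c(n_tr, n_units, n_time))
  trial_table <- tibble::tibble(
    trial = seq_len(n_tr),
    taste = rep(c("Sucrose", "NaCl", "Acid", "QHCl"),
                each = n_trials_per_taste),
    laser_on = rep_len(c(TRUE, FALSE), n_tr))
  unit_table <- tibble::tibble(unit = seq_len(n_units),
                               half_width_ms = 0.4,
                               session_id = "test")
  ensemble_dataset(ras, trial_table, unit_table, t0_ms = t0_ms)
}

# Dataset with per-(taste, condition, time-segment) rates given by a
# function rate_fn(unit, taste, laser_on, t_ms) -> Hz, for targeted
# single-unit scenarios.
rate_fn_dataset <- function(rate_fn, n_trials_per_taste = 15,
                            n_units = 1, seed = 1, laser = TRUE) {
  set.seed(seed)
  n_tr <- 4L * n_trials_per_taste
  n_time <- 4500L
  t_ms <- seq.int(-2000L, 2499L)
  tastes <- rep(c("Sucrose", "NaCl", "Acid", "QHCl"),
                each = n_trials_per_taste)
  laser_on <- if (laser) rep_len(c(TRUE, FALSE), n_tr)
              else rep(FALSE, n_tr)
  ras <- array(0L, dim = c(n_tr, n_units, n_time))
  for (i in seq_len(n_tr)) {
    for (u in seq_len(n_units)) {
      r <- rate_fn(u, tastes[i], laser_on[i], t_ms)
      ras[i, u, ] <- as.integer(runif(n_time) < r / 1000)
    }
  }
  ensemble_dataset(
    ras,
    tibble::tibble(trial = seq_len(n_tr), taste = tastes,
                   laser_on = laser_on),
    tibble::tibble(unit = seq_len(n_units), half_width_ms = 0.4,
                   session_id = "test"))
}

# Null generator config: identical rate profiles for all four tastes.
null_config <- function(n_units = 10, n_trials_per_taste = 30,
                        laser_fraction = 0) {
  base <- seq(2, 8, length.out = n_units)
  generator_config(
    n_units = n_units, n_trials_per_taste = n_trials_per_taste,
    laser_fraction = laser_fraction,
    identity_rates_hz = matrix(base + 3, n_units, 4),
    palatability_gain_hz = 0,
    laser_effect = 1)
}

# Independent brute-force jack-knife classifier: explicit loops, per-bin
# distances accumulated in unit space. Mirrors the variance-matched
# template definition: every taste's template drops the trial whose
# within-taste index matches the held-out trial's.
brute_force_classify <- function(dataset, condition, window, bin_ms) {
  tastes <- c("Sucrose", "NaCl", "Acid", "QHCl")
  trials <- which(if (condition == "off") !dataset$trial_table$laser_on
                  else dataset$trial_table$laser_on)
  labs <- dataset$trial_table$taste[trials]
  by_taste <- lapply(tastes, function(t) trials[labs == t])
  starts <- seq(window[1], window[2] - bin_ms, by = bin_ms)
  n_units <- dim(dataset$rasters)[2]
  count1 <- function(tr, u, s) {
    cols <- (s - dataset$t0_ms + 1):(s + bin_ms - dataset$t0_ms)
    sum(dataset$rasters[tr, u, cols])
  }
  pred <- character(length(trials))
  for (k in seq_along(trials)) {
    i <- trials[k]
    own <- match(labs[k], tastes)
    own_idx <- match(i, by_taste[[own]])
    d2 <- numeric(4)
    for (t in seq_along(tastes)) {
      grp <- by_taste[[t]]
      drop_tr <- if (t == own) i
                 else grp[(own_idx - 1) %% length(grp) + 1]
      others <- setdiff(grp, drop_tr)
      for (s in starts) {
        for (u in seq_len(n_units)) {
          templ <- mean(vapply(others, count1, numeric(1), u = u, s = s))
          d2[t] <- d2[t] + (count1(i, u, s) - templ)^2
        }
      }
    }
    pred[k] <- tastes[which.min(d2)]
  }
  tibble::tibble(trial = trials, predicted = pred)
}

# Exhaustive-path posterior oracle for a Poisson HMM on a toy instance.
enumerate_posterior <- function(counts, rates, A, pi0) {
  S <- ncol(rates); B <- ncol(counts)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), B)))
  logp <- apply(paths, 1, function(z) {
    lp <- log(pi0[z[1]])
    for (b in 2:B) lp <- lp + log(A[z[b - 1], z[b]])
    for (b in 1:B)
      lp <- lp + sum(dpois(counts[, b], rates[, z[b]], log = TRUE))
    lp
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  post <- matrix(0, B, S)
  for (b in 1:B) for (s in 1:S)
    post[b, s] <- sum(w[paths[, b] == s])
  post
}
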