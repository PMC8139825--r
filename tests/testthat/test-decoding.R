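mk_separable <- function(n_per = 4) {
  # each taste drives a different unit deterministically (spike every 2nd
  # ms in the evoked window): perfectly separable, noise-free
  tastes <- c("Sucrose", "NaCl", "Acid", "QHCl")
  n_tr <- 4L * n_per
  ras <- array(0L, dim = c(n_tr, 4, 4500))
  lab <- rep(tastes, each = n_per)
  for (i in seq_len(n_tr)) {
    u <- match(lab[i], tastes)
    ras[i, u, seq(2001, 4500, by = 2)] <- 1L
  }
  ensemble_dataset(
    ras,
    tibble::tibble(trial = seq_len(n_tr), taste = lab,
                   laser_on = rep(FALSE, n_tr)),
    tibble::tibble(unit = 1:4, half_width_ms = 0.4, session_id = "s"))
}

test_that("noise-free separable ensembles decode perfectly", {
  ds <- mk_separable()
  res <- jackknife_classify(ds, "off")
  expect_equal(res$overall_accuracy, 1)
  expect_true(all(res$per_taste_accuracy$accuracy == 1))
  res2 <- classify_identity_epoch(ds, "off")
  expect_equal(res2$overall_accuracy, 1)
})

test_that("classifier equals a brute-force oracle on a small instance", {
  g <- generate_ensemble(generator_config(n_units = 3,
                                          n_trials_per_taste = 4,
                                          laser_fraction = 0),
                         seed = 61)
  res <- jackknife_classify(g$dataset, "off")
  bf <- brute_force_classify(g$dataset, "off", c(250, 1750), 250)
  expect_equal(res$predictions$predicted, bf$predicted)
  expect_equal(res$predictions$trial, bf$trial)
})

test_that("predictions are invariant to unit reordering", {
  g <- generate_ensemble(generator_config(n_units = 5,
                                          n_trials_per_taste = 6,
                                          laser_fraction = 0),
                         seed = 62)
  ds <- g$dataset
  perm <- c(4, 1, 5, 2, 3)
  ds2 <- ensemble_dataset(ds$rasters[, perm, , drop = FALSE],
                          ds$trial_table, ds$unit_table[perm, ],
                          t0_ms = ds$t0_ms)
  expect_equal(jackknife_classify(ds, "off")$predictions$predicted,
               jackknife_classify(ds2, "off")$predictions$predicted)
})

test_that("label-shuffled data decodes at chance on average", {
  g <- generate_ensemble(generator_config(n_units = 6,
                                          n_trials_per_taste = 30,
                                          laser_fraction = 0),
                         seed = 63)
  ds <- g$dataset
  accs <- numeric(100)
  set.seed(64)
  for (k in 1:100) {
    ds$trial_table$taste <- sample(ds$trial_table$taste)
    accs[k] <- jackknife_classify(ds, "off")$overall_accuracy
  }
  expect_gt(mean(accs), 0.20)
  expect_lt(mean(accs), 0.30)
})

test_that("cross-condition accuracy tracks the laser perturbation", {
  # no perturbation: cross approximately equals within
  cf0 <- generator_config(n_units = 10, laser_effect = 1)
  d0 <- generate_ensemble(cf0, seed = 65)$dataset
  within <- jackknife_classify(d0, "off")$overall_accuracy
  cross <- cross_condition_classify(d0, "off", "on")$overall_accuracy
  expect_lt(abs(within - cross), 0.15)

  # strong rescaling on half the units: cross drops by > 5 points
  cf1 <- generator_config(n_units = 10,
                          laser_effect = rep(c(0.3, 1), 5),
                          laser_onset_ms = 0)
  d1 <- generate_ensemble(cf1, seed = 66)$dataset
  w1 <- jackknife_classify(d1, "off")$overall_accuracy
  x1 <- cross_condition_classify(d1, "off", "on")$overall_accuracy
  expect_gt(w1 - x1, 0.05)

  # restricting to the perturbed units drops accuracy further
  x_imp <- cross_condition_classify(d1, "off", "on",
                                    units = which(rep(c(0.3, 1), 5) !=
                                                    1))$overall_accuracy
  expect_lt(x_imp, x1 + 0.02)
})

test_that("identity-epoch accuracy is close to whole-window accuracy", {
  gaps <- vapply(67:69, function(s) {
    d <- generate_ensemble(generator_config(), seed = s)$dataset
    jackknife_classify(d, "off")$overall_accuracy -
      classify_identity_epoch(d, "off")$overall_accuracy
  }, numeric(1))
  expect_lt(mean(abs(gaps)), 0.10)
})
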