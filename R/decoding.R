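# Jack-knife Euclidean template classification of taste identity from
# ensemble responses. Single trials are binned (250 ms bins, 250-1750 ms
# by default), each taste's template is the mean binned response of all
# other trials of that taste, and the held-out trial is assigned to the
# taste whose template lies at minimal Euclidean distance in the
# concatenated unit x bin space (equivalent to accumulating per-bin
# distances computed in unit space).

# trials x (units * bins) feature matrix of spike counts
trial_features <- function(dataset, trials, window, bin_ms) {
  starts <- seq(window[1], window[2] - bin_ms, by = bin_ms)
  n_units <- dim(dataset$rasters)[2]
  feats <- matrix(0, length(trials), n_units * length(starts))
  for (j in seq_along(starts)) {
    idx <- time_index(dataset, starts[j], starts[j] + bin_ms)
    cnt <- rowSums(dataset$rasters[trials, , idx, drop = FALSE], dims = 2)
    feats[, (j - 1) * n_units + seq_len(n_units)] <- cnt
  }
  feats
}

classifier_result <- function(pred, truth, tested, window, bin_ms,
                              train, test, ties) {
  pred <- factor(pred, TASTES)
  truth <- factor(truth, TASTES)
  cm <- table(truth = truth, predicted = pred)
  per_taste <- diag(cm) / rowSums(cm)
  structure(list(
    predictions = tibble(trial = tested, truth = as.character(truth),
                         predicted = as.character(pred)),
    confusion = cm,
    per_taste_accuracy = tibble(taste = TASTES,
                                accuracy = as.numeric(per_taste),
                                n_trials = as.numeric(rowSums(cm))),
    overall_accuracy = mean(pred == truth),
    n_tested = length(truth), n_ties = ties,
    train_condition = train, test_condition = test,
    window_ms = window, bin_ms = bin_ms),
    class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat("<classifier_result> train:", x$train_condition, "test:",
      x$test_condition, sprintf("overall %.1f%%", 100 * x$overall_accuracy),
      "over", x$n_tested, "trials\n")
  invisible(x)
}

#' Jack-knife taste classification within one laser condition
#'
#' Leave-one-trial-out nearest-template decoding: each trial of the chosen
#' condition is held out, taste templates are the mean binned responses of
#' the remaining trials, and the trial is assigned to the nearest template
#' by Euclidean distance. Accuracy above the 25% chance level indicates
#' taste-specific ensemble firing. Distance ties are broken by canonical
#' taste order and counted.
#'
#' With `equalize_templates = TRUE` (the default) every taste's template —
#' not only the held-out trial's own — is computed from one trial fewer
#' (the trial with the matching within-taste index is dropped). This keeps
#' the four template variances identical, which makes the four distances
#' exchangeable under the null and pins finite-sample chance at exactly
#' 25%; with the naive asymmetric templates the own-taste template has
#' higher variance and chance sits measurably below 25% at 30
#' trials/taste. Set to FALSE for the plain asymmetric variant.
#'
#' @param dataset An [ensemble_dataset()].
#' @param condition `"off"`, `"on"` or `"both"`.
#' @param window `c(from, to)` ms window (default 250-1750 ms).
#' @param bin_ms Bin width within the window (default 250 ms).
#' @param equalize_templates Use variance-matched templates (see above).
#' @return A `classifier_result`: confusion matrix, per-taste and overall
#'   accuracy, tie count, window settings.
#' @export
jackknife_classify <- function(dataset, condition = "off",
                               window = c(250, 1750), bin_ms = 250,
                               equalize_templates = TRUE) {
  trials <- condition_trials(dataset, condition)
  labs <- dataset$trial_table$taste[trials]
  if (any(table(factor(labs, TASTES)) < 2))
    stop("need at least 2 trials per taste in condition", call. = FALSE)
  feats <- trial_features(dataset, trials, window, bin_ms)
  sums <- rowsum(feats, labs)[TASTES, , drop = FALSE]
  ns <- as.numeric(table(factor(labs, TASTES)))
  # within-taste index of each trial, and row lookup by (taste, index)
  widx <- stats::ave(seq_along(trials), labs, FUN = seq_along)
  row_of <- matrix(NA_integer_, 4, max(ns))
  for (i in seq_along(trials))
    row_of[match(labs[i], TASTES), widx[i]] <- i
  pred <- character(length(trials))
  ties <- 0L
  for (i in seq_along(trials)) {
    templ <- sums
    nlo <- ns
    k <- match(labs[i], TASTES)
    for (c in 1:4) {
      drop_row <- if (c == k) i
                  else row_of[c, (widx[i] - 1L) %% ns[c] + 1L]
      if (c == k || equalize_templates) {
        templ[c, ] <- templ[c, ] - feats[drop_row, ]
        nlo[c] <- nlo[c] - 1L
      }
    }
    templ <- templ / nlo
    d2 <- rowSums((templ - matrix(feats[i, ], 4, ncol(feats),
                                  byrow = TRUE))^2)
    if (sum(d2 == min(d2)) > 1) ties <- ties + 1L
    pred[i] <- TASTES[which.min(d2)]
  }
  classifier_result(pred, labs, trials, window, bin_ms,
                    condition, condition, ties)
}

#' Cross-condition taste classification
#'
#' Builds taste templates from every trial of the training condition and
#' scores every trial of the (disjoint) test condition against them; no
#' jack-knifing is needed because train and test sets do not overlap.
#'
#' @inheritParams jackknife_classify
#' @param train,test Laser conditions (`"off"`/`"on"`) for templates and
#'   scored trials.
#' @param units Optional unit subset (e.g. only laser-impacted units).
#' @return A `classifier_result`.
#' @export
cross_condition_classify <- function(dataset, train = "off", test = "on",
                                     window = c(250, 1750), bin_ms = 250,
                                     units = NULL) {
  if (!is.null(units)) dataset <- subset_units(dataset, units)
  tr <- condition_trials(dataset, train)
  te <- condition_trials(dataset, test)
  if (!length(tr) || !length(te))
    stop("both conditions must be populated", call. = FALSE)
  labs_tr <- dataset$trial_table$taste[tr]
  labs_te <- dataset$trial_table$taste[te]
  f_tr <- trial_features(dataset, tr, window, bin_ms)
  f_te <- trial_features(dataset, te, window, bin_ms)
  templ <- rowsum(f_tr, labs_tr)[TASTES, , drop = FALSE] /
    as.numeric(table(factor(labs_tr, TASTES)))
  pred <- character(length(te))
  ties <- 0L
  for (i in seq_along(te)) {
    d2 <- rowSums((templ - matrix(f_te[i, ], 4, ncol(templ),
                                  byrow = TRUE))^2)
    if (sum(d2 == min(d2)) > 1) ties <- ties + 1L
    pred[i] <- TASTES[which.min(d2)]
  }
  classifier_result(pred, labs_te, te, window, bin_ms, train, test, ties)
}

#' Identity-epoch classification
#'
#' [jackknife_classify()] restricted to the identity epoch
#' (250-750 ms, two 250 ms bins).
#'
#' @inheritParams jackknife_classify
#' @return A `classifier_result`.
#' @export
classify_identity_epoch <- function(dataset, condition = "off",
                                    window = c(250, 750), bin_ms = 250,
                                    equalize_templates = TRUE) {
  jackknife_classify(dataset, condition, window, bin_ms,
                     equalize_templates = equalize_templates)
}

# Restrict a dataset to a unit subset (keeps trial structure).
subset_units <- function(dataset, units) {
  ensemble_dataset(dataset$rasters[, units, , drop = FALSE],
                   dataset$trial_table,
                   dataset$unit_table[units, ],
                   bin_size_ms = dataset$bin_size_ms,
                   t0_ms = dataset$t0_ms)
}
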