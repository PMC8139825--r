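# Poisson ensemble hidden Markov model. Hidden states are vectors of
# per-unit firing rates; emissions are independent Poisson counts per unit
# in fixed bins (default 10 ms); inference is Baum-Welch EM with scaled
# forward-backward, best of several random restarts. The transition
# matrix is unconstrained (any state may transition to any other).

# counts array trials x units x bins over [window) ms
bin_counts <- function(dataset, trials, bin_ms = 10, window = c(0, 2500)) {
  starts <- seq(window[1], window[2] - bin_ms, by = bin_ms)
  n_units <- dim(dataset$rasters)[2]
  out <- array(0L, dim = c(length(trials), n_units, length(starts)))
  idx0 <- time_index(dataset, window[1], window[2])
  sub <- dataset$rasters[trials, , idx0, drop = FALSE]
  grp <- rep(seq_along(starts), each = bin_ms)
  for (i in seq_along(trials)) {
    m <- matrix(sub[i, , ], nrow = n_units)
    out[i, , ] <- t(rowsum(t(m), grp))
  }
  out
}

# Scaled forward-backward for one trial.
# logB: bins x states log emission probabilities.
# Returns gamma (bins x states), xi_sum (states x states), loglik.
forward_backward <- function(logB, A, pi0) {
  B <- nrow(logB); S <- ncol(logB)
  off <- apply(logB, 1, max)
  Bm <- exp(logB - off)
  alpha <- matrix(0, B, S)
  cvec <- numeric(B)
  a <- pi0 * Bm[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (b in 2:B) {
    a <- (alpha[b - 1, ] %*% A) * Bm[b, ]
    cvec[b] <- sum(a)
    alpha[b, ] <- a / cvec[b]
  }
  beta <- matrix(0, B, S)
  beta[B, ] <- 1
  for (b in (B - 1):1) {
    beta[b, ] <- (A %*% (Bm[b + 1, ] * beta[b + 1, ])) / cvec[b + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, S, S)
  for (b in 1:(B - 1)) {
    xi <- (alpha[b, ] %o% (Bm[b + 1, ] * beta[b + 1, ])) * A / cvec[b + 1]
    xi_sum <- xi_sum + xi
  }
  list(gamma = gamma, xi_sum = xi_sum,
       loglik = sum(log(cvec)) + sum(off))
}

# log emission matrix (bins x states) for counts C (units x bins) and
# rates r (units x states, counts per bin)
log_emission <- function(C, r) {
  lr <- log(pmax(r, 1e-12))
  t(C) %*% lr - matrix(colSums(r), ncol(C), ncol(r), byrow = TRUE) -
    rowSums(lgamma(t(C) + 1))
}

#' Fit a Poisson ensemble HMM
#'
#' Baum-Welch EM for a hidden Markov model whose states emit independent
#' Poisson spike counts per unit per bin, fitted to all trials of one
#' taste and laser condition. The best of `restarts` random
#' initializations (by final log-likelihood) is returned; the EM
#' log-likelihood trace of every restart is non-decreasing.
#'
#' @param dataset An [ensemble_dataset()].
#' @param taste Taste label to select trials (NULL = all tastes).
#' @param laser `"off"`, `"on"` or `"both"`.
#' @param n_states Number of hidden states (default 4: background,
#'   detection, identity, palatability).
#' @param bin_ms Emission bin width (ms, default 10).
#' @param window `c(from, to)` ms analysed (default the 0-2500 ms
#'   post-delivery period).
#' @param restarts Number of EM restarts.
#' @param seed Integer seed (restart r uses stream `seed * 1000 + r`).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An `hmm_model`: `init`, `trans` (row-stochastic), `rates`
#'   (units x states, counts/bin), `rates_hz`, `loglik`, `loglik_trace`,
#'   `restart_logliks`, `converged`, `bin_ms`, `window`, `trials`.
#' @export
fit_hmm <- function(dataset, taste = NULL, laser = "off", n_states = 4,
                    bin_ms = 10, window = c(0, 2500), restarts = 20,
                    seed = 1, max_iter = 200, tol = 1e-4) {
  trials <- condition_trials(dataset, laser)
  if (!is.null(taste))
    trials <- intersect(trials,
                        which(dataset$trial_table$taste %in% taste))
  if (length(trials) < 5) stop("need at least 5 trials", call. = FALSE)
  stopifnot(n_states >= 2)
  counts <- bin_counts(dataset, trials, bin_ms, window)
  n_tr <- dim(counts)[1]; n_units <- dim(counts)[2]; B <- dim(counts)[3]
  mean_rate <- apply(counts, 2, mean)  # counts per bin per unit

  best <- NULL
  restart_ll <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(seed * 1000 + r)
    rates <- matrix(pmax(mean_rate, 1e-3), n_units, n_states) *
      matrix(exp(rnorm(n_units * n_states, 0, 0.5)), n_units, n_states)
    A <- matrix(0.05 / (n_states - 1), n_states, n_states)
    diag(A) <- 0.95
    pi0 <- rep(1 / n_states, n_states)
    fit <- em_hmm(counts, rates, A, pi0, max_iter, tol)
    restart_ll[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$restart <- r
    }
  }
  structure(list(
    n_states = n_states, init = best$pi0, trans = best$A,
    rates = best$rates, rates_hz = best$rates / bin_ms * 1000,
    loglik = best$loglik, loglik_trace = best$trace,
    restart_logliks = restart_ll, restart = best$restart,
    converged = best$converged, n_iter = length(best$trace),
    bin_ms = bin_ms, window = window, trials = trials,
    n_units = n_units, seed = seed), class = "hmm_model")
}

# EM over all trials at once. The emission log-probabilities for every
# (trial, bin) pair are one matrix product of the stacked counts with
# log rates; forward-backward recursions run over bins with all trials
# batched as rows.
em_hmm <- function(counts, rates, A, pi0, max_iter, tol) {
  n_tr <- dim(counts)[1]; n_units <- dim(counts)[2]; B <- dim(counts)[3]
  S <- ncol(rates)
  # stacked counts: row (trial i, bin b) at index (b-1)*n_tr + i
  M <- matrix(aperm(counts, c(1, 3, 2)), n_tr * B, n_units)
  lgam <- rowSums(lgamma(M + 1))
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  bin_rows <- function(b) (b - 1L) * n_tr + seq_len(n_tr)
  for (it in seq_len(max_iter)) {
    lr <- log(pmax(rates, 1e-12))
    logB <- M %*% lr -
      matrix(colSums(rates), n_tr * B, S, byrow = TRUE) - lgam
    off <- row_maxs(logB)
    Bm <- exp(logB - off)
    alpha <- array(0, dim = c(n_tr, S, B))
    cmat <- matrix(0, n_tr, B)
    a <- matrix(pi0, n_tr, S, byrow = TRUE) * Bm[bin_rows(1), ,
                                                 drop = FALSE]
    cmat[, 1] <- rowSums(a)
    alpha[, , 1] <- a / cmat[, 1]
    for (b in 2:B) {
      a <- (alpha[, , b - 1] %*% A) * Bm[bin_rows(b), , drop = FALSE]
      cmat[, b] <- rowSums(a)
      alpha[, , b] <- a / cmat[, b]
    }
    ll <- sum(log(cmat)) + sum(off)
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
    ll_old <- ll
    # backward pass with gamma/xi accumulation
    beta <- matrix(1, n_tr, S)
    gamma_flat <- matrix(0, n_tr * B, S)
    g <- alpha[, , B] * beta
    gamma_flat[bin_rows(B), ] <- g / rowSums(g)
    xi <- matrix(0, S, S)
    for (b in (B - 1):1) {
      x <- Bm[bin_rows(b + 1), , drop = FALSE] * beta / cmat[, b + 1]
      xi <- xi + A * crossprod(alpha[, , b], x)
      beta <- x %*% t(A)
      g <- alpha[, , b] * beta
      gamma_flat[bin_rows(b), ] <- g / rowSums(g)
    }
    pi0 <- colSums(gamma_flat[bin_rows(1), , drop = FALSE])
    pi0 <- pi0 / sum(pi0)
    A <- xi / rowSums(xi)
    den <- colSums(gamma_flat)
    rates <- crossprod(M, gamma_flat)
    rates <- sweep(rates, 2, pmax(den, 1e-12), "/")
    rates <- pmax(rates, 1e-6)
  }
  list(rates = rates, A = A, pi0 = pi0, loglik = trace[length(trace)],
       trace = trace, converged = converged)
}

row_maxs <- function(m) do.call(pmax, as.data.frame(m))

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model>", x$n_states, "states,", x$n_units, "units,",
      length(x$trials), "trials; logLik", sprintf("%.1f", x$loglik),
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' Posterior state probabilities for one trial
#'
#' Forward-backward smoothed posteriors of each hidden state at each
#' emission bin; columns (states) sum to 1 at every bin.
#'
#' @param model An [fit_hmm()] model.
#' @param counts Units x bins count matrix for one trial (same unit count
#'   and binning as the model).
#' @return Matrix `bins x states` of posterior probabilities.
#' @export
decode_hmm <- function(model, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(model$rates))
    stop("trial has ", nrow(counts), " units but model expects ",
         nrow(model$rates), call. = FALSE)
  fb <- forward_backward(log_emission(counts, model$rates),
                         model$trans, model$init)
  fb$gamma
}

#' Posterior state probabilities for a set of trials
#'
#' @param model An [fit_hmm()] model.
#' @param dataset The dataset the model was fitted to (or a compatible
#'   one).
#' @param trials Trial indices; defaults to the trials the model was
#'   fitted on.
#' @return A named list (by trial index) of `bins x states` posterior
#'   matrices.
#' @export
decode_trials <- function(model, dataset, trials = NULL) {
  if (is.null(trials)) trials <- model$trials
  counts <- bin_counts(dataset, trials, model$bin_ms, model$window)
  out <- lapply(seq_along(trials), function(i)
    decode_hmm(model, matrix(counts[i, , ], nrow = dim(counts)[2])))
  names(out) <- trials
  out
}

#' Identify the palatability (or identity) state
#'
#' The candidate state is the one with the highest mean posterior
#' probability across all trials within a time window — 500-1500 ms for
#' the palatability state, 100-600 ms for the identity state. Ties go to
#' the lower state index.
#'
#' @param model An [fit_hmm()] model.
#' @param posteriors List of posterior matrices from [decode_trials()].
#' @param window `c(from, to)` ms window of expected dominance.
#' @return Integer state id.
#' @export
identify_state <- function(model, posteriors, window = c(500, 1500)) {
  b0 <- floor((window[1] - model$window[1]) / model$bin_ms) + 1L
  b1 <- min(ceiling((window[2] - model$window[1]) / model$bin_ms),
            nrow(posteriors[[1]]))
  mass <- Reduce(`+`, lapply(posteriors, function(g)
    colMeans(g[b0:b1, , drop = FALSE])))
  which.max(mass)  # which.max takes the first (lowest) index on ties
}

#' State-transition onset for one trial
#'
#' The onset is the time of the first emission bin at which the
#' posterior probability of the given state reaches the threshold
#' (default 0.5); a posterior stepping from 0 to 1 at (0-based) bin 70
#' with 10 ms bins yields 700 ms. `NA` if the threshold is never
#' reached.
#'
#' @param posterior `bins x states` posterior matrix.
#' @param state State id.
#' @param threshold Posterior probability threshold.
#' @param bin_ms Emission bin width (ms).
#' @param window_start_ms Time of the first bin (ms).
#' @return Onset time in ms, or `NA_real_`.
#' @export
transition_onset <- function(posterior, state, threshold = 0.5,
                             bin_ms = 10, window_start_ms = 0) {
  hit <- which(posterior[, state] >= threshold)
  if (!length(hit)) return(NA_real_)
  window_start_ms + (hit[1] - 1) * bin_ms
}

#' Per-trial state-onset alignment table
#'
#' Decodes each trial, finds the onset of the target state at the 0.5
#' posterior threshold, and returns the alignment used to re-zero trials.
#'
#' @param model An [fit_hmm()] model.
#' @param dataset The dataset.
#' @param state Target state id (e.g. from [identify_state()]).
#' @param trials Trial indices (default: the model's trials).
#' @param threshold Posterior threshold.
#' @return A `trial_alignment` tibble: `trial`, `state`, `onset_ms`,
#'   `valid`.
#' @export
align_trials <- function(model, dataset, state, trials = NULL,
                         threshold = 0.5) {
  if (is.null(trials)) trials <- model$trials
  post <- decode_trials(model, dataset, trials)
  onsets <- vapply(post, transition_onset, numeric(1), state = state,
                   threshold = threshold, bin_ms = model$bin_ms,
                   window_start_ms = model$window[1])
  out <- tibble(trial = trials, state = state, onset_ms = unname(onsets),
                valid = !is.na(onsets))
  class(out) <- c("trial_alignment", class(out))
  out
}

#' Re-align trials to their state-transition onsets
#'
#' Re-windows each valid trial's raster about its transition onset
#' (onset = time zero). Bins outside the recorded range are padded as
#' missing (`NA`) and the trial is flagged `padded`.
#'
#' @param dataset An [ensemble_dataset()].
#' @param alignment A [align_trials()] tibble.
#' @param span `c(before, after)` ms about the onset (default -1000 to
#'   +1500 ms).
#' @return A `realigned_ensemble`: `rasters` (valid-trials x units x
#'   span bins, NA-padded), `time_ms` (bin starts relative to onset),
#'   `trial_table` (valid trials with `onset_ms`, `padded`).
#' @export
realign <- function(dataset, alignment, span = c(-1000, 1500)) {
  al <- alignment[alignment$valid, ]
  if (!nrow(al)) stop("no valid trials to realign", call. = FALSE)
  n_span <- span[2] - span[1]
  n_units <- dim(dataset$rasters)[2]
  n_time <- dim(dataset$rasters)[3]
  ras <- array(NA_integer_, dim = c(nrow(al), n_units, n_span))
  padded <- logical(nrow(al))
  for (i in seq_len(nrow(al))) {
    from <- al$onset_ms[i] + span[1]
    cols <- seq.int(from - dataset$t0_ms + 1L, length.out = n_span)
    ok <- cols >= 1L & cols <= n_time
    padded[i] <- !all(ok)
    ras[i, , which(ok)] <- dataset$rasters[al$trial[i], , cols[ok]]
  }
  tt <- dataset$trial_table[al$trial, ] %>%
    mutate(onset_ms = al$onset_ms, padded = padded)
  structure(list(rasters = ras, time_ms = seq.int(span[1],
                                                  span[2] - 1L),
                 trial_table = tt, span = span),
            class = "realigned_ensemble")
}
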