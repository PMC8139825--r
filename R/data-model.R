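# Trial-structured ensemble container: 1-ms binary rasters over
# [-2000, 2500) ms around stimulus delivery, plus trial and unit tables.

#' Construct an ensemble dataset
#'
#' Bundles the binary spike rasters of one recording session with its trial
#' and unit tables. Rasters are 1-ms bins spanning `[t0_ms, t0_ms + n_time)`
#' relative to stimulus delivery (default -2000 to +2500 ms); windows
#' elsewhere in the package are half-open `[t, t + w)`.
#'
#' @param rasters Integer/logical array `trials x units x time` with entries
#'   in `{0, 1}`.
#' @param trial_table Tibble with columns `trial`, `taste` (one of
#'   `"Sucrose"`, `"NaCl"`, `"Acid"`, `"QHCl"`) and `laser_on` (logical).
#' @param unit_table Tibble with columns `unit`, `half_width_ms`,
#'   `session_id`.
#' @param bin_size_ms Raster bin width; only 1 ms is supported.
#' @param t0_ms Time (ms, relative to stimulus) of the first raster bin.
#' @return An object of class `ensemble_dataset`.
#' @export
ensemble_dataset <- function(rasters, trial_table, unit_table,
                             bin_size_ms = 1, t0_ms = -2000) {
  trial_table <- as_tibble(trial_table)
  unit_table <- as_tibble(unit_table)
  x <- structure(
    list(rasters = rasters, trial_table = trial_table,
         unit_table = unit_table, bin_size_ms = bin_size_ms, t0_ms = t0_ms),
    class = "ensemble_dataset")
  validate_ensemble_dataset(x)
}

validate_ensemble_dataset <- function(x) {
  stopifnot(inherits(x, "ensemble_dataset"))
  if (length(dim(x$rasters)) != 3L)
    stop("rasters must be a trials x units x time array", call. = FALSE)
  d <- dim(x$rasters)
  need_tr <- c("trial", "taste", "laser_on")
  miss <- setdiff(need_tr, names(x$trial_table))
  if (length(miss))
    stop("trial_table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  need_un <- c("unit", "half_width_ms", "session_id")
  miss <- setdiff(need_un, names(x$unit_table))
  if (length(miss))
    stop("unit_table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(x$trial_table) != d[1])
    stop("trial_table rows (", nrow(x$trial_table),
         ") do not match raster trials (", d[1], ")", call. = FALSE)
  if (nrow(x$unit_table) != d[2])
    stop("unit_table rows do not match raster units", call. = FALSE)
  if (d[2] < 1) stop("at least one unit is required", call. = FALSE)
  bad <- setdiff(unique(x$trial_table$taste), TASTES)
  if (length(bad))
    stop("unknown taste label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.logical(x$trial_table$laser_on))
    stop("laser_on must be logical", call. = FALSE)
  v <- unique(as.vector(x$rasters))
  if (!all(v %in% c(0L, 1L)))
    stop("raster entries must be 0 or 1", call. = FALSE)
  if (x$bin_size_ms != 1) stop("only 1 ms raster bins are supported",
                               call. = FALSE)
  x
}

#' @export
print.ensemble_dataset <- function(x, ...) {
  d <- dim(x$rasters)
  cat("<ensemble_dataset> ", d[1], " trials x ", d[2], " units x ", d[3],
      " ms bins, t0 = ", x$t0_ms, " ms\n", sep = "")
  cat("  tastes:", paste(table(x$trial_table$taste)[TASTES], collapse = "/"),
      " laser on:", sum(x$trial_table$laser_on), "\n")
  invisible(x)
}

#' Number of time bins / time axis helpers
#' @param dataset An `ensemble_dataset`.
#' @return `dataset_times()` returns the vector of bin start times (ms).
#' @export
dataset_times <- function(dataset) {
  dataset$t0_ms + seq_len(dim(dataset$rasters)[3]) - 1
}

# Column index range of the half-open window [from, to) in ms.
time_index <- function(dataset, from, to) {
  i0 <- from - dataset$t0_ms + 1L
  i1 <- to - dataset$t0_ms
  if (i0 < 1L || i1 > dim(dataset$rasters)[3] || i0 > i1)
    stop("window [", from, ", ", to, ") outside recorded range", call. = FALSE)
  seq.int(i0, i1)
}

#' Write a session bundle to disk
#'
#' Serializes an ensemble dataset to a plain-text bundle directory holding
#' `meta.json`, `trial_table.csv`, `unit_table.csv` and a sparse
#' `spikes.csv` (`trial,unit,time_ms` of every spike, sorted). Serialization
#' is deterministic: identical datasets produce byte-identical bundles.
#'
#' @param dataset An `ensemble_dataset`.
#' @param path Bundle directory to create (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  validate_ensemble_dataset(dataset)
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok) stop("cannot create bundle directory: ", path, call. = FALSE)
  d <- dim(dataset$rasters)
  meta <- list(format = "gustate-session", version = 1L,
               n_trials = d[1], n_units = d[2], n_time = d[3],
               bin_size_ms = dataset$bin_size_ms, t0_ms = dataset$t0_ms)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(path, "meta.json"))
  readr::write_csv(dataset$trial_table, file.path(path, "trial_table.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$unit_table, file.path(path, "unit_table.csv"),
                   progress = FALSE)
  idx <- which(dataset$rasters == 1L, arr.ind = TRUE)
  spikes <- tibble(trial = as.integer(idx[, 1]),
                   unit = as.integer(idx[, 2]),
                   time_ms = as.integer(dataset$t0_ms + idx[, 3] - 1L)) %>%
    arrange(.data$trial, .data$unit, .data$time_ms)
  readr::write_csv(spikes, file.path(path, "spikes.csv"), progress = FALSE)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' @param path Bundle directory written by [write_dataset()].
#' @return An `ensemble_dataset`; round-trips with [write_dataset()]
#'   bit-exactly.
#' @export
read_dataset <- function(path) {
  need <- c("meta.json", "trial_table.csv", "unit_table.csv", "spikes.csv")
  have <- file.exists(file.path(path, need))
  if (!all(have))
    stop("session bundle at ", path, " is missing: ",
         paste(need[!have], collapse = ", "), call. = FALSE)
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  if (is.null(meta$n_trials) || is.null(meta$t0_ms))
    stop("meta.json is missing required fields", call. = FALSE)
  trial_table <- readr::read_csv(file.path(path, "trial_table.csv"),
                                 show_col_types = FALSE, progress = FALSE)
  unit_table <- readr::read_csv(file.path(path, "unit_table.csv"),
                                show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("trial", "taste", "laser_on"), names(trial_table))
  if (length(miss))
    stop("trial_table.csv is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  spikes <- readr::read_csv(file.path(path, "spikes.csv"),
                            show_col_types = FALSE, progress = FALSE)
  ras <- array(0L, dim = c(meta$n_trials, meta$n_units, meta$n_time))
  if (nrow(spikes)) {
    if (max(spikes$trial) > meta$n_trials)
      stop("spikes.csv refers to trials beyond the trial table",
           call. = FALSE)
    ras[cbind(spikes$trial, spikes$unit,
              spikes$time_ms - meta$t0_ms + 1L)] <- 1L
  }
  trial_table$trial <- as.integer(trial_table$trial)
  unit_table$unit <- as.integer(unit_table$unit)
  ensemble_dataset(ras, trial_table, unit_table,
                   bin_size_ms = meta$bin_size_ms, t0_ms = meta$t0_ms)
}

#' Peri-stimulus time histogram from a raster matrix
#'
#' Trial-averaged firing rate in a moving window. The window is half-open
#' `[t, t + w)`; rate in Hz is (mean spike count in window) /
#' (window length in s). With window `w`, step `s` and `T` ms of raster the
#' trace has `floor((T - w) / s) + 1` windows.
#'
#' @param spk Binary matrix `trials x time` of 1-ms bins.
#' @param window_ms Window length (ms), at least 1.
#' @param step_ms Step between window starts (ms), at least 1.
#' @param t_start_ms Time of the first raster column (ms).
#' @return A tibble with `time_ms` (window centers) and `rate_hz`; the
#'   number of trials averaged is in attribute `n_trials`.
#' @export
compute_psth <- function(spk, window_ms, step_ms, t_start_ms = 0) {
  if (is.null(dim(spk))) spk <- matrix(spk, nrow = 1)
  if (nrow(spk) == 0L) stop("empty trial selection", call. = FALSE)
  stopifnot(window_ms >= 1, step_ms >= 1)
  n_time <- ncol(spk)
  if (n_time < window_ms) stop("raster shorter than window", call. = FALSE)
  starts <- seq.int(1L, n_time - window_ms + 1L, by = step_ms)
  # cumulative counts along time make each window an O(1) difference
  cs <- cbind(0, t(apply(spk, 1, cumsum)))
  counts <- cs[, starts + window_ms, drop = FALSE] -
    cs[, starts, drop = FALSE]
  rate <- colMeans(counts) / (window_ms / 1000)
  out <- tibble(time_ms = t_start_ms + (starts - 1) + window_ms / 2,
                rate_hz = rate)
  attr(out, "n_trials") <- nrow(spk)
  attr(out, "window_ms") <- window_ms
  attr(out, "step_ms") <- step_ms
  out
}

# Per-trial spike counts for one unit in [from, to) ms; returns a vector
# over trials (optionally restricted to rows `trials`).
unit_window_counts <- function(dataset, unit, from, to, trials = NULL) {
  idx <- time_index(dataset, from, to)
  m <- dataset$rasters[, unit, idx, drop = FALSE]
  cnt <- rowSums(m, dims = 1)
  if (!is.null(trials)) cnt <- cnt[trials]
  cnt
}
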