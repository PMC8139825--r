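# End-to-end orchestration: generate -> single-unit stats -> latency
# model -> decoding -> HMM/realignment -> transition dynamics, with
# per-stage seeds and a consolidated JSON-able report.

#' Default pipeline configuration
#'
#' @param generator A [generator_config()].
#' @param stages Character vector of stages to run, in dependency order,
#'   among `"generate"`, `"single_unit"`, `"latency"`, `"decode"`,
#'   `"hmm"`, `"transitions"` (`"transitions"` requires `"hmm"`).
#' @param seed Base integer seed; each stage derives its own stream.
#' @param out_dir Optional directory for the JSON report (NULL = don't
#'   write).
#' @param glm_units How many units to run the MCMC laser-impact GLM on
#'   (the slowest single-unit step); NULL = all.
#' @param mcmc_iter,hmm_restarts,sigmoid Scale knobs for the stochastic
#'   stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       stages = c("generate", "single_unit", "latency",
                                  "decode", "hmm", "transitions"),
                       seed = 1, out_dir = NULL, glm_units = 4,
                       mcmc_iter = 500, hmm_restarts = 5,
                       sigmoid = FALSE) {
  structure(list(generator = generator, stages = stages, seed = seed,
                 out_dir = out_dir, glm_units = glm_units,
                 mcmc_iter = mcmc_iter, hmm_restarts = hmm_restarts,
                 sigmoid = sigmoid), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes the enabled stages in dependency order with per-stage seeds
#' derived from the base seed and collects one consolidated report.
#' Identical configurations and seeds give identical reports.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list with one section per executed stage
#'   (skipped stages are absent; a stage whose dependency was disabled is
#'   recorded under `skipped`), plus `seeds` and `timing_s`. If
#'   `config$out_dir` is set, the report (minus bulky objects) is written
#'   to `report.json` there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  report <- list(seeds = list(base = config$seed), skipped = character(0))
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  gen <- NULL

  if ("generate" %in% st) {
    t0 <- tic()
    gen <- generate_ensemble(config$generator, seed = config$seed)
    report$generate <- list(
      n_trials = nrow(gen$dataset$trial_table),
      n_units = nrow(gen$dataset$unit_table),
      trials_per_taste = unname(table(gen$dataset$trial_table$taste)[1]),
      laser_on_trials = sum(gen$dataset$trial_table$laser_on),
      mean_transition_ms = mean(gen$truth$trials$transition_ms))
    timing["generate"] <- tic() - t0
  }
  needs_data <- setdiff(st, "generate")
  if (is.null(gen) && length(needs_data)) {
    report$skipped <- needs_data
    report$timing_s <- as.list(timing)
    class(report) <- "pipeline_report"
    return(report)
  }
  ds <- gen$dataset

  if ("single_unit" %in% st) {
    t0 <- tic()
    resp <- taste_responsivity(ds)
    spec <- taste_specificity(ds)
    types <- classify_unit_type(ds$unit_table$half_width_ms)
    pal <- palatability_units(ds, condition = "off")
    gu <- seq_len(min(config$glm_units %||% nrow(ds$unit_table),
                      nrow(ds$unit_table)))
    glm <- purrr::map(gu, function(u)
      laser_impact_glm(ds, u, n_iter = config$mcmc_iter,
                       n_warmup = config$mcmc_iter,
                       seed = config$seed + u))
    impacted <- vapply(glm, attr, logical(1), which = "impacted")
    lat <- vapply(gu[impacted], function(u) impact_latency(ds, u),
                  numeric(1))
    report$single_unit <- list(
      n_responsive = sum(resp$responsive),
      n_specific = sum(spec$specific),
      n_in = sum(types == "IN"), n_pc = sum(types == "PC"),
      n_palatability = sum(pal$flagged),
      glm_units = length(gu), n_impacted = sum(impacted),
      impact_latencies_ms = as.numeric(na.omit(lat)))
    timing["single_unit"] <- tic() - t0
  }

  if ("latency" %in% st) {
    t0 <- tic()
    lats <- generate_latencies(n = 2000, seed = config$seed + 101)
    cmpf <- compare_fits(lats, seed = config$seed + 102)
    report$latency <- list(
      mixture_means_ms = cmpf$mixture$means_ms,
      mixture_sds_ms = cmpf$mixture$sds_ms,
      r2_mixture = cmpf$r2_mixture, r2_exp = cmpf$r2_exp,
      t = cmpf$t, df = cmpf$df, p_value = cmpf$p_value)
    timing["latency"] <- tic() - t0
  }

  if ("decode" %in% st) {
    t0 <- tic()
    within_off <- jackknife_classify(ds, "off")
    within_on <- jackknife_classify(ds, "on")
    cross <- cross_condition_classify(ds, "off", "on")
    report$decode <- list(
      accuracy_off = within_off$overall_accuracy,
      accuracy_on = within_on$overall_accuracy,
      accuracy_cross = cross$overall_accuracy,
      per_taste_off = setNames(within_off$per_taste_accuracy$accuracy,
                               within_off$per_taste_accuracy$taste))
    timing["decode"] <- tic() - t0
  }

  ta <- NULL
  if ("hmm" %in% st) {
    t0 <- tic()
    if ("transitions" %in% st) {
      ta <- transition_analysis(ds, restarts = config$hmm_restarts,
                                seed = config$seed + 301,
                                sigmoid = config$sigmoid)
      al <- ta$off$alignment
    } else {
      m <- fit_hmm(ds, taste = TASTES[1], laser = "off",
                   restarts = config$hmm_restarts,
                   seed = config$seed + 301)
      stt <- identify_state(m, decode_trials(m, ds))
      al <- align_trials(m, ds, stt)
    }
    report$hmm <- list(
      n_valid_alignments = sum(al$valid),
      median_onset_ms = median(al$onset_ms, na.rm = TRUE))
    timing["hmm"] <- tic() - t0
  } else if ("transitions" %in% st) {
    report$skipped <- c(report$skipped, "transitions")
    warning("transitions stage skipped: hmm stage disabled",
            call. = FALSE)
  }

  if (!is.null(ta)) {
    t0 <- tic()
    report$transitions <- list(
      regression_slope = ta$comparison$regression$slope,
      p_vs_1 = ta$comparison$regression$p_vs_1,
      latency_chisq_p = ta$comparison$latency_chisq$p_value,
      sigmoid_differs = ta$sigmoid_differs)
    timing["transitions"] <- tic() - t0
  }

  report$timing_s <- as.list(round(timing, 2))
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages:",
      paste(setdiff(names(x), c("seeds", "skipped", "timing_s")),
            collapse = ", "), "\n")
  if (length(x$skipped)) cat("  skipped:",
                             paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
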