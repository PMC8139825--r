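Package: gustate
Title: Ensemble State Dynamics of Cortical Taste Responses Under
    Optogenetic Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured multi-neuron spike
    trains recorded from gustatory cortex while basolateral-amygdala
    axonal input is optogenetically perturbed. Provides single-unit taste
    responsivity, specificity and palatability statistics, a hierarchical
    Bayesian Poisson GLM for laser-impact contrasts, Gaussian-mixture and
    exponential models of impact-latency distributions, jack-knife
    Euclidean template decoding of taste identity, Poisson ensemble hidden
    Markov models with trial realignment to state-transition onsets, and
    peri-transition slope analyses that quantify the sharpness of ensemble
    state transitions. Includes a synthetic spike-train generator with
    ground truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
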