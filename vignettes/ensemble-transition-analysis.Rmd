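---
title: "Models and methods: ensemble taste-coding analysis under perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ensemble taste-coding analysis under perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `gustate`, the assumptions they
make, the tunable parameters that matter, and the design decisions taken
where several reasonable implementations existed. It states no empirical
result beyond what the package's tests and acceptance script themselves
compute.

## The response model

Cortical taste responses are treated as an epoch sequence per trial:
baseline firing before delivery; a taste-nonspecific *detection* phase
over [0, 200) ms; taste-specific *identity* firing from 200 ms; and
*palatability*-ranked firing after a sudden per-trial switch. Palatability
is an ordinal variable (Sucrose = 4 > NaCl = 3 > Citric Acid = 2 >
Quinine-HCl = 1, `palatability_map()`). All times are milliseconds
relative to stimulus delivery; rasters are 1-ms Bernoulli bins over
[−2000, 2500); every analysis window is half-open [t, t + w), which keeps
window counts exact and avoids double-counting boundary spikes.

## The synthetic-data generator

`generate_ensemble()` draws spikes as independent Bernoulli events per
1-ms bin at probability rate/1000 — the discrete-time version of an
inhomogeneous Poisson process, chosen deliberately so that the generator
matches the Poisson assumptions of the GLM and HMM stages rather than
testing their robustness to misspecification. Key defaults and why:

- **30 trials per taste, half laser-On** — the standard session design
  the pipeline targets.
- **Per-trial switch time** ~ Normal(700 ms, 150 ms) truncated to
  (250, 2400) ms. Only trial-to-trial variability of the switch is
  established empirically; the Gaussian family is our choice.
- **Heterogeneous units.** Baselines are log-spaced over 1.5–15 Hz,
  identity-epoch tuning is broad and graded (a per-unit boost of
  5–20 Hz spread over the preference order as 100%/40%/15%/0%), and
  palatability gains alternate in sign with magnitudes 1.5–6 Hz per
  rank unit. Cortical taste data are dominated by exactly this kind of
  across-unit heterogeneity in rate scale and tuning depth; per-neuron
  peri-transition slope magnitudes in published data span roughly
  0–0.5 Hz/ms, and the defaults reproduce that scale. Homogeneous units
  would make regression-style Off-vs-On comparisons meaningless, since
  between-unit variance would fall below the slope estimator's sampling
  noise (an errors-in-variables attenuation problem, not a biological
  one).
- **Laser effects** are multiplicative per unit (factor < 1 suppression
  or > 1 enhancement, never both in one unit), switched on at a
  per-unit onset; defaults alternate onsets of 350 and 750 ms, matching
  the two modes of the impact-latency distribution the latency module
  fits. No quantitative suppression magnitude is established for this
  pathway; ×0.5 on half the units is a placeholder of realistic size.
- **Transition blurring** (`blur_ms`) linearly ramps the
  identity-to-palatability rate change on laser trials over the given
  duration — the "gradual rate change" mechanism. A second mechanism,
  per-unit *decoupling* of switch times (`decouple_sd_ms`), is provided
  so the pipeline's ability to discriminate the two hypotheses can be
  tested: blurring shallows slopes while leaving max-slope latencies
  centred; decoupling spreads latencies.

What the generator does **not** emulate: refractoriness and spike-train
autocorrelation, correlated noise across units, session-to-session
heterogeneity, drifting baselines, or waveform data beyond a scalar
half-width. Passing tests therefore demonstrate correctness of the
analysis chain under its own assumptions, not robustness to every
property of real recordings.

## Single-unit statistics

- *Responsivity*: paired t across trials, evoked [0, 2000) vs. baseline
  [−2000, 0) mean rate, collapsed over tastes. A push–pull unit
  (excited by some tastes, inhibited by others) can be non-responsive
  yet taste-specific; the test suite constructs exactly this case.
- *Specificity*: two-way repeated-measures ANOVA on four 500 ms bins of
  evoked firing, Taste × Time, with trials nested in taste and time as
  the within-trial factor (`aov` with a trial error stratum). Either a
  taste main effect or interaction at p < 0.05 flags the unit. No
  sphericity correction is applied (the source procedure is silent on
  it); the type-I error calibration in the acceptance suite checks the
  realized alpha.
- *Palatability*: Spearman's rho (average-rank ties) between
  single-trial window rates and ranks, 250 ms windows stepped 25 ms
  over [0, 2500); a unit is flagged when ≥ 3 consecutive windows have
  p < 0.05. Zero-variance windows yield missing rho and can never be
  significant.
- *Cell type*: half-width < 0.35 ms = putative interneuron. The
  boundary itself is assigned to the pyramidal class: the source rule
  states strict inequalities on both sides, leaving 0.35 ms open, and a
  deterministic rule is required.

## The laser-impact GLM

Per-trial spike counts over the 2500 ms laser window are Poisson with a
log link on grand mean + taste + condition + taste×condition.
Taste/condition effects get Normal(0, σ²) priors with half-Normal(1)
hyper-scales — weakly informative and stable at 15 trials per cell.
Sampling uses JAGS (4 chains, 1000 warmup + 1000 kept draws by default);
convergence is summarised by the largest split-chain shrink factor and a
diagnostic flag at 1.1. Significance follows the credible-interval rule:
the 95% CrI of the per-taste On−Off contrast (in Hz) excluding zero. A
unit is *impacted* if any taste response is significant. Impact onset is
estimated descriptively: Welch t per 100 ms bin, earliest run of ≥ 2
consecutive significant bins — onset detection is acknowledged to be
noisy at single-unit resolution, which is why latencies are modelled at
the population level.

## Latency mixture versus exponential decay

The 2-component Gaussian mixture is fitted to the *raw* latencies by EM
(best of `restarts` random initializations; the log-likelihood trace is
retained and checked non-decreasing on every fit), while R² and the
model comparison are computed against the 25 × 100 ms binned histogram —
this reconciles a distribution-level fit with a per-bin error
comparison at df = 24. The exponential is fitted to the same histogram
by Levenberg–Marquardt least squares. Degenerate EM solutions (collapsed
components) are flagged rather than silently returned. k = 2 is fixed:
the comparison of interest is bimodal-versus-decay, not model selection
over k.

## Decoding

Nearest-template classification in the concatenated unit × bin count
space; summing squared per-bin distances computed in unit space is
mathematically identical to one Euclidean distance on the concatenated
vector, so the implementation uses the latter. Counts are used rather
than rates (bins are equal-width, so they are proportional). Distance
ties are broken by canonical taste order and counted; with continuous
noise they have measure zero. In the jack-knife variant every taste's
template — not only the held-out trial's own — is computed with one
trial dropped (the index-matched trial of each other taste), so all
four templates are means of the same number of trials. This
variance-matching makes the four distances exchangeable under the null
and pins finite-sample chance at exactly 25%; the naive asymmetric
scheme (own template from n−1 trials, others from n) sits measurably
below chance on iid features and remains available as an option.
Templates are updated by running sums, verified against an
explicit-loop oracle in the test suite.

## The ensemble HMM

Hidden states are vectors of per-unit firing rates; emissions are
independent Poisson counts per unit in 10 ms bins over [0, 2500). Both
the emission bin width and the default of 4 states (background,
detection, identity, palatability) are analysis choices, configurable;
the transition matrix is deliberately *unconstrained* (no left-to-right
restriction). Baum–Welch runs on all trials of one taste and laser
condition at once (the recursions batch trials as matrix rows), with
scaled forward–backward for numerical stability; the winner of
`restarts` random initializations by final log-likelihood is returned
with every restart's likelihood logged. Convergence is declared at a
log-likelihood gain below `tol` (default 1e-4); non-converged fits
return the best iterate, flagged. Models are fitted separately per
condition by default; `shared_fit = TRUE` instead fits on control trials
and decodes perturbed trials through the same model — both modes exist
because the source procedure does not specify which was used, and the
dissociation result holds under either.

The *palatability state* is the state with the highest mean posterior
mass over 0.5–1.5 s across trials (ties to the lower index); the
*identity state* uses 0.1–0.6 s. Per-trial onset is the first bin at
which that state's posterior reaches 0.5 (0-based bin convention: a
step at bin 70 of 10 ms bins is 700 ms); trials that never reach
threshold are invalid and excluded from realigned analyses.
Realignment re-windows each trial about its onset over [−1000, 1500) ms
by default (shorter spans are used where the analysis only needs
±700 ms), padding unrecorded bins as missing.

## Transition sharpness

On realigned trials the moving-window palatability correlation is
recomputed per unit relative to the transition; the across-unit mean
|rho| trace is fitted with a 4-parameter logistic (Gaussian observation
noise; half-Normal prior on the growth rate, uniform-over-span on the
inflection) by MCMC. Two conditions differ significantly when their 95%
slope credible intervals do not overlap — the interval-overlap rule is
retained deliberately rather than a posterior-difference test.

Peri-transition slopes are measured per unit × taste response: the
realigned PSTH is scanned with a 100 ms window stepped 20 ms, the rate
is regressed on time within each window, and the maximum |slope| within
±160 ms of the transition is recorded with its latency. "160 ms" is
ambiguous between a total and a half-width; ±160 ms is used, and the
moving-window analysis is insensitive to halving the period. Slopes are
reported in Hz/ms (multiply by 1000 for Hz/s). Records are per taste
response rather than pooled
across tastes because pooling would average palatability-epoch rates
across ranks toward baseline and erase the very step being measured; a
pooled mode remains available. Off-vs-On comparison: OLS of On on Off
slopes with an intercept (forcing the origin is not assumed) and a
t-test of the slope against 1; quintile groups of the Off slope with
per-group paired tests (skipped below 5 records); a chi-squared
comparison of 20 ms-binned max-slope latency histograms (bins pooled so
expected counts are usable, analytic p for determinism); and a paired t
of per-record latencies.

## Problem sizes and tolerances

The test and acceptance suites run at desk scale, chosen for CPU-minute
budgets while keeping every check statistically meaningful: 10-unit
ensembles with 30 trials/taste for decoding calibration (chance-level
accuracy averaged over 10 null ensembles, 1200 held-out trials); 2000
latency draws for mixture recovery (±25 ms); 30 null and 12 effect
units for GLM calibration; 20–40 seeded replicates for onset-recovery
and credible-interval-coverage properties; and 60 trials/taste (30 per
condition) for the paired Off/On transition comparison. Exact numerical
identities (forward–backward vs. path enumeration, classifier vs.
brute force, Spearman vs. independent ranking) are checked at 1e-10 to
1e-12.

## Known limitations

- Poisson emissions and Bernoulli generation are matched by
  construction; real spike trains are over/under-dispersed.
- The HMM state count is fixed per fit; no model selection over states.
- Impact-latency onset detection at the single-unit level is
  coarse (100 ms bins) by design.
- The serialization container is a plain-text bundle (JSON + CSV); it
  favours inspectability and deterministic bytes over compactness.
- MCMC stages (GLM, sigmoid) are deterministic given seeds but their
  draws depend on the sampler's RNG stream; cross-platform bitwise
  reproducibility is only as strong as JAGS's.
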