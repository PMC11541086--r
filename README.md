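# oscbayes

Oscillation analysis and Bayesian group comparison for EEG and LFP
recordings.

## What problem this package addresses

Studies of cortical excitation/inhibition balance compare groups of
subjects (e.g. carriers of a synaptic gene variant vs matched controls, or
knockout vs wildtype mice) on a battery of oscillation-derived measures:
inter-regional coherence in theta and gamma bands, theta-phase-to-
gamma-amplitude coupling between entorhinal cortex and hippocampus,
resting-state EEG microstate statistics, TMS-evoked global mean field
power, and neuropsychological score tables. The group-level inference is
Bayesian: posterior probability of a mean difference with 80% / 90%
significance tiers and a posterior effect-size mode, or Bayes-factor
ANOVAs with 3 / 10 / 100 evidence thresholds.

`oscbayes` implements that full analysis chain as reusable, tested R code,
together with a synthetic-data module that generates every input with
known ground truth (coupling depth, coherence mix, microstate sequence,
evoked response, group moments), so that each estimator can be validated
against closed forms and recovery oracles without any recordings.

## The statistics at the core

* **Coherence.** Signals are standardized, split into `M` disjoint
  segments of length `L` (`N = LM`, remainder dropped), and segment-
  averaged auto-/cross-spectra give the magnitude-squared coherence
  `C(f) = |S_xy|^2 / (S_xx S_yy)`. Values above the analytic confidence
  limit `1 - (1 - alpha)^(1/(M-1))` (default `alpha = 0.99`) are
  significant; under independent noise ~1% of frequencies exceed it.
* **Phase-amplitude coupling.** The amplitude envelope of the fast band
  (e.g. 30-100 Hz) is binned by the phase of the slow oscillation (e.g.
  10 Hz); with per-bin means `p`, the modulation index is
  `m = (max(p) - min(p)) / max(p)`. For a generated envelope
  `a (1 + d cos phi)` the closed form is `m = 2d / (1 + d)`.
* **Microstates.** Topographies at GFP peaks are clustered by
  polarity-invariant modified k-means into 4 classes, back-fitted to every
  sample by maximal `|spatial correlation|`, and summarized per class by
  duration (ms), occurrence (1/s) and coverage.
* **Evoked responses.** GMFP is the root-mean-square deviation from the
  instantaneous mean over an electrode subset of the evoked average,
  on a -0.25 to 2 s window; band-power ratios are baseline-normalized per
  condition: `(P_cond / P_base) / (P'_cond / P'_base)`.
* **Group comparison.** A robust two-group model (Student-t likelihood,
  per-group means and SDs, shared normality parameter) is sampled by MCMC
  (default 100,000 draws). Reported are
  `P(diff) = 100 max(P(mu1 > mu2), P(mu2 > mu1))`, tiers at > 80%
  (significant) and > 90% (highly significant), and the kernel-density
  mode of the per-draw effect size
  `(mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2)`. A JZS (Zellner-Siow)
  one-way ANOVA Bayes factor covers the microstate contrasts.

## Worked example

```r
library(oscbayes)

# two coupled regions: 5 Hz theta in A, theta-modulated 60 Hz gamma in B
spec <- coupling_spec(theta_freq = 5, gamma_freq = 60, d = 0.6, w = 0.4,
                      noise_sd = 0.3, fs = 1000, duration = 60, seed = 1)
pair <- gen_coupled_pair(spec)

ch <- coherence(as.numeric(pair$region_A$data[1, ]),
                as.numeric(pair$region_B$data[1, ]), L = 2000, fs = 1000)
ch
#> <coherence_result> 1001 frequencies, M = 30, conf limit (alpha = 0.99) = 0.147
band_summary(ch, band_profile("human")$theta)
#> <band_summary> 4-8 Hz: mean 0.193, peak 0.3483 at 4 Hz (9 bins)

pac_binned(pair$region_A, pair$region_B, phase_freq = 5,
           amp_band = c(30, 100), direction = c("EC", "HC"))
#> <pac_result> m = 0.7021 (EC -> HC phase 5 Hz -> amplitude 30-100 Hz, 18 bins)

# two-group comparison on moment-matched scores (273.7 +/- 35.1 vs 266.1 +/- 32.3)
g <- gen_group_scores(group_spec(273.7, 35.1, 25, 266.1, 32.3, 25, seed = 1))
best_compare(g$group1, g$group2, n_mcmc = 100000, seed = 2)
#> <group_comparison> P(difference) = 81.6%, effect-size mode = 0.273, significant
#>   mean difference 8.985 [-10.88, 28.73] (n = 25 vs 25, 100000 draws)
effect_size_mode_formula(273.7, 266.1, 35.1, 32.3)
#> [1] 0.2253249
```

Reading the output: theta-band coherence (mean 0.19) sits above the
`M = 30` confidence limit (0.147) because 40% of the noise is a shared
source; the modulation index 0.70 is close to the closed form
`2 * 0.6 / 1.6 = 0.75` for the generated depth `d = 0.6`; and the score
comparison lands in the "significant" tier with a posterior effect-size
mode near the plug-in value 0.225.

End-to-end synthetic-cohort studies (generate two cohorts, analyze every
subject, compare all measures) run from a single config:

```r
res <- run_study(list(species_profile = "mouse", seed = 1, n_subjects = 8,
                      cohorts = list(control = list(coupling = list()),
                                     carrier = list(coupling = list(d = 0.3)))),
                 out_dir = "study_out")
res$comparisons
```

A command-line interface with subcommands `synth`, `coherence`, `pac`,
`microstates`, `gmfp`, `compare`, `study` is installed at
`inst/cli/oscbayes` (see `?oscbayes_cli`).

## Documentation

The methods vignette (`vignettes/oscbayes-methods.Rmd`) documents the
models, the synthetic-data generator's assumptions, all numerical choices
and known limitations.
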