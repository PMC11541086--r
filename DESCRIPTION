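Package: oscbayes
Title: Oscillation Analysis and Bayesian Group Comparison for EEG and LFP
    Recordings
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for frequency-domain analysis of multichannel neural
    recordings and Bayesian comparison of derived measures between groups.
    Implements segment-averaged magnitude-squared coherence with an analytic
    confidence limit, Morlet-wavelet band power, theta-gamma phase-amplitude
    coupling (phase-binned modulation index and Hilbert-envelope variants,
    with comodulograms and surrogate nulls), resting-state EEG microstate
    segmentation (polarity-invariant modified k-means, back-fitting, and
    duration/occurrence/coverage statistics), stimulus-locked global mean
    field power with baseline-normalized band-power ratios, a robust
    Bayesian two-group comparison via MCMC with posterior effect-size mode
    and probability-of-difference significance tiers, and a JZS Bayes-factor
    one-way ANOVA. A synthetic-data module generates coupled two-region
    signals, microstate EEG, evoked epochs, and moment-matched group scores
    with known ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
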