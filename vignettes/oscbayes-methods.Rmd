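---
title: "oscbayes: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oscbayes: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the estimators, their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite or the acceptance script does not itself compute.

# Spectra and coherence

Two concurrently recorded series `x(t)`, `y(t)` of length `N` are
standardized (mean 0, SD 1 — this makes coherence exactly invariant to
channel-wise affine rescaling), divided into `M = floor(N/L)` disjoint
segments of length `L` (remainder samples dropped and recorded in the
result), tapered, Fourier transformed, and the per-segment auto- and
cross-spectra are averaged. The magnitude-squared coherence
`C(f) = |S_xy|^2 / (S_xx S_yy)` lies in `[0, 1]`; it equals 1 identically
for `y = x` and, for `y = x + independent noise` with per-frequency SNR
`s`, approaches `s / (1 + s)`.

**Confidence limit.** For `M` averaged segments the null distribution of
the coherence estimate has CDF `1 - (1 - C)^(M-1)`, so values above
`1 - (1 - alpha)^(1/(M-1))` are significant at level `alpha` (default
0.99), and under independence the exceedance rate is exactly `1 - alpha`.
`M = 1` leaves the limit undefined, so `coherence()` requires `M >= 2`
(the spectra themselves are available for `M = 1` and then equal the plain
periodogram).

**Taper.** The taper is configuration (`boxcar`, `hann` — the default —
or `multitaper`). No DPSS implementation exists in the dependency set, so
the multitaper option uses sine tapers
(`sqrt(2/(L+1)) sin(pi k n/(L+1))`), the closed-form multitaper family;
the confidence limit is still computed from the segment count `M`, which
is conservative when several tapers are averaged per segment.

**Band profiles.** Theta is 4-8 Hz for the human profile and 7-12 Hz for
the mouse profile; gamma is 30-100 Hz with a low/high split at 70 Hz. The
profile argument is mandatory everywhere bands are implied — the two
theta definitions must never be mixed silently. Band summaries use
edge-inclusive bins and report the in-band mean and argmax peak.

**Morlet power.** Wavelets are Gaussian-windowed complex exponentials
with `sigma_t = n_cycles / (2 pi f)` (default 3 cycles, centers 1-100 Hz),
truncated at 3.5 sigma and normalized to unit energy; the spectrum is the
time-averaged magnitude of the transform, with one half-support excluded
at each edge. "Power" is the plain magnitude by default
(`power_exponent = 1`); squared magnitude is one option away. Two
consequences of these conventions are worth knowing: three-cycle wavelets
are spectrally broad (`sigma_f = f/3`), and unit-energy normalization
gives a mild `f^(-1/2)` gain tilt, so in multi-component signals a
high-frequency local maximum can sit a couple of bins below the true
component frequency. The tests assert localization at that fidelity and
no better.

# Phase-amplitude coupling

Both PAC variants reduce to the same binned modulation index on their
respective phase/envelope estimates, which makes their outputs
numerically comparable:

* `pac_binned()` (field-potential style): phase of the slow region at a
  single frequency (default 10 Hz, band-pass of total width 4 Hz),
  envelope of the fast region over a band (default 30-100 Hz), both via
  zero-phase frequency-domain filtering plus the analytic signal.
* `pac_hilbert()` (scalp style): the same machinery parameterized by
  explicit theta and gamma bands (defaults 3-7 Hz and 30-100 Hz, i.e. a
  5 Hz center).

With per-phase-bin envelope means `p` over `n_bins = 18` bins (20-degree
bins, common practice and configurable) the index is
`m = (max(p) - min(p)) / max(p)`, in `[0, 1]` whenever all `p > 0`. For a
generated envelope `a (1 + d cos phi)` the closed form is
`m = 2d/(1+d)`; binning averages the cosine within each bin, so even
noiseless data recovers the closed form only to about 0.005 at 18 bins —
test tolerances (0.02) account for that. Phase 0 is the oscillation peak
and bins tile `[-pi, pi)`; empty bins are an error advising longer input
or fewer bins.

Zero-phase filtering matters: a causal filter would delay the envelope
relative to the phase and bias the bin profile's location. All filters
here are frequency-domain masks with raised-cosine transitions (15% of
each edge frequency, at least 0.5 Hz), hence exactly zero-phase.

The significance of a single index is assessed against circular
time-shift surrogates (envelope rotated by at least 1 s, 200 draws, 95th
percentile). No published single-recording null exists for this index; the
surrogate procedure is an explicit artifact addition and is labeled as
such in its output.

`pac_comodulogram()` scans (phase frequency, amplitude frequency) grids;
each amplitude cell uses a half-bandwidth of `max(1.5 f_phase, 5)` Hz so
the modulation sidebands `f_amp ± f_phase` fall inside the cell's band —
too narrow a band would structurally miss the coupling.

# Microstates

The pipeline is GFP → peak picking → modified k-means → back-fitting →
run-length statistics. All topographic steps run on average-referenced
data; GFP (the per-sample population SD across channels) and
polarity-invariant spatial correlation presuppose that reference, which
the source analyses leave unstated.

* **Peak picking:** strict local maxima, greedily thinned highest-first to
  a minimum separation (default 1 sample, i.e. no thinning).
* **Clustering:** polarity-invariant k-means — assignment by maximal
  squared projection, prototype update as the first eigenvector of the
  assigned maps' scatter, which is exactly the GEV-optimal unit map.
  Both steps are monotone in GEV, so the per-iteration GEV trace (kept on
  the model object and asserted in tests) never decreases. Convergence at
  GEV increment < 1e-6; 100 restarts by default, best GEV kept; k = 4
  fixed as in the source analyses. Empty clusters keep their previous
  prototype. AAHC is not implemented.
* **Class letters:** the published canonical template maps are not
  available in this environment, and inventing maps and calling them
  canonical would be misleading. Deviation from the original design
  sketch: `templates` is an optional argument (greedy assignment by
  maximal absolute correlation); without it, letters follow decreasing
  explained variance. Letter identity therefore carries no anatomical
  claim unless the user supplies templates.
* **Back-fitting:** per-sample argmax of `|corr|` with ties broken to the
  first class; temporal smoothing exists (majority vote) but is off by
  default, since the source analyses mention none.
* **Statistics:** per class, mean run length (ms), runs per second, and
  sample fraction. Coverages over observed classes sum to 1 by
  construction.

# Evoked responses

GMFP uses the Lehmann–Skrandies field-power form — the root-mean-square
deviation from the instantaneous mean over the electrode subset — applied
to the epoch-averaged evoked response on a −0.25 to 2 s window. The
formula is invariant to a common offset across the subset. The default
16-label frontal subset for the 10–10 montage shipped with the package is
configuration, not a claim about any particular study's montage.
Band power over an interval is the Hann-windowed periodogram summed over
in-band one-sided bins, which returns `a^2/2` for an in-band sinusoid of
amplitude `a` (the tests assert 2%). Condition contrasts are
double-normalized ratios `(P_cond/P_base) / (P'_cond/P'_base)`; the
baseline interval defaults to the pre-stimulus part of the window
(−0.25–0 s), which the source analyses do not state.

# Bayesian group comparison

No MCMC engine or Bayes-factor package exists in the supported dependency
set, so both samplers are implemented in the package.

**Two-group model.** `y_ij ~ t_nu(mu_j, sigma_j)` with a shared normality
parameter `nu` (a Kruschke-style robust model — the standard realization
of a "posterior of the difference plus effect-size mode" output). Priors
are deliberately vague and scaled by the pooled sample SD: `mu_j ~
N(pooled mean, (1000 pooled SD)^2)`, `sigma_j` uniform on `(pooled
SD/1000, 1000 pooled SD)`, `nu - 1 ~ Exponential(mean 29)`. Sampling uses
the scale-mixture representation of the t (per-observation Gamma latent
precisions), giving conjugate updates for `mu_j` and `sigma_j^2` and a
random-walk Metropolis step on `log(nu - 1)`; 100,000 draws after 2,000
burn-in by default. Constant input degenerates to a unit prior scale with
a warning. Observations are exchangeable under the model, so each group is
sorted before sampling — this makes results exactly invariant to input row
order at identical seeds.

Per draw, the effect size is `(mu1 - mu2)/sqrt((sigma1^2 + sigma2^2)/2)`.
The reported mode is the argmax of a Gaussian KDE over the draws
(Silverman bandwidth): a continuous posterior's "mode" needs an
estimator, and the KDE argmax is the conventional one. The plug-in
formula on printed group moments uses the same expression; of the two
possible parenthesizations of the printed formula, the adopted one
reproduces the published example values (e.g. 273.7/35.1 vs 266.1/32.3
gives 0.225 against a printed 0.22), while the literal alternative
(`sqrt(s1^2 + s2^2)/2`) gives 0.319 and is rejected.

**Significance tiers.** `P(diff) = 100 max(P(mu1 > mu2), P(mu2 > mu1))`,
significant above 80, highly significant above 90. The per-draw effect
size carries the sign of the mean difference, so the "effect size above
80%" clause is satisfied exactly when the mean-difference clause is; both
probabilities are reported so alternative readings can be audited. One
calibration fact follows directly and is reported (not failed) by a test:
under the null this probability is approximately Uniform(50, 100), so the
80% rule flags roughly 40% of null measures. A "null study" is therefore
only deterministically clean when the two cohorts are literally identical
(same generator parameters and same seed offset), which is how the
acceptance suite constructs it; with resampled cohorts the flag rate is
the rule's nominal behavior, not a bug.

**Bayes-factor ANOVA.** The JZS (Zellner–Siow) one-way Bayes factor is
computed from the ANOVA `R^2` by one-dimensional integration of the
g-prior marginal over `g ~ InverseGamma(1/2, N rscale^2/2)` on the
log-`g` scale (with a peak-shift for numerical stability), `rscale = 0.5`
(the conventional "medium" fixed-effect scale, logged in the result).
Verdicts follow the 3 / 10 / 100 thresholds. Different toolboxes differ
in design-matrix scaling conventions; the implementation is validated on
behavior (null BF < 1 in median, large separations above 100, verdict
consistency), not against another package's third decimal.

**Covariates.** "Correction" for covariates is pre-residualization: per
measure, scores are replaced by residuals of `value ~ covariates` plus
the grand mean before comparison. This is an artifact implementation
choice, flagged in the output.

# The synthetic-data generators: a stated world

`gen_coupled_pair()` generates region A as
`theta_amp * cos(2 pi f_theta t)` plus noise and region B as
`gamma_amp (1 + d cos phi_theta) cos(2 pi f_gamma t)` plus noise. The
ground-truth theta phase is the analytic phase of the noiseless theta
component — exact by construction, so recovery tests never depend on the
estimator under test. Noise is white Gaussian (the source analyses
specify none); a fraction `w` of each region's noise is a shared source,
which makes coherence tunable and monotone in `w`. Optional per-band
mixes `w_theta` / `w_gamma` (default `w`) apply different shared
fractions inside the theta and gamma bands — a compatible extension
needed to plant "lower theta coherence, higher gamma coherence" in one
cohort, as the planted-effect study requires.

`gen_microstate_eeg()` draws geometric dwell times (memoryless switching
is the simplest model consistent with ~100 ms quasi-stable states;
default mean 100 ms), per-sample amplitudes `|N(1, 0.3^2)|` with a random
but within-instance-constant polarity, and white noise scaled to the
requested amplitude SNR (signal RMS / noise RMS). The amplitude model
fluctuates around a typical strength without vanishing — a vanishing
envelope would make single-sample classification ill-posed at any SNR and
claims like "99% label recovery" meaningless; real GFP rarely touches
zero.

`gen_group_scores()` draws Gaussians; with `moment_match` each sample is
affinely rescaled so its mean and (n−1) SD equal the requested values to
floating precision. Moment matching pins two moments only — higher
moments still vary with the seed, and the robust model responds to them,
which is why the acceptance script averages its reported posterior modes
over five replicate samples (variance reduction of the same estimand; no
tolerance depends on it).

`gen_evoked_epochs()` injects a known decaying oscillation (default
10 Hz, 0.3 s time constant) after t = 0, distributed over channels by a
weight vector, plus white noise; the epoch must cover the −0.25 to 2 s
analysis window.

What the generators do **not** emulate: 1/f background spectra, line
noise, eye blinks and other artifacts, volume conduction / field spread,
non-stationarity, and correlated noise between channels. A green
recovery test therefore establishes correctness of the estimators under
the stated model, not robustness to real-world contamination.

# Reproducibility and the study pipeline

`run_study()` derives every subject's seed from the config seed plus a
per-cohort `seed_offset`; identical parameters and offsets give
bit-identical cohorts, and identical configs give byte-identical output
tables. Each output bundle embeds the seed and a hash of the full
config. Configs are JSON (no YAML parser is available in the dependency
set); `validate_config()` fills documented defaults, rejects unknown keys
with their path, is idempotent, and refuses profile/band mismatches
(e.g. a 4-8 Hz theta under the mouse profile) without an explicit
`force`.

Two runtime notes on the shipped test suite: the posterior-mode
convergence check uses n = 4,000 per group (scaled down from the
ten-thousand-scale statement of the property for runtime; the tolerance,
0.02, is unchanged), and the end-to-end studies use 20-s recordings with
6-8 subjects per cohort and 10,000 MCMC draws per measure so the whole
suite stays around a minute.

# Known limitations

* Coherence confidence limits assume independent segments; with the
  multitaper option the limit ignores the extra averaging across tapers
  (conservative).
* The EDF reader/writer supports the common case only: one sampling rate
  across signals, 16-bit records. It is a convenience path; the
  delimited-text + JSON sidecar format is primary.
* The JZS ANOVA uses the `R^2` form with a single `g`; unbalanced designs
  are handled, random effects and multi-factor designs are not.
* Microstate letters are arbitrary without user-supplied templates.
* The surrogate PAC null and covariate pre-residualization are artifact
  additions, flagged in their outputs.
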