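---
title: "Stability-driven EEG network classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-driven EEG network classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

netstab classifies subjects from multichannel EEG through a fixed sequence of
stages: band-limited functional connectivity (phase-locking value and
magnitude-squared coherence), graph-theoretic summaries of the resulting
brain networks, a *stability score* that ranks features by how consistently
important they are across cross-validation folds, and nested subject-wise
cross-validation of SVM and random-forest classifiers with subject-level
aggregation and bootstrap confidence intervals. This vignette documents the
models, the tunable parameters, and the design decisions — including the
places where the design space was genuinely open and a choice had to be made.

## The measurement model

**Phase-locking value.** For two channels with instantaneous phases
$\varphi_i(t)$, $\varphi_j(t)$ (from the Hilbert analytic signal of the
band-filtered data),

$$\mathrm{PLV}_{ij} = \Big| \tfrac{1}{T} \sum_t e^{i(\varphi_i(t) - \varphi_j(t))} \Big|.$$

PLV is 1 under rigid phase locking and has an independence floor of about
$\sqrt{\pi}/(2\sqrt{T})$ for $T$ samples. Ten percent of the samples at each
epoch edge are discarded before the PLV sum to suppress filter and Hilbert
transients; this fraction is the `edge_trim` parameter.

**Coherence.** Magnitude-squared coherence
$C_{ij}(f) = |S_{ij}(f)|^2 / (S_{ii}(f)\,S_{jj}(f))$ is estimated by Welch's
method inside each 2-s epoch (1-s Hann segments, 50% overlap — three segments)
and averaged over the frequency bins inside the band. With so few segments
the estimator has a substantial positive bias under independence (about 0.34
for these settings); that floor is group-independent and therefore harmless
for between-group contrasts, but coherence values should not be read as
absolute coupling strengths.

**Graph metrics.** Subject-level connectivity matrices (the unweighted mean
over that subject's epoch matrices) become fully weighted graphs: the
diagonal is zeroed and, by default, *no* threshold is applied — thresholding
would introduce a free parameter the downstream analysis does not need.
Proportional thresholding (retain the strongest fraction `p` of edges) is
available behind `graph$threshold_p`; ties at the cutoff are resolved by a
fixed edge ordering (ascending row, then column index) so results are
reproducible. Path-based metrics use edge length $1/w$, the standard choice
for coupling weights in $[0,1]$: global efficiency is the mean inverse
shortest-path length over ordered pairs (disconnected pairs contribute 0),
characteristic path length the mean shortest-path length (undefined on a
disconnected graph; `largest_component = TRUE` reports the largest-component
value, flagged via an attribute). Weighted clustering uses the Onnela
geometric-mean form with weights normalised by the network maximum. Node
strength is the weighted degree.

**Feature table.** Per subject, band and measure the table contains: the mean
connectivity of every unordered region pair (including within-region pairs),
global efficiency, characteristic path length, network-mean clustering and
network-mean strength, named `<measure>_<band>_<descriptor>` (e.g.
`plv_theta_frontal_parietal`, `plv_theta_geff`). Regions default to
channel-name prefixes (F/Fp frontal, C central, P parietal, O occipital,
T temporal; midline `z` channels follow their letter). A within-region pair
spanning a single channel has no value and its column is dropped with a
message.

One genuinely open design point is whether classifier rows are subjects or
epochs. The default is one row per subject with features computed from
epoch-averaged connectivity, which matches how group-level connectivity and
network tables are usually reported and keeps the classifier sample size
honest (subjects, not epochs, are the independent units). With
`features_per = "epoch"` the table has one row per epoch instead, and
out-of-fold epoch probabilities are averaged into a single subject
probability before any metric is computed — the epoch-level route with
subject-level evaluation. Both obey subject-wise fold boundaries.

## Stability-driven feature selection

For each feature $f$, fold-wise importances yield a mean $\mu_f$ and a sample
(n−1) standard deviation $\sigma_f$, combined as

$$\mathrm{Stability}_f = \frac{\mu_f}{\sigma_f + \varepsilon},
\qquad \varepsilon = 10^{-9},$$

so a feature must be both important and *consistently* important to rank
highly. $\varepsilon$ only guards the $\sigma_f = 0$ case and is numerically
negligible at realistic dispersions. Ties are broken by larger $\mu_f$, then
feature name. The top `k` features (default 10) are retained.

Importance is permutation importance: the drop in a held-out score when one
feature column is shuffled. The scoring rule matters more than is obvious.
With subject-level rows, validation sets are small, and discrete scores
(accuracy, rank-based AUC) are quantized so coarsely that permuting a single
column of a many-feature model almost never changes them — every importance
is then exactly zero and the ranking collapses to tie-breaks. The default
rule is therefore the (negative) Brier score, which is continuous in the
predicted probabilities and registers arbitrarily small perturbations; AUC
and accuracy remain available via `stability$score`.

Within each outer-fold training set the inner grouped folds drive four steps:
hyperparameters are tuned on all features (pooled subject-level AUC over the
inner folds; ties resolved by grid order), fold-wise importances are estimated
with the tuned settings (fit on inner-train, score on inner-validation),
the stability score selects the top-`k` features, and the grid is re-tuned on
the selected set before refitting on the full training fold. Estimating
importances with a *tuned* model rather than an arbitrary grid point is
deliberate: a badly regularized model spreads probability mass so flatly that
importances are dominated by fold-to-fold scale, not by features.

The reported global ranking aggregates one record per feature per outer fold
(the mean of that fold's inner-fold importances) and applies the same score
across the outer folds. Selection itself always happens strictly inside each
outer training fold; the global ranking is reporting, not selection.

Shapley attributions are computed for interpretation, never for selection.
With at most `exact_limit` (12) features all $2^p$ coalitions are enumerated
against a background sample — attributions are exact and satisfy local
accuracy to machine precision; larger sets fall back to permutation sampling.

## Classifiers and evaluation

The SVM uses an RBF kernel with grids $C \in \{0.1, 1, 10, 100\}$ and
$\gamma \in \{10^{-3}, 10^{-2}, 10^{-1}, 1\}$ on z-scored features
(standardization fitted on training folds only, applied to test folds). SVM
probabilities come from Platt-style calibration — a logistic fit of the
training labels on the SVM decision values. This is fitted deterministically
on the training outputs rather than by the internal cross-validated variant
some libraries use, because the pipeline guarantees byte-identical outputs
for identical seeds and an unseedable calibration step would break that
contract. The random forest baseline tunes tree count {100, 300} and depth
{unlimited, 5, 10}.

The outer loop is stratified five-fold cross-validation *over subjects*:
every epoch of a subject lives entirely in either the training or the test
side, asserted on every fold at run time. Out-of-fold subject probabilities
(threshold 0.5, positive class = patients) give accuracy, recall,
specificity, and AUC via the rank statistic with mid-rank tie correction.
Fold-to-fold dispersion is reported as the across-fold SD; 95% confidence
intervals for accuracy and AUC use percentile bootstrap over subjects
(default 10,000 resamples; resamples lacking a class are redrawn).

All randomness derives from a single master seed through a deterministic
hash, so any stage can be reproduced in isolation and identical runs are
byte-identical.

## The synthetic data generator

The generator emulates the structure the pipeline assumes: two groups of
subjects, each contributing many 2-s epochs of multichannel band-limited
activity, with a group difference planted in theta-band phase coupling
between designated frontal and parietal channels.

Each coupled pair shares a carrier: phase
$\phi(t) = 2\pi f_{\mathrm{pair}} t + W(t)$ with a slow random-walk
perturbation ($W$ increments of SD 0.05 rad/sample). The first member carries
$\cos\phi(t)$; the second carries $\cos(\phi(t) + \delta(t))$ where
$\delta(t)$ is von Mises with the group's concentration $\kappa$, so the
pair's population PLV is the closed form $I_1(\kappa)/I_0(\kappa)$. Two
implementation details keep the planted effect where it is declared:

* **Blockwise jitter.** $\delta(t)$ is held constant over 0.5-s blocks
  (`jitter_block_s`) instead of being redrawn every sample. The marginal
  distribution — and hence the closed-form PLV target — is unchanged, but
  per-sample white jitter would be averaged away by the band-pass filter and
  Hilbert transform (the measured PLV for $\kappa = 1$ inflates from 0.45
  toward 0.8), compressing the planted contrast, and its broadband spectral
  splatter would give jittered channels a group-dependent in-band
  signal-to-noise ratio, leaking the effect into every pair they touch.
* **Spaced carriers.** Distinct pairs receive evenly spaced carrier
  frequencies inside the band. If pairs shared one frequency, cross-pair
  channel combinations would themselves be phase-locked (with effective
  jitter $\delta_1 - \delta_2$, PLV $\approx R(\kappa)^2$) — a spurious
  planted feature.

Uncoupled channels carry independent band-limited Gaussian oscillations of
matching RMS, and every channel receives additive broadband noise
(white by default; a $1/f^a$ exponent is available, off by default since the
analysis is within fixed bands). Defaults: 16 channels in a 10-20-style
layout, 128 Hz sampling (a common analysis rate whose Nyquist comfortably
clears the 40 Hz band ceiling), 2-s epochs, groups of 19 and 24 subjects
with about 500 epochs each (matching the cohort scale the pipeline targets),
coupled pairs (F3, P3) and (F4, P4), $\kappa_P = 1$ vs
$\kappa_{HC} = 6$ — patients get the weaker, noisier coupling — oscillation
amplitude 1 and noise SD 1.

What the generator does *not* emulate: ocular/muscle artifacts and their
topographies, task-event structure, volume conduction, channel-specific
noise, nonstationarity beyond the carrier phase walk. Passing tests on this
generator therefore demonstrate that the pipeline recovers planted
band-specific coupling differences under realistic sample sizes and honest
cross-validation — not that it handles artifact-laden recordings; real data
still need the usual artifact pipeline (a hook is provided but intentionally
does nothing by default, because no defensible automatic component-rejection
rule is bundled).

## Preprocessing choices

Zero-phase (forward-backward) IIR filtering throughout: a 4th-order
Butterworth band-pass (default 1–40 Hz) and a narrow Butterworth band-stop
notch (default 50 Hz, quality factor 30). Zero-phase filtering is essential
here — phase distortion would corrupt PLV directly. Band decomposition
(delta 1–4, theta 4–8, alpha 8–13, beta 13–30 Hz; only theta's edges are
anchored, all are overridable) happens on the *continuous* recording before
epoching so epoch edges carry no fresh filter transients; the residual edge
effects of the Hilbert transform are handled by the PLV edge trim.
Re-referencing to the common average comes after filtering; it is idempotent
and exact (channel means zero to machine precision).

## Numerical and reproducibility notes

* `expected_plv_von_mises` switches to the asymptotic expansion
  $1 - 1/(2\kappa) - 1/(8\kappa^2)$ above $\kappa = 100$, where the direct
  Bessel ratio loses precision; both branches agree to $<10^{-6}$ at the
  switch point.
* The von Mises sampler is the Best–Fisher rejection algorithm; $\kappa = 0$
  reduces to the circular uniform.
* Grid-search ties go to the first combination in grid order; stability ties
  to larger $\mu$, then name — every tie-break is documented and
  deterministic.
* Degenerate inputs fail loudly before computation: single-class training
  sets, single-fold stability records, disconnected graphs (for path
  length), empty band lists, overlapping band definitions, unknown config
  keys.

The test suite exercises the full pipeline at deliberately moderate problem
sizes — e.g. planted-effect studies with 12 + 12 subjects and 100 epochs each
over 20 seeds, and label-permuted null studies with 10 + 10 subjects and 30
epochs — which are large enough for the subject-level contrasts of interest
while keeping a complete run of the suite fast enough to be part of routine
development.

## Known limitations

* Coherence shares the PLV pipeline's epoch-wise estimation; with three
  Welch segments per epoch its single-epoch values are noisy and biased, and
  only averages across many epochs are interpretable.
* The stability score is scale-aware but not scale-free: comparing scores
  across different importance estimators (or scoring rules) is not
  meaningful; rank within one estimator is.
* With very small cohorts the inner grouped folds contain few validation
  subjects; importance estimates are correspondingly noisy, which is exactly
  the situation the cross-fold stability aggregation is designed to expose
  rather than hide.
* The CLI covers dataset simulation and full-pipeline runs; intermediate
  stages (feature extraction, selection, training, reporting) are exposed as
  package functions rather than separate subcommands, since their natural
  interchange format is the run directory the full run already writes.
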