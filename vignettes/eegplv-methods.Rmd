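---
title: "Occipital-seeded phase-locking connectivity with a bootstrap baseline screen: models and methods"
author: "eegplv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eegplv methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(eegplv)
```

## Scope

`eegplv` implements a complete event-related EEG analysis chain for the
question "which scalp regions phase-couple to the visual cortex after a
stimulus, and how does oscillatory power and ERP lateralization change?":

1. preprocessing — common-average reference, zero-phase 1–30 Hz bandpass,
   AMUSE blind source separation for ocular artifacts, epoching with a
   200 ms pre-stimulus baseline, 100 µV amplitude rejection, band
   splitting (delta 1–3, theta 4–7, alpha 8–13, beta 14–30 Hz);
2. connectivity — phase-locking values (PLV) from a fused occipital seed
   (mean of Oz, O1, O2, POz, PO3, PO4) to every other electrode, screened
   into *effective* PLVs (ePLVs) by a bootstrap test against the
   pre-stimulus baseline;
3. spectral analysis — Morlet-wavelet event-related spectral perturbation
   (ERSP), a Hjorth finite-difference surface Laplacian, mu-rhythm ERD/ERS
   extraction, and the PO7–PO8 ERP lateralization contrast;
4. a synthetic-EEG generator with known ground truth, so the whole chain is
   validated end to end without any recorded data.

Real participant EEG of the kind this pipeline targets is typically not
redistributable, so the package treats the generator as a first-class
module: every statistical property asserted by the test suite is measured
on data whose true coupling, gains and ERPs are known by construction.

## The statistics

### Monte-Carlo permutation test (independent samples)

For samples $A$, $B$ with $H_0\!: \bar A \le \bar B$ the statistic is
$v_0 = \bar A - \bar B$. Each of $n_r$ resamples pools the data and splits
it at random into groups of the original sizes, recording the new mean
difference. With the resampled statistics sorted ascending, the *location*
is the rank of the first value strictly greater than $v_0$ and

$$p = 1 - \frac{\text{location}}{n_r}.$$

When no resampled value exceeds $v_0$ the rank is undefined and $p$ is
taken at its limit, $0$; `floor_p = TRUE` substitutes the conservative
$1/(n_r+1)$. An exhaustive-enumeration oracle
(`permutation_test_exhaustive`) applies the same strict ordering to every
$\binom{n_A+n_B}{n_A}$ split and anchors the Monte-Carlo engine in the
test suite (agreement within 0.02 at $n_r = 10{,}000$). The engine's
type-I error at $\alpha = 0.05$ is checked by simulation
(`permutation_calibration`, 1000 null datasets of 19 vs 19 standard
normals).

### Paired bootstrap test

For paired samples $C$, $D$ with $H_0\!: \bar C \le \bar D$, the
differences $P = C - D$ are resampled with replacement $n_r$ times; each
mean $A_k$ is recorded. With $A_{(1)} \le \dots \le A_{(n_r)}$, the
*index* is the rank of the first value strictly greater than zero and
$p' = \text{index}/n_r$; if all resampled means are positive the index is
1 ($p' = 1/n_r$ with no extra floor), and if none are, $p' = 1$. Ties are
broken strictly, consistently with the permutation engine.

Both engines draw all randomness from one explicit `seed` argument;
`seed = NULL` means "continue the caller's RNG stream", which is how
`screen_eplv` keeps thousands of inner tests reproducible under a single
outer seed.

### One-way ANOVA

The ERP lateralization contrast uses the classical one-way $F$ test with
Tukey HSD pairwise comparisons, via `stats::aov` / `stats::TukeyHSD`.

## Phase-locking value and the ePLV screen

Instantaneous phases come from the analytic signal (frequency-domain
Hilbert transform) of band-limited epochs; each epoch is mirror-padded
200 ms per side so the transform's edge transients do not contaminate the
pre-stimulus baseline. For seed phase $\theta_{i,k,t}$ and target phase
$\theta_{j,k,t}$ (epoch $k$ of $n$, time $t$):

$$\mathrm{PLV}_{i,j,t} = \Big[\tfrac1n\sum_k \cos\Delta\theta_{k,t}\Big]^2 +
  \Big[\tfrac1n\sum_k \sin\Delta\theta_{k,t}\Big]^2,$$

the **squared** resultant length of the phase differences. The squared
form is the package default; the conventional resultant (its square root)
is available via `convention = "sqrt"`. The two are monotonically related,
so the baseline-relative screen below is unaffected by the choice; the
squared form has null expectation exactly $1/n$ for uniform phases, and
for von Mises distributed phase differences with concentration $\kappa$
its expectation approaches $(I_1(\kappa)/I_0(\kappa))^2$ — the closed
form the acceptance checks recover.

The seed is formed at the *signal* level: the arithmetic mean of the six
occipital channels, before any phase extraction. Averaging phases, or
averaging per-channel PLVs, would measure something different (phase
averaging is not linear); signal fusion is the plainest reading of a
"fused occipital channel" and behaves like a low-noise virtual electrode.

The ePLV screen works in two steps, per electrode and band:

1. per participant, the baseline-window PLVs are resampled with
   replacement, averaged, and the bootstrap distribution of averages is
   reduced to its grand mean (`bootstrap_baseline_mean`) — a stable
   per-participant control value;
2. at each time point, the across-participant PLVs are tested against the
   per-participant control values with the one-tailed paired bootstrap
   (PLV above baseline). Cells with $p' \le \alpha$ form the ePLV mask.

No multiple-comparison correction is applied across electrodes or time —
that is the procedure's published form — so the mask's false-positive
rate is controlled per cell (at $\alpha$), not familywise. Consumers who
need familywise control can apply `p.adjust` to the mask's `p` matrix.
The screen tests every `time_stride`-th sample (default 1; the pipeline
uses 25, i.e. 50 ms at 500 Hz): PLV series are smooth at the analyzed
bandwidths and the stride bounds the cost of the inner bootstrap.

The test direction is one-tailed for PLV *increase* by default
(`direction = "greater"`), with the decrease direction exposed, since a
"significantly different from baseline" connectivity claim in this design
is a claim of phase-locking above the pre-stimulus level.

## ERSP, surface Laplacian, ERD/ERS, ERP lateralization

**Morlet transform.** Implemented as a Gaussian (Gabor) filter on the
analytic spectrum; ridge magnitude equals the tone amplitude in µV. The
cycle count ramps linearly from 3 cycles at 1 Hz to 8 at 30 Hz — the
usual compromise between temporal resolution at low frequencies and
spectral resolution at high ones — and is configurable. Samples within
two wavelet standard deviations of an epoch edge are flagged.

**ERSP.** Per epoch, channel and frequency,
$10\log_{10}(u_{i,j}/\mathrm{baseline}_j)$ where $u$ is the
wavelet-coefficient *magnitude* and $\mathrm{baseline}_j$ its
pre-stimulus average; epochs are averaged afterwards. The magnitude
convention is the default; `convention = "power"` squares $u$ first
(a 20 log scale on amplitude). Two numerical choices matter for a 200 ms
baseline that starts at the epoch edge: (i) the per-frequency baseline
average excludes samples inside the wavelet edge zone (falling back to
the later half of the window when the zone covers it), since the taper
decay otherwise biases the baseline downward by several percent; and
(ii) `mu_erd_ers` searches ERD/ERS excursions only outside the flagged
edge zones, where taper decay would masquerade as desynchronization.
Zero baselines yield `NaN` with a warning rather than infinities.

**Surface Laplacian.** Hjorth finite differences: each channel minus the
inverse-distance-weighted mean of its $k = 4$ nearest montage neighbours.
It annihilates spatially uniform maps exactly, nearly annihilates linear
gradients over the cap interior, and turns a focal hotspot into a
positive centre with negative neighbours. Following the source analysis
it is applied to ERSP topographies, not raw potentials.

**ERP lateralization.** Epochs are baseline-corrected (pre-stimulus mean
subtracted — the difference waveform presupposes zero-centred baselines),
grand-averaged per condition at PO7 and PO8, and the left-minus-right
difference is summarized by window means ± SE (default window
246–300 ms), peak counts (local maxima of the rectified difference above
a configurable 0.5 µV prominence), and the one-way ANOVA across
conditions on per-epoch window means.

## The synthetic generator

`synth_config()` describes a session the way the emulated experiment is
structured: four stimulus conditions (A–D), 35 trials per condition per
session (140 total), 1 s fixation, 1 s stimulus (the stimulus duration is
not dictated by the design being emulated; 1 s is the package default),
1–2 s uniformly jittered inter-trial interval, 500 Hz sampling on a
64-channel 10-10 montage. Defaults were chosen once, as field-realistic
values, and the tests run under them:

* background: $1/f^\alpha$ pink noise, $\alpha = 1$, 10 µV SD per channel
  — the canonical EEG-like spectrum with closed-form control;
* coupling: a band-limited oscillation (default 15 µV) added to the six
  occipital seed channels, with a phase-lagged copy on each target
  channel jittered per trial by a von Mises(0, $\kappa$) angle; 25 ms
  cosine ramps sit *outside* the stated window so the full effect covers
  it;
* power modulation: a band-centre oscillation (default 20 µV) spanning
  the epoch whose envelope is multiplied by `gain` inside the window
  (gain < 1 → ERD, > 1 → ERS);
* ERPs: Gaussian-windowed deflections, per-channel amplitudes for
  lateral asymmetry;
* blinks: 400 ms raised-cosine transients, 200 µV at the frontal pole
  (typical physiological scale) decaying exponentially with montage
  distance from the pole — a fixed spatial pattern times a smooth time
  course, i.e. exactly the second-order structure AMUSE separates;
* outlier trials: a 180 µV excursion on a random channel in a configured
  fraction of trials (default 2 %), exercising the 100 µV rejection.

The montage is a schematic top-view disc (rows at fixed anterior–
posterior heights, lateral positions along circular arcs, exact left–
right mirror symmetry), adequate for topographies and nearest-neighbour
operators; it is not a digitised electrode cloud, and the generator does
no biophysical forward modelling — no head model, no dipoles, no
volume conduction. Consequently the tests demonstrate *algorithmic*
correctness (the screen detects coupling that is there and stays at its
nominal false-positive rate when it is not), not robustness to the
spatial correlation structure of real scalp EEG.

Recordings round-trip through 16-bit EDF (`write_edf` / `read_edf`) with
a TSV event sidecar; the true sample count rides in the header's reserved
field so final-record padding is trimmed on read. The format is
cross-validated against an independent reader in the test suite.

## Preprocessing choices

* The bandpass is a frequency-domain mask with raised-cosine transitions
  of 0.5 Hz per edge (avoiding brick-wall ringing) and exactly zero group
  delay. FFT lengths are padded to 2-3-5-smooth sizes (mirror
  continuation) for performance.
* AMUSE uses lag-1 symmetrized covariance $(C_\tau + C_\tau^\top)/2$ of
  whitened data, the canonical formulation; the lag is exposed. Because
  common-average referencing leaves the data rank $n-1$, whitening
  truncates near-zero eigenvalues instead of failing: reconstruction
  without component removal is then exact (the discarded direction
  carries no variance). Channels with zero variance are a named error.
* No dedicated EOG channels are assumed: frontal-pole electrodes
  (Fp1/Fpz/Fp2) act as proxies, and components correlating $\ge 0.7$ in
  absolute value with any proxy are removed. Threshold and proxies are
  arguments.
* The 100 µV rejection applies after re-referencing, filtering and
  artifact removal (strictly greater-than comparison), matching the
  stated processing order of the emulated analysis; whether rejection
  preceded the ICA there is not documented, and post-ICA is the choice
  that keeps blinks from consuming the trial budget.
* The epoch end is configurable (default +1.0 s — the emulated design
  ends a trial 1 s after onset).
* Band splitting operates per epoch with 200 ms mirror padding. The
  narrowband kernels (0.5 Hz transitions ≈ 2 s impulse response) are
  longer than an epoch, so per-epoch filtering approximates — it cannot
  equal — filtering the continuous record; mid-epoch the two paths
  correlate above 0.97, which is the property the tests assert.

## Pipeline and problem sizes

`run_pipeline()` drives the full analysis per simulated participant
(synthesis → preprocess → band split → per-condition PLV → ERSP → ERP),
caches each participant's intermediates under `outdir/cache` (an
interrupted run resumes), then runs the group-level screen, ERSP/ERD/ERS
summaries with a Laplacian topography snapshot, the ERS condition
contrast, and the ERP ANOVA, writing TSV tables plus a JSON manifest
(config hash, seed, versions). With one seed, all fixed-seed outputs are
byte-identical across runs.

Resampling defaults are 10,000 draws, the published figure; the bundled
demo profile uses 1,000 (recorded in the manifest) and the validation
suite sizes its simulations for desk-scale runs: the group detection
study uses 19 simulated participants × 40 epochs with theta coupling to
three electrodes ($\kappa = 4$), screened at 50 ms stride with 1,000
bootstrap draws; the determinism check runs the demo pipeline twice at
3 participants × 16 trials. These sizes are the package's validation
design; all thresholds (sensitivity ≥ 80 %, per-cell false positives
≈ α, gain recovery within 1 dB, calibration within 1.5 points of α) are
stated in `tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

## Known limitations

* No volume conduction or source geometry in the generator: spatial
  leakage between channels (and through the common-average reference) is
  not emulated unless injected explicitly. Notably, common-average
  referencing mixes seed activity into every channel and thereby creates
  real, weak, widespread coupling — a property of referencing that users
  of seeded connectivity should expect on real data too.
* The screen controls false positives per cell, not familywise (by
  design, matching the published procedure).
* AMUSE is the only BSS algorithm offered (no Infomax/FastICA), lag-1 by
  default; sources with identical lagged autocorrelation are not
  separable by any second-order method.
* The ePLV screen assumes one PLV series per participant per electrode;
  epochs are pooled within participant before the across-epoch sum.
* PLV requires narrowband input; phases of broadband signals are
  computed but not meaningful, and the package does not guard against
  that misuse beyond documentation.
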