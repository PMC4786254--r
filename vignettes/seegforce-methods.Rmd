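---
title: "Band-power decoding of grasp force from SEEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power decoding of grasp force from SEEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`seegforce` implements an analysis pipeline for grasp force-matching
experiments recorded with stereoelectroencephalography (SEEG) depth
electrodes: it asks which brain regions modulate their field-potential
band power when a person produces (or imagines) a graded grasp force, and
how well those modulations decode force state on single trials. Because
clinical SEEG recordings cannot be redistributed, the package ships a
synthetic session generator that plants modulation of known depth into
realistic 1/f background noise, so every downstream stage is testable
end to end.

## The experimental protocol being modelled

A session consists of blocks of force-matching trials: a visual target is
shown for 5 s, followed by 5 s of rest, with force targets at 20, 30 and
40 % of the participant's maximum voluntary contraction (MVC), five
trials per level per block in randomized order, in two grasp
configurations (lateral pinch and whole-hand power grasp). Imagined
blocks follow the same timing but produce no force output. The force
sensor runs on its own clock (100 Hz by default) separately from the
2 kHz neural channels.

## Signal model of the generator

Each channel is `1/f^a` Gaussian background noise (FFT amplitude shaping,
`a = 1` by default). For every planted (region, band) entry the generator
adds a band-passed Gaussian carrier (4th-order Butterworth, zero-phase)
whose variance is `carrier_snr` times the background variance in that
band — the carrier is the "oscillation" whose event-related
synchronization (ERS) or desynchronization (ERD) we plant. Modulation is
a *multiplicative envelope* on the carrier: a raised-cosine ramp (100 ms)
into a plateau that ends at force offset. Multiplicative scaling of a
noise carrier moves band power without introducing line spectra, matching
the broadband character of high-gamma activity.

Three design choices deserve explanation:

* **Modulation onset.** The envelope starts 1 s *before* force onset
  (`latency_s = -1`), i.e. at the cue, because motor preparation builds
  ERD/ERS before overt force output and the modulation-depth statistic
  reads a response window of −1 to 0 s relative to force onset. A latency
  of 0 would leave that window almost empty. The latency is configurable
  per planted entry.
* **Depth units and calibration.** Planted depths are expressed in
  baseline-SD units of the *band feature* — the mean of per-1 Hz-bin
  z-scores that the analysis pipeline itself computes. The generator
  calibrates the envelope gain per channel and band against a rehearsal
  of its own baseline: for depth `d`, the plateau gain is
  `g = sqrt(1 + d * SD_feat / gain_per_unit)` where `gain_per_unit` is
  the feature change produced per unit of relative carrier-power change.
  The per-trial realized depth (with its ±15 % jitter) is recorded in the
  ground truth.
* **The ERD feasibility bound.** Desynchronization can at most abolish
  the carrier: gains clip at zero, so a band can lose no more power than
  its oscillatory fraction contributes. With the default
  `carrier_snr = 4` the reachable ERD depth is roughly 1 baseline SD for
  alpha (3 populated bins) and 1.7–1.8 for beta; ERS is unbounded. Gains
  that clip are recorded at their realized (clipped) depth. This is a
  real physical constraint, not an artifact: a rhythm cannot desynchronize
  below zero power.

Regions listed in `noise_floor_per_region` (insula and white matter by
default, cutoff 50 Hz) drop planted modulation in bands starting at or
above the cutoff, emulating the region-dependent power cutoff seen on
such contacts; this is what lets tests reproduce an "alpha-only" insular
modulation profile. Imagined trials scale all planted depths by
`imagined_scale` (default 0.5) and are centred on the cue plus the mean
executed reaction latency.

What the generator deliberately does *not* emulate: volume conduction and
inter-channel correlation (channels are independent, which is why the
common average reference is optional in `session_features()` — on
independent synthetic channels CAR only mixes signals), epileptiform
activity, artifacts beyond an optional stationary 60 Hz line, and
non-stationary background drift. Passing tests therefore demonstrate the
statistical machinery, not robustness to clinical-grade artifacts.

## Preprocessing

The common average reference groups contacts by (shaft, region) — the
grouping is reported per region, and a depth electrode passes through
several structures — subtracting the group mean of non-noisy channels
from every group member. A single-channel group self-references to zero
(the arithmetic consequence of mean subtraction), which the function
warns about; montages should provide at least two usable contacts per
group. Force onsets are detected as the first time force exceeds 10 % of
the trial's target and stays above it for 200 ms, a rule robust to the
overshoot behaviour of real force matching. Imagined trials receive
surrogate onsets at cue + mean executed latency, per grasp. All event
times are seconds from recording start; windows are half-open `[t0, t1)`
and events snap to the nearest frame at or before them.

## Spectral features

The short-time Fourier transform uses a 512 ms Hann window stepped every
50 ms. FFT bins are pooled into 1 Hz intervals by the interval containing
each bin's centre frequency. At 512 ms the native resolution is ~2 Hz, so
some 1 Hz intervals are empty; they are excluded from band means. Setting
`zero_pad = TRUE` pads each frame to 1 s, making every interval exactly
one bin (the alternative reading of "1 Hz bins"); the default is the
honest unpadded grid, and both produce identical band features up to the
bin bookkeeping. Each 1 Hz track is z-scored per channel using the
population SD over a normalization epoch — the whole block by default,
or explicit windows (e.g. pre-cue rest) via `norm_windows`. Band features
are unweighted means of member-bin z-scores over six bands (0–6, 6–12,
12–30, 30–50, 70–110, 130–170 Hz; the gaps avoid 60 Hz and its
harmonics). The seventh feature, the local motor potential (LMP), is the
raw trace smoothed by a 2nd-order Savitzky–Golay filter over 250 ms,
sampled at frame centres and z-scored like the rest, so all seven
features share one 50 ms time base.

## Modulation statistics

For each channel × feature, the trial-averaged z-trace is scanned over
the response window (−1 to 0 s before force onset; 0–2 s after the cue
for imagined trials) for the frame of maximum absolute deviation from the
baseline mean (−3 to −1 s). Per-trial values at that frame are compared
against per-trial baseline means with a Welch two-sample t-test at
p < 0.002. Choices made where the procedure is ambiguous: the peak frame
is chosen on the *trial-averaged* trace (per-trial maxima would inflate
the t-statistic much more); baseline frames are averaged per trial rather
than pooled (pooling underestimates the baseline SE because frames within
a trial are correlated); the Welch variant is used because response and
baseline variances genuinely differ.

Two depth measures are reported. `depth` is the raw change in the mean
bin z-score, the quantity conventionally plotted. `depth_norm` rescales
it by the pooled baseline-frame SD of the band feature; this is the unit
in which the generator plants depths, and it is invariant to the choice
of z-normalization epoch (both numerator and denominator scale with the
per-bin SDs), so ground-truth comparisons use it.

**Known limitation — the scanned maximum.** Testing a maximum selected
over ~21 partially correlated frames with a nominal-level t-test is
anticonservative. With the response frame fixed a priori the test is
exactly calibrated, but the scan raises the null flag rate at p < 0.002
to roughly 2 % (the acceptance script measures this as
`modulation_null_flag_rate` on ~1000 simulated null channel × band
pairs). The threshold is therefore conservative relative to 0.05-level
testing but not relative to its nominal 0.002; a max-t permutation
correction would calibrate it exactly at the cost of changing the test.
The same selection biases |depth| upward by ~0.2 baseline SD in single
datasets, which averages out across seeds.

## Classification

Trial features are window means: −400 to +400 ms around force onset for
force trials, and an equal-width window centred 1 s into the rest period
(600–1400 ms after force offset) for rest rows, late enough for channels
to return to resting levels. Rest rows are subsampled to match each force
class so priors are flat. Two problems are posed: rest vs force (all
levels pooled) and rest vs light vs hard (lowest and highest levels;
intermediate levels are dropped in the three-state problem).

The classifier is an RBF-kernel SVM inside two-stage cross-validation:
stratified outer folds measure generalization; hyperparameters
`C ∈ 2^{-5..15}` and kernel width `δ ∈ 2^{-15..3}` (powers of 4,
libSVM-style, since no grid is canonical) are tuned by stratified inner
CV on each outer-training partition; standardization is refit inside
every training split; duplicated rows are forced into one fold. The
whole procedure is repeated 10 times on fresh partitions and accuracies
averaged. Sequential forward selection, when enabled, runs entirely
within outer-training data: (C, δ) are tuned once per outer fold on all
features and held fixed while features are added greedily; a candidate is
accepted only if its mean inner-CV improvement exceeds one standard error
of the paired per-fold differences (a concrete reading of "not
significantly better", which is otherwise unquantified); ties break to
the lowest feature index. Tuning (C, δ) per candidate subset would be
combinatorially infeasible and is the one place the implementation
resolves the procedure's ambiguity in favour of tractability.

Chance levels come from label permutations of the full pipeline
(97.5th percentile of the permuted-accuracy distribution by default, the
one-sided 95th percentile being selectable); above-chance testing uses
the exact binomial tail with n = number of unique trials (not trials ×
repeats, which would inflate n); and the set of classification tests is
corrected with Benjamini–Hochberg FDR at 5 %. Three-state results are
tested against both 1/3 and the stricter 1/2 reference.

## Problem sizes and numerical conventions

Simulation-based tests and the acceptance script run at 500 Hz sampling
(still beyond twice the highest band edge, with identical STFT geometry
in seconds) with 1–3 blocks of 15 trials and, where noted, 5 seeds; the
config default remains 2 kHz. Envelope calibration uses up to 300 rest
frames. Zero-variance z-score tracks are emitted as zeros with a
warning; epochs falling outside a recording are dropped and counted;
degenerate constant t-test inputs map to p = 0 (separated) or p = 1
(identical). All randomness flows from explicit seeds: the generator
seeds everything from `sim_config(seed=)`, CV repeat r uses
`seed + r`, and each outer fold re-seeds locally so that fold-level
results are reproducible in isolation.

## Limitations

Beyond the scanned-maximum calibration noted above: the generator's
channels are independent, so the common average reference — faithful to
clinical practice — mixes planted signals between the (typically two)
contacts of a synthetic group and halves measured depths;
ground-truth-comparison workflows therefore disable it. Force levels
share one planted depth, so the three-state problem is driven by the
rest/force contrast, consistent with force levels being hard to separate
cortically. The printed modulation tables will occasionally flag an
unplanted channel × band; at ~2 % per pair this is expected behaviour of
the procedure, not a simulation defect.
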