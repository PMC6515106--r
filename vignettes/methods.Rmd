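---
title: "Smart annotation of cycle phases: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smart annotation of cycle phases: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cyclephase` labels per-foot cycle phases — swing (foot in the air) and
stance (foot on the ground) — in recordings of cyclic activities from
shoe-mounted IMUs and pressure insoles. Three annotation engines are
provided: pressure edge detection, a semi-supervised hierarchical HMM, and
unsupervised cycle detectors for phase-less activities (cycling). Their
purpose is not autonomous recognition but *smart annotation*: proposing a
segmentation a human corrects, with the cost quantified by event-based
metrics under a 50 ms tolerance.

# Label model

A `LabelTrack` is an ordered list of non-overlapping, half-open segments
`[start_s, end_s)` carrying `(activity, phase)`. Conventions:

* Rest (standing, weight shifts) is **background**: any instant not covered
  by a segment is rest. This makes boundary counting comparable across
  engines — an engine that says nothing produces no boundaries, not a wall
  of rest segments. Sit is an explicit labeled activity.
* A **bout** — a maximal contiguous run of one cyclic activity — begins when
  the foot first leaves the ground and ends at its final ground contact:
  `swing, stance, ..., stance, swing`. So a bout of *n* cycles has *n*
  swings and *n − 1* stances; the surrounding ground contact belongs to
  rest. A single stance *separating two adjacent bouts of different
  activities* is permitted at transitions.
* Cycling carries no phases (the insole barely unloads on a pedal); only
  whole cycles, delimited anchor-to-anchor at the dominant GZ peak, phase
  `none`.
* Boundaries are the segmentation points: every segment start/end, shared
  endpoints de-duplicated. A contiguous *n*-segment track has *n + 1*
  boundaries.

# Pressure edge detection

Each of the five pressure channels is min-max normalized to [0, 1] and
low-pass filtered (4th-order Butterworth, forward-backward, 15 Hz default;
zero-phase so edge timing is unbiased). Events are the local extrema of the
first difference exceeding `min_strength` (default 8 s⁻¹): positive = the
foot loading, negative = unloading. The published description of the
aggregation is only "empirically found rules", so the rules here are a
documented reconstruction, all exposed in configuration:

1. same-polarity events within 100 ms form a cluster; the contact start is
   the **earliest rising** event (the heel loads first), the contact end the
   **latest falling** event (the toe unloads last);
2. alternation is enforced by keeping the stronger of two same-polarity
   neighbors; unpaired leading falls / trailing rises are dropped;
3. contacts shorter than 80 ms are discarded, gaps shorter than 80 ms merged.

Gaps between ground contacts are swings; a contact is a stance when it lies
between two swings and is not mostly covered by the rest mask. The
`min_strength` default separates genuine loading ramps (> 20 s⁻¹ after
filtering, on the synthetic generator) from filter step-response ringing
(< 5 s⁻¹); it was chosen once from that measured bimodal gap.

# Hierarchical HMM

**Architecture.** The hierarchy activities → phases → internal states is
flattened into one HMM with a block-structured transition mask. Cyclic
activities contribute two blocks (swing, stance) of 4 internal states —
enough to express the sub-phases of gait; simple activities (rest, sit)
contribute one block of 3 states (initiation, steady state, termination);
cycling one block of 4. Within a block transitions are left-right
(self-loop + forward, final state may self-loop); the final state of every
block connects to the entry state of every block. Allowed transitions start
uniform; structural zeros are never touched by training.

**Features.** Per 70 ms window stepped every 5 ms, per channel (GZ, AX):
variance, the three coefficients of a least-squares quadratic fit over
window-local time (centered for conditioning), and the raw sample at the
window center — then z-scored per subject over the whole recording. The
70 ms window is a deliberate reading of an implausible "70 s" in the source
description: phases average ~0.5 s, and a 70 s window could not segment
them. Variance is the population (divide-by-*n*) form, consistent with the
maximum-likelihood Gaussian updates.

**Semi-supervised training.** Labels are trusted at the block level only:
each frame's admissible states are those of its labeled activity + phase
(background frames are rest); the internal alignment is unsupervised.
Emissions are initialized by splitting every labeled occurrence into equal
consecutive parts, one per internal state ("linear initialization"), and
fitting a diagonal-covariance Gaussian (optionally a mixture, 10 EM
iterations) per state. Training is Viterbi re-estimation (segmental
k-means): best constrained path, then ML updates of transitions and
Gaussians. This was chosen over full Baum–Welch for determinism and speed;
it converges to a fixed point in well under the nominal 100 iterations, so
iterations after the alignment stops changing are short-circuited and the
likelihood history padded with the fixed-point value — bit-identical to
running them. The constrained log-likelihood is non-decreasing (tolerance
10⁻⁶ per frame in tests).

**Prediction.** Viterbi over the full state space, with states of
activities not allowed by the enclosing protocol task window scored
impossible (rest is always admissible). The decoded path is collapsed into
segments, post-processed, and rest discarded as background.

**Iterative protocol.** Batch 1 is labeled by edge detection and (in the
synthetic study, where corrected labels equal ground truth) trains the first
model; each later batch is predicted by the previous model, scored, added to
the training corpus, and the model retrained warm-started. Every
intermediate model is also scored on the final batch as a fixed holdout,
separating model improvement from batch difficulty.

# Cycle detectors

**Peak detection (PD).** Local maxima of the max-abs-normalized GZ at least
0.5 high, accepted greedily in descending height (earlier wins ties) with a
400 ms minimum spacing — standard `findpeaks` semantics. In the pipeline the
GZ channel is lightly smoothed (10 Hz zero-phase low-pass, configurable)
before normalization so anchors sit on the motion peak rather than a noise
spike.

**Local cyclicity estimation (LCE).** The published method is external and
only sketched; this is a documented reconstruction. A sliding window is
scored, for each candidate period *p* with 1/*p* in 0.5–6 Hz, by the
normalized autocorrelation at lag *p* over a ±2*p* window; a region is
locally cyclic when the best score exceeds `0.5 × noise_threshold` (default
threshold 1.0, i.e., autocorrelation 0.5 — white noise stays well below,
clean periodicity well above). Anchors are then the GZ maxima within
accepted regions, spaced at least 0.7 of the estimated period.

# Rest detection and synchronization

The rest mask thresholds the windowed mean energy of the mean-removed,
max-abs-normalized motion channels. Window 0.3 s and threshold 0.016 were
calibrated **once** on the generator defaults (≥ 95% frame agreement with
ground-truth rest across seeds) and stored in configuration; the source
method states only that the threshold was found empirically.

Insole-to-IMU synchronization resamples the insole accelerometer by every
ratio in 1.4–3.3 at 0.001 resolution (linear interpolation — the simplest
method consistent with that grid), cross-correlates against the shoe IMU
axis via FFT, and returns the (ratio, lag) with maximal normalized
correlation; ties break toward smaller lag, then smaller ratio. A practical
identifiability bound: a ratio error δ only shifts the alignment by
`T·δ/ratio` seconds over an overlap of `T`, so resolving 0.001 at ratio ~3
needs roughly `3/(0.001·rate)` seconds — about 15 s at 200 Hz. Tests use
16 s signals for that reason.

# Post-processing and outliers

Two rules run between prediction and correction: equal-labeled contiguous
neighbors are merged, and a bout-leading/trailing stance is relabeled rest
(removed, as rest is background) unless it is a transition separator. Both
are idempotent; relabeling (not deleting time) preserves coverage. Outlier
flagging computes per-activity cycle times and swing fractions and flags
cycles beyond `k` standard deviations (default 3); `k = 0` is the degenerate
flag-everything limit; labels are never modified.

# The synthetic world

The generator emulates exactly the features the detectors key on, with
defaults chosen once as a realistic stated world:

* stride times 0.55–1.15 s decreasing from walking to jogging to running;
  swing fractions ~40% (walk, stairs, hop) to ~60% (skip, side-step, jump);
  stride-time CV 5%; per-subject jitter (±10% stride, ±0.03 swing fraction,
  ±15% amplitude) emulating inter-subject style variety;
* GZ: one raised-cosine pulse per swing peaking at mid-swing, plus a
  negative stance "roll-over" rotation at 35% amplitude — the physical
  heel-to-toe pitch rotation, and what keeps stance distinguishable from
  standing rest at any window length;
* AX: gravity baseline, a decaying-oscillation impact at every ground
  contact;
* pressure: loaded whenever the foot is on the ground (stance *and*
  standing rest — as on a physical insole), 30 ms ramps staggered 10 ms
  heel-to-toe, so bout starts/ends are observable as unloading/loading
  edges;
* insole accelerometer: the clean AX resampled by the true ratio
  (default 2.0) and delayed (default 0.3 s), plus independent noise;
* additive Gaussian noise, default sd 0.1 of a unit GZ peak — visible in
  plots, non-trivial for the detectors, and not crippling.

What a green test establishes: that each algorithm recovers the structure
it was designed to key on, at calibrated thresholds, under this noise
model. What it does not establish: performance on real signals with
sensor drift, soft-tissue artifacts, mislabeled protocol timing,
individual pathology, or activity styles outside the template family. The
generator has no biomechanical model; amplitudes are in arbitrary units.

# Numerical choices

* Log-space throughout; disallowed states/transitions use −10³⁰ rather than
  −∞ so sums stay finite; emission log-densities floored at −10¹⁰.
* Emission variance floor 10⁻³ on z-scored features. A floor of 10⁻⁶ was
  tried first and rejected: with zero observation noise, rest states
  collapse to near point masses whose astronomical densities destabilize
  boundary placement (visible as spurious stance segments spanning rest
  gaps). 10⁻³ is still three orders of magnitude below the unit feature
  variance.
* Viterbi ties break toward the lowest state index; PD ties toward the
  earlier peak; sync ties toward smaller lag then smaller ratio.
* Degenerate inputs error loudly (all-zero channel normalization, constant
  sync signals, over-long windows) or warn and continue (zero-variance
  feature columns, empty emission states seeded from the global
  distribution, too few cycles for outlier statistics).

# Open design points, resolved

* "First three coefficients of the second-order polynomial fit" is read as
  all three quadratic coefficients; "the raw data itself" as the window
  center sample (earlier of the two for even windows).
* The four GMM "centers per phase" are realized as one Gaussian per internal
  state by default (`emission_components` config switches to per-state
  mixtures).
* Whether training "iterations" are EM epochs or realignment rounds is
  config (`training mode` fixed to Viterbi realignment here; the iteration
  count is honored either way).
* Boundary identity in evaluation is time-only (the definition mentions
  only the segmentation point); a strict mode additionally requiring label
  agreement exists in configuration. Spans labeled `unknown` in the
  reference are excluded from both sides of the match.
* Direction-change strides at bout edges are a human-judgment exclusion in
  the source labeling conventions and are not automated.

# Known limitations

* The hierarchical HMM treats feet independently; no bilateral coupling.
* LCE is a reconstruction in outline; its noise threshold is interpreted as
  a score multiplier, not whatever the original implementation quantified.
* The edge-rule set reconstructs unpublished heuristics; on real insoles
  with drift (the known failure mode of half the original recordings) it
  would need recalibration or the HMM path.
* Effort can exceed 1 by construction (false positives are unbounded); no
  clamping is applied anywhere.
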