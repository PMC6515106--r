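# cyclephase

Smart annotation of cycle phases in wearable-sensor recordings of cyclic
human activities (walking, jogging, running, jumping, cycling, ...).

## The problem

Cycle-level analysis of human movement — step counts, gait phases, stride
timing — needs datasets where every swing (foot off the ground) and stance
(foot on the ground) is labeled per foot. Manually placing those labels for
hours of recordings is prohibitively expensive. *Smart annotation* flips the
task: algorithms propose the segmentation, and a human only corrects it. The
cost is then measured as **labeling effort**,

```
effort = (FP + FN) / (TP + FN)
```

the fraction of segmentation boundaries that must be added or deleted, where
a predicted boundary counts as a true positive if it falls within 50 ms of a
reference boundary (one-to-one matching). The companion metrics are
`F1 = 2TP/(2TP+FP+FN)`, miss rate `MR = FN/(TP+FN)` and false discovery rate
`FDR = FP/(TP+FP)`.

`cyclephase` implements the full pipeline for shoe-mounted inertial sensors
(gyroscope sagittal axis GZ, accelerometer axial axis AX, 200 Hz) and
5-channel pressure insoles (100 Hz):

* **datamodel / io** — time series, per-foot label tracks (half-open
  segments with activity + swing/stance phase), protocol task windows,
  boundary extraction, plain-CSV/JSON persistence.
* **synthio** — a synthetic-subject generator with ground truth: raised-
  cosine mid-swing GZ pulses, stance roll-over rotation, heel-to-toe
  staggered pressure ramps, activity bouts separated by standing rest, and
  an insole accelerometer on a resampled (ratio 1.4–3.3) and delayed clock.
* **preprocess** — max-abs and per-person (z-score) normalization, a
  zero-phase Butterworth low-pass, an energy-threshold rest mask, and
  insole-to-IMU synchronization by cross-correlation over a resampling-ratio
  grid at 0.001 resolution.
* **edge_detect** — stance onsets/ends from the positive/negative peaks of
  the derivative of the filtered, normalized pressure channels, aggregated
  across channels with empirical pairing rules.
* **features / hhmm** — windowed features (variance, quadratic-fit
  coefficients, raw center sample; 70 ms windows, 5 ms steps) feeding a
  hierarchical HMM: activities → phases → left-right chains of internal
  states (4 per phase, 3 per simple activity), Gaussian emissions with
  diagonal covariance, semi-supervised Viterbi training (labels pin the
  block, alignment is learned), task-restricted decoding, and the iterative
  batch protocol (train on corrected batches 1..k, predict batch k+1).
* **cycledet** — unsupervised cycle anchors for phase-less activities:
  peak detection (min distance 400 ms, min height 0.5 on normalized GZ) and
  a local cyclicity estimator (autocorrelation over candidate periods,
  0.5–6 Hz).
* **postprocess** — label rules (merge equal neighbors; bouts start/end
  with swing) and statistical outlier flagging of cycles.
* **evaluate / pipeline** — tolerance-window boundary matching, the four
  metrics, per-activity breakdowns, and the end-to-end iterative study.

## Worked example

```r
library(cyclephase)

sub <- generate_subject(subject_scenario(seed = 42))  # walk, jog, run bouts
res <- run_annotation(sub, "edge")                    # pressure edge detection
res$reports$left
#> <MetricsReport> F1 = 1.000, MR = 0.000, FDR = 0.000, effort = 0.000
```

At the default noise level the staggered pressure ramps place every stance
onset/end within the 50 ms tolerance, so no reference boundary needs manual
correction (effort 0).

The iterative annotation study (batch 1 labeled by edge detection, batches
2–7 predicted by the hierarchical HMM retrained on everything corrected so
far, every model also scored on the final batch as a fixed holdout):

```r
st <- run_iterative_study(seed = 1)   # 7 batches x 3 synthetic subjects
print(st)
#> <IterativeStudy>
#>           stage     effort        f1
#>     batch1_edge 0.00000000 1.0000000
#>     batch2_hhmm 0.07638889 0.9638462
#>     batch3_hhmm 0.00000000 1.0000000
#>     batch4_hhmm 0.01388889 0.9930556
#>     batch5_hhmm 0.02083333 0.9897251
#>     batch6_hhmm 0.04861111 0.9759070
#>     batch7_hhmm 0.03472222 0.9827806
#>  holdout_model1 0.06944444 0.9665169
#>  holdout_model2 0.02777778 0.9863889
#>  ...
```

Read: the first hHMM (trained on batch 1 only) needs ~7% of boundaries
corrected on unseen subjects; adding corrected batches brings the holdout
effort to ~3.5% with F1 ≈ 0.98. (Runtime: ~5 minutes.)

## Command line

```sh
Rscript inst/cli/cyclephase.R synth --subjects 2 --seed 7 --out data/
Rscript inst/cli/cyclephase.R edges --dir data --subject 1 --out pred.csv
Rscript inst/cli/cyclephase.R evaluate --pred pred.csv \
    --ref data/subject01/truth_left.csv --tolerance-ms 50
Rscript inst/cli/cyclephase.R study --batches 7 --batch-size 3 --seed 1 \
    --out study.json
```

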