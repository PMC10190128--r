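---
title: "Ladder-pulse cytometry with flowLadder: models, choices, limits"
author: "flowLadder authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ladder-pulse cytometry with flowLadder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowLadder)
```

## The measurement model

In a constrictional microchannel the cross-section (20 µm × 20 µm here) is
only marginally larger than a cell, so stained cells transit single file
through a fixed illuminated window of length $L$ along the flow axis. A cell
of diameter $d$ moving at constant velocity $v$ produces, on each detector
channel, a **ladder-shaped (trapezoidal) fluorescence pulse**:

* rise time $T_a = d/v$ while the cell enters the window,
* plateau time $T_s = (L - d)/v$ while it is fully inside,
* fall time $T_d = T_a$ on exit,
* plateau height $I_f$ proportional to the number of fluorophore-conjugated
  antibodies the cell carries.

Because a calibration solution of molar concentration $C$ flowing through
the same constriction fills exactly the same detection volume
$V = L \times A$ (cross-section $A$), its steady plateau anchors the
molecule scale: $N = C \, V \, N_A$ molecules produce intensity
$I = \mathrm{slope} \cdot N + \mathrm{intercept}$, fitted by ordinary least
squares over a gradient dilution series (1:10, 1:50, 1:100, 1:500, 1:1000,
1:5000). This *volume equivalence* is what lets plateau voltages be read
back as **absolute per-cell copy numbers**,
$\hat{N} = (I_f - \mathrm{intercept}) / \mathrm{slope}$, for membrane and
intracellular targets alike — no calibration beads required. Inverting the
trapezoid geometry likewise recovers kinematics:
$v = L/(T_\mathrm{rise} + T_s)$ with
$T_\mathrm{rise} = (T_a + T_d)/2$, $d = v\,T_\mathrm{rise}$.

The package implements this chain end to end — synthetic trace generation,
pulse detection and ladder fitting, calibration and quantification, and
two cell-type classifiers — so that every stage can be exercised and
validated without instrument recordings.

## The synthetic generator

`samplePopulation()` + `renderTrace()` emulate the instrument:

* **Distributions.** Published population statistics come as mean ± SD
  only. All positive per-cell quantities (copy numbers, diameter, velocity)
  are drawn from *moment-matched lognormals* (`lognormalMoments()`): the
  lognormal has positive support and can match both moments exactly, where
  a zero-truncated normal would distort the mean badly for quantities such
  as the A549 velocity (SD 13.12 vs mean 16.32 µm/ms). A tight-SD
  lognormal degenerates smoothly to a point mass, which the tests use.
* **Window length** $L$ = 60 µm by default. The product of typical
  velocities and plateau durations implies a window minus diameter of
  roughly 44–49 µm for both cell lines, so 60 µm is geometrically
  consistent; it is configurable because the true chromium-window length is
  instrument-specific.
* **Forward gains** (mV per molecule) are arbitrary-but-consistent:
  defaults are anchored so the A549 copy-number means map to the typical
  plateau voltages of each channel (≈ 29.7, 80.5, 25.4 mV). Absolute PMT
  gain is unknowable and irrelevant: quantification is gain-invariant as
  long as cells and calibration solutions share the forward map. (The
  published plateau/copy pairs of the two cell lines are not mutually
  consistent on the PE channel — a single linear gain cannot produce both —
  so the A549 pair anchors the default.)
* **Noise** is i.i.d. Gaussian per raw sample, SD 1.5 mV by default;
  baseline 5 mV; sampling fixed at 500 kHz.
* **Arrival process**: homogeneous Poisson (default 100 cells/s) with
  arrivals pushed apart to at least `spacingFactor` (= 3) times the mean of
  the two neighbouring cells' *actual* transit times. Using each cell's own
  transit rather than the population expectation makes non-overlap a hard
  guarantee even for the slow velocity tail.
* **Spillover**: a unit-diagonal 3 × 3 mixing matrix applied to the
  per-channel amplitudes (identity by default; `spilloverPreset()` provides
  a synthetic non-identity matrix for exercising compensation).
* **Stock concentrations** for calibration runs (12 µM FITC, 40 nM PE,
  560 nM PerCP) are package defaults chosen so a 1:100 dilution sits near
  each channel's typical cell plateau.

What the generator does *not* emulate: photobleaching, detector
saturation, pressure fluctuations and velocity drift within a transit,
cell deformation in the constriction, autofluorescence structure, or
coincident doublets. Passing tests therefore demonstrate the correctness
of the analysis chain under the stated signal model, not robustness to
every artefact of real recordings.

## Pulse processing

1. **Median filter** (50 points, replicate-padded edges) suppresses PMT
   background spikes.
2. **Background statistics**: the detection threshold is
   mean + 3 × SD of the background. The estimate is two-pass: a provisional
   median + 3 × MAD threshold first excludes suprathreshold samples (robust
   even when pulses occupy >10 % of the recording), then mean and SD are
   computed over the remainder. A zero-variance channel degenerates to
   threshold = mean and is flagged.
3. **Detection**: maximal suprathreshold runs at least `minEventSamples`
   long (default 250 samples = 0.5 ms; filtered noise is correlated over
   the 50-sample window, so much shorter runs can be noise, while even the
   fastest plausible cells transit for ≈ 0.9 ms). Boundaries are then
   extended to the nearest background-mean crossing so the full trapezoid
   support is fitted, not only its suprathreshold core. Runs longer than
   3 × the median event duration are flagged as possible doublets and
   excluded only if their single-trapezoid fit residual exceeds
   max(5 × background SD, 0.2 mV): a merged doublet fits one trapezoid
   poorly, a slow single cell fits at noise level. Coordinates are 0-based,
   half-open sample intervals.
4. **Ladder fitting** (`fitLadder()`): least squares of a four-breakpoint
   trapezoid on the baseline-subtracted filtered segment. Breakpoints are
   initialized from the 10 %/90 % level crossings and refined by
   Nelder-Mead; the plateau level is profiled out in closed form, so the
   search is four-dimensional. Breakpoints are continuous-time, which gives
   sub-sample timing resolution; segments longer than ≈ 800 points are
   decimated for speed (the tests pin noiseless recovery at one sample
   period / 0.1 mV). Fitting happens on the *filtered* trace.
5. **Coincidence matching**: greedy nearest-center-time matching of
   triples across channels within 1 ms; unmatched events are dropped and
   counted.

## Quantification

Fitted plateau triples are spillover-compensated
(`solve(spillover) %*% I`), converted to copies through the per-channel
calibration lines, and timing is inverted to velocity/diameter using the
channel with the largest plateau (best SNR). Negative calibrated copies are
clipped to zero and flagged rather than dropped, keeping event counts
stable. A multiplicative `equivalenceFactor` (default 1) is exposed for the
cell-versus-solution geometry correction; the synthetic instrument needs
none. The diameter formula is a modeling choice — it is exactly the inverse
of the generator's forward trapezoid, and on real data it inherits the
constant-velocity assumption.

## Classification

* **Feedforward network** (`trainFFNN()`): one hidden layer, 50 logistic
  units by default, softmax output, on z-scored copy-number features
  (training-split statistics). Built on `nnet`, trained in 20-iteration
  stages with the best validation-accuracy checkpoint kept (patience 5).
* **LSTM** (`trainLSTM()`): six named stages — sequence input, LSTM
  (128 units by default), dropout (0.2), dense, softmax, class output — on
  pulses resampled to a fixed length (256 by default) by linear
  interpolation and z-scored per channel. Forward pass, backpropagation
  through time and the Adam optimizer (learning rate 0.001, batch 100) are
  implemented in package code with base matrix algebra; the gradients are
  verified against numerical differentiation in the test suite. Training
  stops early on validation accuracy; a non-finite loss aborts with a
  diagnostic.
* **Splitting**: stratified 70/15/15 with a per-class floor rule
  (`floor(0.7 n)`, `floor(0.15 n)`, remainder), seed-reproducible.
* `hyperparameterScreen()` trains one model per point of the batch-size ×
  learning-rate × hidden-width grid (defaults 10/100/1000 ×
  0.01/0.001/0.0001 × 64/128/256) with a shared seed and reports test
  accuracy and epochs-to-best per point.

The qualitative property the tests enforce: when class information lives in
pulse *shape* beyond the three plateaus, the LSTM outperforms the
plateau-feature network by a clear margin; when the plateaus are sufficient
statistics, the two agree. Real-recording accuracies cannot be reproduced
without the original data and are not targeted.

## Determinism and seeds

A single global seed is expanded into per-stage child seeds
(`childSeed()`, a small congruential mix kept inside the 32-bit range), so
stages are independently reproducible and the full pipeline is
byte-deterministic: identical configuration + seed give identical cell
record CSVs. Every output file carries a sidecar with the package version,
seed and an FNV-1a hash of the configuration.

## Numerical choices and degenerate inputs

* Even median windows are rounded up to odd; a window longer than the
  trace is an error.
* A zero-variance background yields threshold = mean (flagged), not NaN.
* Rectangle pulses (zero rise/fall) fit with $T_a, T_d$ at or below one
  sample period; zero-duration fits are flagged in kinematics.
* Lognormal moment matching requires strictly positive means and SDs.
* Cells with diameter ≥ window length are a geometry error at render time.
* Calibration refuses fewer than two distinct molecule counts or a
  non-positive slope; compensation refuses singular spillover matrices.

## Problem sizes used by the checks

The population-recovery checks run the full pipeline at n = 2000 cells per
condition (chunked 250 cells per rendered trace to bound memory), which
recovers the configured population means to well within 5 % at the default
SNR; classifier property checks use a few hundred to a few thousand
synthetic pulses with reduced sequence lengths and hidden widths. These
sizes are the package's validation choices: estimates sharpen as n grows,
and nothing in the implementation is specific to them.

## Known limitations

* The trapezoid model assumes constant velocity within a transit;
  acceleration inside the constriction would skew $T_a$ vs $T_d$ (an
  asymmetry factor exists in the generator but the fitter already allows
  asymmetric rise/fall).
* Overlapping cell pulses are screened, not deconvolved.
* Calibration assumes a linear detector; saturation is out of scope.
* The spillover preset is synthetic; real compensation matrices must be
  measured.
* Classifier hyperparameter defaults follow the published optimum (batch
  100, learning rate 0.001, 128 hidden units); they are sensible for
  10^4-scale datasets, not universal.
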