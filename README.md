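# flowLadder

Quantitative single-cell protein analysis for **constrictional-microchannel
fluorescent flow cytometry**, in R.

Conventional flow cytometry reports fluorescence intensities, not molecule
counts: bead-based calibration exists for membrane proteins but not for
intracellular ones. When cells transit a microchannel whose cross-section is
only marginally larger than the cell, each transit through the illuminated
window produces a **ladder-shaped (trapezoidal) pulse** per detector
channel, and a solution of known fluorophore concentration flowing through
the same constriction fills exactly the same detection volume. That *volume
equivalence* converts plateau voltages into absolute per-cell copy numbers
for membrane and intracellular targets alike.

flowLadder implements the full analysis chain for three-channel PMT traces
(FITC/β-actin, PE/EpCAM, PerCP/β-tubulin) sampled at 500 kHz:

* **Synthetic instrument** — seeded generator of ground-truth cells
  (moment-matched lognormal copy numbers, diameters, velocities) and
  rendered traces, plus gradient-dilution calibration runs, so the whole
  pipeline is testable without recordings.
* **Pulse processing** — 50-point median filter, robust two-pass
  background statistics with the mean + 3 σ event threshold, trapezoid
  ("ladder") least-squares fitting of `T_a`, `T_s`, `T_d`, `I_f`, and
  cross-channel coincidence matching.
* **Quantification** — per-channel calibration lines
  `I = slope·N + intercept` fitted over the 1:10 … 1:5000 dilution series,
  spillover compensation, copies `= (I_f − intercept)/slope`, and kinematic
  inversion `v = L/(T_rise + T_s)`, `d = v·T_rise` for velocity and
  diameter.
* **Classification** — a two-layer feedforward network (50 hidden units,
  via `nnet`) on the three copy-number features, and an LSTM sequence
  classifier (six stages, 128 hidden units, Adam, batch 100, learning rate
  0.001; implemented in package code with gradient-checked BPTT) on the raw
  fixed-length pulses, both with stratified 70/15/15 splits, plus a
  batch-size × learning-rate × hidden-width screening grid.

## Worked example

```r
library(flowLadder)
config <- readRunConfig(system.file("extdata", "demo_config.yaml",
                                    package = "flowLadder"))
res <- runPipeline(config, "demo_run")
```

```
[simulate] 2 populations x 120 cells (seed 1, config 0057c74e)
[detect] population A549
[detect] population CAL27
[detect] matched 120 + 120 cells
[quantify] 240 records (0 clipped, 0 flagged)
[classify] ffnn test accuracy 0.861
[classify] lstm test accuracy 0.861
```

Every simulated cell was detected, ladder-fitted and matched across the
three channels. The calibration stage recovered the PE channel's forward
map essentially exactly (the series is rendered noiselessly here):

```r
res$curves[[2]]
#> CalibrationCurve [PE]: I = 0.01438 mV/molecule x N + -4.88e-14 mV
#>   (R^2 = 1.000000, 6 points)
```

Population means of the quantified records land on the configured cell-type
moments — β-actin ~1.8 vs 2.7 × 10⁶ copies, EpCAM ~5.7 × 10³ vs
3.5 × 10⁴ copies for the A549-like vs CAL 27-like populations — and EpCAM
alone nearly separates the two types:

```r
aggregate(res$records[, c("copiesFitc", "copiesPe", "copiesPercp",
                          "diameterUm", "velocityUmPerMs")],
          list(population = res$records$population), mean)
#>   population copiesFitc copiesPe copiesPercp diameterUm velocityUmPerMs
#> 1       A549    1797855     5743       75632      14.77            15.1
#> 2      CAL27    2679782    35218       84040      16.92            17.1

res$reports$ffnn
#> ClassifierReport [ffnn]
#>   accuracy: train 0.935 | validation 0.917 | test 0.861 | overall 0.921
#>   test confusion matrix (rows = truth):
#>        prediction
#> truth   A549 CAL27
#>   A549    16     2
#>   CAL27    3    15
```

At this demo scale (240 cells) both classifiers sit near 0.86 test
accuracy; accuracy climbs with the number of cells. Records export to FCS
3.1 with `writeFCS(res$records, "cells.fcs")`, and a thin CLI wraps the
same stages:

```sh
Rscript inst/scripts/flowladder.R run-all --config inst/extdata/demo_config.yaml --out demo_run
```

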