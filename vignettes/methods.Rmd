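---
title: "Methods: simulation, classification and evaluation of calcium transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, classification and evaluation of calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific methods behind `cacti`: why per-frame
activity classification on movie patches is preferable to trace-based spike
inference in densely packed fields of view, how the ground-truthed simulator
is constructed, and how every component is evaluated.

## 1. The problem

In two-photon calcium imaging of densely packed tissue, somata overlap in the
imaged plane. A cell's extracted fluorescence trace is then contaminated by
its neighbours: when an overlapping neighbour fires, the shared pixels
brighten and the trace of the *inactive* cell shows a convincing rise — a
*fake transient*. Any method that sees only the 1-D trace cannot, even in
principle, tell this apart from real activity. `cacti` therefore classifies
activity directly from the movie: the classifier sees the spatial layout of
each fluorescence rise and can attribute it to the correct source.

A cell is defined as *active* during the rise time of a transient — from
onset to peak — and the classifier predicts, for every frame, the probability
that the cell is active.

## 2. Ground-truthed simulator

Real recordings lack per-frame ground truth, so the package generates movies
where the truth is known exactly (`simulate_movie()`):

* **Geometry.** A library of irregular convex-ish polygonal contours is
  sampled, each rasterized to a pixel mask with a nucleus region rendered at
  lower gain than the soma (`nucleus_gain = 0.6`). Cells are placed on a
  100×100 field so that each new cell overlaps 1–4 existing ones, mimicking
  dense packing.
* **Kinetics.** Each cell receives 2–16 transients per 1000 frames (at the
  reference 10 Hz sampling rate, 1.2–9.6 transients/min). A transient rises linearly over
  1–8 frames (100–800 ms) to a log-normal amplitude, then decays as
  `a * exp(-t / tau)` with `tau` uniform in 10–12 frames. Overlapping
  transients within a cell sum.
* **Pixel model.** Frame intensity is a static textured baseline plus each
  cell's trace painted over its mask, with overlap regions receiving the sum
  of contributions.
* **Noise.** I.i.d. Gaussian noise with variance `sigma2 = 0.1` is added to
  every pixel of every frame.

Ground truth (contours, per-cell transient intervals, noiseless traces) is
retained on the returned object and exported alongside the movie by
`export_ground_truth()`.

```{r simulate}
library(cacti)
movie <- simulate_movie(n_frames = 1000, n_cells = 16, seed = 1)
labels <- movie_labels(movie)
```

## 3. Patch pipeline

The classifier input for one cell and one 100-frame segment is a 25×25 crop
centred on the cell, split into three *streams* with pairwise disjoint pixel
support (`make_streams()`):

1. the target cell's own pixels,
2. pixels of cells overlapping the target,
3. everything else (neuropil).

The streams sum exactly to the raw crop; each is normalized by the crop's
99.9th percentile and clipped to [0, 1], identically across streams. This
hands the network the attribution problem explicitly: a rise present in
stream 2 but not stream 1 is a neighbour's event.

Movies are tiled by `temporal_segments()` with a stride of 10 frames.
Segments are classified (`classify_segment()`) as containing a real
transient, only fake transients, or neither, and `stratify()` resamples them
to a 60/30/10 composition, weighting fake-only segments five-fold in the loss
so the network is forced to study the hard cases. Scarce classes are
oversampled with lattice-exact spatial augmentations
(`augment_spatial()`: flips, 90° rotations, small translations). The
train/validation split is by cell (`split_train_validation()`), never by
segment, so no cell leaks across the split.

## 4. Classifier

`build_model()` + `cacti_train()` implement a three-branch network, one
branch per stream, entirely in base R (with sparse-matrix convolution
operators from `Matrix`):

* three 3×3 convolution blocks (swish activations, 2×2 max-pooling),
* temporal soft attention over the pooled feature sequence, scaled so that
  uniform attention is the identity,
* two stacked bidirectional LSTMs per branch (the second consumes the
  attention output concatenated with the first's output),
* a merge LSTM over the concatenated branch outputs and a per-frame sigmoid.

Training uses weighted binary cross-entropy, RMSprop, dropout 0.5, and
Glorot initialization; forget-gate biases start at 1. The fitting function
returns a classed `cacti_fit` object with the training history and the
selected (best-validation) epoch; `predict_movie()` tiles a movie and
averages overlapping segment predictions. A softmax variant of the same
architecture (`celltype_model_config()`) classifies whole cells into types
from one input sequence.

```{r train}
cfg <- activity_model_config(preset = "desk")
model <- build_model(cfg, seed = 2)
fit <- cacti_train(model, train_samples, val_samples, epochs = 10,
                   batch_size = 4, lr = 3e-3)
preds <- predict_movie(fit$model, movie)
```

## 5. Transient-level evaluation

Frame-wise scores reward trivia (most frames are silent), so evaluation is at
the transient level (`match_transients()`): a real transient counts as
detected iff any of its rise frames is predicted active (strictly above the
threshold); a predicted active run counts as true iff it intersects a real
rise. Sensitivity, precision and F1 follow (`metric_report()`), with NA — not
0 — when a denominator is empty. `rise_coverage()` reports the fraction of
rise frames recovered, and `compare_methods()` applies a paired two-sided
Wilcoxon signed-rank test across cells, refusing tiny or degenerate samples.

## 6. Overlap analysis and audit

`detect_false_transients()` provides simulator-independent ground truth for
the fake-transient problem: for each overlapping pair (sharing at least 15%
of the larger footprint), each putative transient's spatial profile (rise
frames minus onset frame) is correlated against both cells' *source
profiles* (their average transient image). A rise in cell B that correlates
≥ 0.7 with A's fingerprint and ≤ 0.2 with B's own is a false transient
attributed to A. `audit_classifier()` then checks the classifier against this
ground truth: a false transient is rejected iff no rise frame is predicted
active.

## 7. Reproducibility

Every stochastic step takes an explicit seed; `desk_benchmark()` chains
simulation → pipeline → training → evaluation → audit deterministically, and
every CLI stage (`inst/cli/cacti.R`) writes a manifest with the seed, config
hash and package versions needed to regenerate its outputs.
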