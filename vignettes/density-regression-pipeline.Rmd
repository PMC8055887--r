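---
title: "Cell detection and Ki-67/TILs scoring by density-map regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell detection and Ki-67/TILs scoring by density-map regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67cells)
```

## The problem

Grading breast tumors requires counting cells on Ki-67 stained biopsy
sections: the *Ki-67 proliferation index* is the fraction of tumor cells
whose nuclei take up the stain (immunopositive, brown under DAB) among all
tumor cells (the immunonegative rest counterstains hematoxylin blue), and
the *TILs score* is the fraction of tumor-infiltrating lymphocytes among all
counted cells. Both indices drive clinical cut-off categories (Ki-67:
below 16 % low, 16–30 % intermediate, above 30 % high; TILs: up to 10 % low,
to 40 % intermediate, from 40 % high). Counting thousands of touching,
variably sized nuclei per slide by hand is slow and error-prone; this
package implements an automated pipeline that goes from an RGB microscopy
tile to per-class cell-center coordinates and the two clinical scores.

Annotations are cell centers plus a class, not masks: segmentation-style
per-pixel labels are impractical for overlapping nuclei at this scale, and
bounding boxes fit poorly to small round objects. A center-pixel
classification target, however, punishes a 2-pixel miss as harshly as a
200-pixel miss, so the point labels are softened into per-class **density
maps**: each annotated center contributes a truncated isotropic Gaussian
bump to the channel of its class, and the network regresses the three
channels jointly.

## Density encoding

`encode_density()` places, for every annotated point, a Gaussian kernel with
standard deviation `sigma` (default 3 px — the nucleus scale at the
tile magnification), center value `peak_amplitude` (default 1), truncated on
a disk of `truncation_radius` sigmas (default 4, which discards well under
1e-3 of the mass). Design points that the encoding fixes explicitly:

* **Overlap**: same-class kernels add by default (`combine_mode = "sum"`),
  preserving total mass — channel mass divided by kernel mass recovers the
  cell count. `"max"` is available when amplitude-stable thresholds matter
  more than mass.
* **Borders**: kernels are clipped at the image edge and *not*
  renormalized; a network can only learn what the image shows, and a
  clipped target matches the clipped evidence.
* **Coordinates** are 0-based, `x` = column, `y` = row, stored as integers;
  kernels are evaluated at pixel centers.

## The network

The regression backend is a U-Net-like encoder–decoder whose working block
is the **residual dilated inception module (RDIM)**: two parallel paths — a
pair of plain 3×3 convolutions and a pair of 3×3 dilated convolutions with
dilation rate 4 (taps spaced 4 px apart, widening the field of view at no
parameter cost) — summed with a residual of the block input. In the encoder
the output width is twice the input width, so the residual duplicates the
input along channels; in the decoder a 1×1 convolution projects the input
instead. A two-layer stem precedes three encoder stages (2×2 max-pool, then
an encoder RDIM); the decoder has four RDIMs — one at the bottleneck, then
three interleaved with 2× nearest-neighbour upsampling and skip
connections (channel concatenation by default, addition available) — and a
head of three 1×1 convolutions ending in a linear activation, one output
channel per cell class. ReLU follows every other convolution (applied after
each RDIM's branch sum). With 256×256 input the output is a 256×256×3
density map; any size divisible by 8 works.

Per-stage channel widths are configuration, not constants
(`network_config()`); the defaults are a stem of 16 and encoder-RDIM input
widths (16, 32, 64). The tests and the bundled benchmark use a reduced
configuration (stem 8, widths 8/16/32, 64×64 tiles) sized for a single CPU.

### Training and a note on initialization

Training (`train_network()`) minimizes mean-squared error on the density
maps with Adam; the learning rate starts at 1e-4 and is multiplied by 0.1
every 10 epochs by default (`lr_schedule()`), and the per-patient 70/30
split helper (`split_by_patient()`) mirrors how such datasets are divided.

Density targets are sparse: almost all pixels are zero, so "predict zero
everywhere" is a strong attractor for MSE, and with plain He initialization
the escape from it was found to be slow and seed-dependent. Three
initialization choices make small-compute training escape it reliably, and
all are package defaults:

* the closing convolution of each RDIM branch starts **near zero**
  (N(0, 1e-3)), so a fresh module computes approximately its residual
  mapping and the network begins as a shallow, well-conditioned color model
  into which the branches grow (the zero-γ trick of residual-network
  practice, kept slightly non-zero so every path carries gradient from the
  first step);
* each decoder RDIM's 1×1 residual projection starts as a **partial
  identity** over its trailing input channels — the concatenated skip — so
  an untrained decoder forwards encoder features instead of randomly mixing
  them, and the head sees the stem's full-resolution features directly;
* the final linear readout starts near zero, so the untrained network
  predicts an almost-empty density map and early optimization grows signal
  rather than crushing feature amplitudes (amplitude-crushing is what kills
  ReLUs); ReLU convolutions also get a small positive bias (0.01) so narrow
  layers do not start dead.

Learning rates at or above 1e-3 reliably destroyed the deep model in our
probes (Adam's fixed-size steps inflate weights, activations saturate, the
ReLUs die); 1e-4 — the schedule's default — trains steadily. Gradients are
verified against central finite differences in the test suite.

## From density map to cell centers

`extract_centers()` runs, per channel:

1. **Threshold** at `T` (default 0.4 × the unit peak; values ≥ `T` become
   foreground — a fixed fraction of the peak survives amplitude rescaling).
2. **Euclidean distance transform** of the foreground.
3. **Negation** — the watershed floods minima, and region centers must be
   the deepest points.
4. **Priority-flood watershed** restricted to the foreground, seeded at the
   regional minima (plateau-aware). The queue discipline is deterministic:
   pixels are popped in `(value, row, col)` order and take the label of
   their lowest labeled neighbour, so output is bit-reproducible and ties
   at basin boundaries are resolved identically on every run.
5. One detection per basin at the basin's distance-transform argmax (ties
   broken by row, then column); basins smaller than `min_region_area`
   (default 4 px) are dropped as noise.

Overlapping cells whose thresholded blobs merge into one region are split
wherever the distance transform has two maxima — the watershed's purpose.
Connectivity is 8 by default (round nuclei, fewer spurious splits). The
test suite checks the watershed against an exhaustive level-by-level
flooding oracle on thousands of small reliefs.

## Evaluation

`match_detections()` scores a detection set against ground truth per class:
candidate pairs closer than `radius` (strict inequality; default 10 px at
the 256-px tile scale — the radius is configuration, since no canonical
value exists) are accepted greedily in ascending distance, each center used
at most once; if two detections fall inside the radius of one truth center,
only the closer one counts and the other becomes a false positive.
Precision, recall and F1 follow the usual definitions with 0/0 defined as 0
(and warned about) so batch evaluation stays total. Per-class values are
combined by support-weighted averaging — equivalently, TP/FP/FN are summed
over images before rates are computed (micro averaging within class).

Clinical scores use ratios of summed counts (`aggregate_patients()` sums a
patient's per-tile counts before dividing — a ratio of sums, not a mean of
ratios), then the cut-off rules above. The published TILs bands leave
(39, 40) uncovered; the package closes the gap as "intermediate below 40,
high at and above 40". RMSE between predicted and true score vectors is
reported per image by default and per patient as an option, since the
convention is ambiguous in the field.

## The synthetic generator, and what passing it means

`generate_image()` draws filled, randomly oriented ellipses in per-class
colors (DAB-brown, hematoxylin-blue, small dark lymphocytes) on a pale
background with Gaussian pixel noise, records every center exactly, and is
byte-deterministic given its seed. Placement uses rejection sampling (1000
retries, then an explicit packing error); a configurable fraction of cells
is deliberately placed to intersect an earlier cell, since touching nuclei
are the hard case the watershed exists for. Defaults mirror the published
dataset's structure: 256×256 tiles, about 69 cells in a 22/43/4 class mix,
per-patient grouping in `generate_dataset()`.

The generator emulates the *geometry and chromatics* of IHC tiles, not
their biology: no tissue texture, no staining-gradient artifacts, no
out-of-focus blur, no hue overlap between weakly stained classes. Passing
the bundled benchmark therefore demonstrates that the architecture,
gradients, post-processing and scoring compose correctly — it does not
certify performance on real slides, where class confusion (notably
lymphocyte vs immunonegative) dominates the error budget.

`run_synthetic_benchmark()` is the package's self-contained end-to-end
check: 300 easy 64×64 training tiles (high-contrast preset
`easy_synth_params()`: 2+2+2 non-overlapping cells, lymphocytes drawn
dark), 25 epochs of the reduced network at lr 1e-4, then the full pipeline
on 50 held-out tiles. Problem sizes were chosen so the whole run fits in
minutes on one CPU; at these settings the pipeline recovers essentially
every cell (per-class F1 ≈ 1), and truth scored against itself is exact by
construction. The real-dataset figures reported for this class of methods
(weighted F1 near 0.79 after long GPU training on 100k+ annotations) are
out of reach at desk scale and are not a target of the benchmark.

## Numerical choices and degenerate inputs

* Dilated convolution is centered cross-correlation with zero padding (the
  deep-learning convention); dilation 1 is ordinary convolution, and
  dilation *d* equals ordinary convolution with a zero-inflated kernel.
* Thresholding keeps equality (`value >= T`), following "remove what is
  below the threshold".
* A thresholded frame with *no* background would give unbounded distances;
  the transform caps them at the image diagonal.
* Empty annotation sets encode to all-zero maps; all-zero maps yield empty
  detection sets; empty detection sets score precision = recall = 0 with a
  warning rather than an error, while the scalar score functions
  (`ki67_index()`, `til_score()`) refuse empty denominators outright.
* Seeds: every stochastic step (generation, init, shuffling) derives from
  an explicit integer seed; derived seeds stay below 2^31.

## Limitations

* The exact channel widths of the published architecture are not available
  in machine-readable form; widths here are configuration, and parameter
  counts are checked against a closed form of this package's layer plan,
  not against the published total.
* Training is plain R plus compiled convolution kernels on one CPU;
  it is meant for the reduced configuration and small studies, not for
  full-resolution training runs.
* Non-overlapping prediction tiling only; acquisition overlap and
  detection deduplication across tile seams are out of scope.
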