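---
title: "Methods: snapshot-mosaic hyperspectral brain-tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snapshot-mosaic hyperspectral brain-tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsibrain)
```

## The problem

During resection of high-grade gliomas the margin between tumor and healthy
cortex is hard to see. Hyperspectral imaging (HSI) records a reflectance
spectrum at every pixel; with a snapshot mosaic camera, all 25 bands
(655-975 nm, laid out as repeating 5x5 filter blocks on the sensor) are
captured in one exposure, fast enough for intraoperative use. Supervised
classifiers trained on surgeon-labeled pixels then paint the surgical field
as a five-class map: healthy tissue, tumor, venous blood, arterial blood and
dura mater.

This package implements the full processing chain — synthetic scene
generation, pre-processing, spectral-angle labeling, three classifiers,
nested cross-validation and metrics — so that every stage is testable
without access to patient data, which are private.

## The phantom generator

Real in-vivo captures cannot be redistributed, so `make_signature_library()`
and `make_phantom_scene()` produce scenes with known ground truth that
reproduce the *structural* difficulties of the clinical data:

* **Class similarity structure.** Healthy and tumor mean spectra nearly
  coincide across the measured range; venous and arterial blood are mutually
  similar but follow a different trend; dura mater is the most distinct
  class. The tumor signature is `healthy + separation * p` with `p` a smooth
  perturbation orthogonal to the healthy vector and `||p|| = ||healthy||`,
  so the spectral angle between healthy and tumor is exactly
  `atan(separation)` — strictly monotone in the separation dial, which the
  tests exploit. The library constructor rejects parameterizations that
  break the similarity ordering.
* **Class imbalance.** Default pixel fractions (healthy 0.32, tumor 0.17,
  venous 0.035, arterial 0.014, dura 0.17 of the image; the rest unlabeled)
  mirror the labeled-pixel shares of the published per-patient counts
  (`tissue_pixel_counts()`): arterial blood is rare, healthy and tumor
  abundant.
* **Region geometry.** Labeled regions are thresholded smoothed Gaussian
  random fields; classes claim their pixel budget sequentially in class-id
  order, so requested counts are met exactly and overlaps resolve
  deterministically. `blob_scale` (default 0.2 of the short side) sets the
  smoothing length: the default yields a few large coherent regions per
  class, like hand-drawn ground-truth maps. This matters for the patch-based
  classifier: pixels within a patch radius of a region boundary have mixed
  spatial context, so fragmented phantoms understate what the method does on
  realistically chunky anatomy.
* **Illumination.** The brain's curved surface puts pixels at different
  heights, so collected intensity varies smoothly across the field. A
  low-order polynomial dome with `max/min - 1 = illum_amplitude`
  (default 0.3) multiplies all reflectances.
* **Sensor model.** `render_capture()` maps reflectance to radiance
  (`rho * (white - dark) + dark`), mixes each pixel's 25-band vector with a
  crosstalk matrix, and tiles the bands into the 5x5 mosaic.
  The crosstalk matrix has exponentially decaying off-diagonals
  (`leak^|i-j|`), column-normalised so the calibration denominator is
  exactly flat — which makes the noise-free
  generate-then-preprocess round trip exact to machine precision, the
  anchor oracle of the test suite. Gaussian noise (`noise_sd`, reflectance
  units, default 0.02) is added in the scene cube; because radiance is
  affine in reflectance this is equivalent to radiance-domain noise up to
  the fixed white-dark scale.

What the generator does **not** emulate: wavelength-resolved chromophore
optics, specular glare, instruments in the field, spatially correlated
sensor noise, or registration error. Passing tests therefore demonstrate
correctness of the algorithms, not clinical performance.

## Pre-processing chain

Four steps, each a separate tested function:

1. `demosaic()` — rearranges the `H x W` sensor frame into an
   `H/5 x W/5 x 25` cube; no interpolation. The band position inside the
   5x5 block is a convention the camera vendor does not publish; the
   row-major default is overridable (`default_band_layout()`) and recorded
   in cube metadata. A 2045 x 1085 active area gives a 409 x 217 x 25 cube
   (2045/5 = 409; a published figure of "419" rows is inconsistent with
   that arithmetic and is treated as a typo).
2. `calibrate()` — `(I - D) / (W - D)` per band against white/dark
   reference frames, removing the illuminant spectrum and sensor offset.
   Denominator entries below `eps = 1e-6` (white and dark references can
   coincide on dead regions) are clamped, counted, and reported in a
   warning rather than silently producing infinities.
3. `spectral_correct()` — right-multiplies each pixel's row vector by the
   25 x 25 spectral correction matrix (each row holds one virtual band's
   coefficients), undoing filter crosstalk.
4. `rms_normalize()` — divides each spectrum by its root-mean-square over
   bands, discarding brightness while preserving spectral shape; this is
   what makes pixels of one tissue comparable across the curved surface.
   All-zero pixels cannot be normalized: they propagate as zeros and are
   flagged as degenerate instead of becoming NaN.

## Ground-truth labeling

`label_by_threshold()` reproduces the interactive tool semantics: the
annotator picks a seed pixel, and every pixel of the image whose spectral
angle (`sam()`) to that pixel's spectrum falls below a tolerance receives
the class. Thresholding is global (no connectivity constraint), the
reference is the single seed pixel, and later actions overwrite earlier
labels; every action is appended to a provenance log whose replay
reproduces the map exactly. Class-count summaries report percentages
rounded half-up to two decimals; note that a handful of cells in the
published per-patient table are printed one unit in the last digit away
from this rule (its own rounding is internally inconsistent), and the
published text total of 1256 arterial pixels disagrees with the table's
column sum of 1252 — the per-row counts are taken as authoritative.

## Classifiers

* **Linear SVM** (`e1071`, C = 1, no feature scaling — inputs are already
  RMS-normalized) and **random forest** (`ranger`, 100 trees, one thread,
  seeded) operate on single-pixel spectra.
* **3D CNN** operates on 9 x 9 x 25 patches centered on the target pixel,
  mirror-padded at image borders so no labeled pixel is dropped. Two
  blocks of (3D valid convolution -> batch normalization -> spectral-only
  max pooling -> ReLU), then two fully connected layers with dropout 0.3
  and 0.5, then a softmax output; trained with AdamW (learning rate 5e-5,
  weight decay 0.01) on fixed mini-batches of 1024, passing twice over the
  batch sequence. Published figures do not give kernel sizes or fully
  connected widths; this implementation uses 3x3x5 kernels
  (spatial x spatial x spectral), pooling kernel (1,1,2), and configurable
  widths. The shape trace for a 9x9x25 patch is
  9x9x25 -> 7x7x21 -> 7x7x10 -> 5x5x6 -> 5x5x3 -> flatten.
  Dropout rates are read as 0.3/0.5 (values of 0.003/0.005 would be
  practically inert). The loss is categorical cross-entropy, implied by the
  softmax output. No class weighting is applied.

Two numerical choices in the CNN trainer deserve explanation, because the
training budget — a few dozen optimizer steps at a 5e-5 learning rate — is
tiny by deep-learning standards:

* **Zero-initialised classifier head with a fixed output multiplier.**
  AdamW moves every weight by roughly the learning rate per step,
  irrespective of gradient magnitude. With a conventionally initialised
  head the logits start at order one and cannot move measurably within the
  budget; training would be a no-op. The head is therefore initialised at
  zero (so the initial class distribution is exactly uniform) and its
  logits are multiplied by a fixed constant, `4 / (lr * H2)` where `H2` is
  the width feeding the head — a maximal-update-style parametrization under
  which one optimizer step moves the logits by order one. The multiplier is
  a reparametrization, not an optimizer change: learning rate, weight
  decay, batch size and pass count are exactly the published settings.
* **Batch-norm inference statistics** use a cumulative average of the batch
  statistics seen during training rather than a fixed-momentum running
  estimate, which after so few steps would still be dominated by its
  initialization.

The convolution is implemented as im2col gathers feeding BLAS matrix
products, with activations kept channel-fastest so no transposes occur in
the hot path; gradients are verified against central finite differences in
the test suite.

## Model selection and experiments

`stratified_kfold()` shuffles each class independently and deals samples
round-robin into 5 folds (per-class fold counts differ by at most one).
`double_cv()` nests two such loops: each outer test fold is isolated while
the remaining 80% is re-stratified; five inner models (4 calibration folds,
1 validation fold) compete on validation overall accuracy, the winner
predicts the outer test fold, and the best outer iteration is selected —
exactly 25 models per run. Ties break to the lowest fold index and the
selected model is used as-is, without refitting.

`run_experiment_a()` (intra-patient) adds the third loop: each image is
stratified into 5 folds, and for each fold-grouping (the same fold index
across all images) the other four folds of every image (80% per image) feed
a double cross-validation, with the held-out 20% union scoring the
grouping. Whether published per-patient results refer to the held-out folds
or to full-image predictions is ambiguous in the source; both are computed
and reported under distinct names (`heldout`, `full`).
`run_experiment_b()` (inter-patient) is leave-one-image-out: the pooled
other images select a model by double cross-validation and the held-out
image is classified in full — the deployment scenario, and the harder test
of generalization. One master seed derives all stage seeds by fixed
offsets.

## Metrics

`confusion()` (rows = truth), `oacc()` (trace over total), one-vs-rest
`class_metrics()` (ACC, SEN, SPE, Error; `ACC + Error = 1` by
construction), and `blood_sen()`, which merges venous and arterial blood —
clinically interchangeable during resection — counting venous-arterial
cross-predictions as merged-class hits by default (`strict = TRUE` keeps
them as errors). Metrics with empty denominators are reported as `NA`,
never 0, so aggregation cannot silently deflate. Per-image summaries use
the population SD convention (switchable). `oacc_per_band()` divides an
overall accuracy in percent by the camera's band count, rounding half-up
to 2 decimals, enabling comparison across cameras of very different
spectral resolution (a 25-band snapshot system at 60% beats a 128-band
system at 80% on this metric, 2.4 vs 0.63 — the published comparison also
contains one row, 96.7% over 826 bands, printed as 0.11 where the
arithmetic gives 0.12).

## Desk-scale test sizes

The test suite exercises every stage on phantom scenes of 20-64 pixels per
side, three to five scenes per experiment, with the CNN at 8/16 filters and
1024/512 fully connected widths (the architecture is identical to the
default 128/256 configuration; widths are hyperparameters of the spec
object). The CNN accuracy benchmark trains on four balanced 64 x 64 scenes
(about 2300 patches per class, mirroring the benchmark convention of at
least 2000 samples per class) at the full published training budget. These
sizes were chosen so the whole suite runs comfortably on a single CPU;
they are stated here because absolute accuracies depend on them.

## Known limitations

* The generator's spectra are smooth parametric curves, not measured tissue
  reflectances; absolute accuracies on phantoms say nothing about patients.
* Only the 9x9 patch size is implemented for the CNN (published work swept
  3x3 to 21x21).
* The bone class present in some clinical ground-truth maps is out of
  scope, as it was excluded from the published experiments.
* ENVI support covers the BSQ float32 files this package writes, not the
  full format zoo; palette PNG maps are written as RGB with exact palette
  colors (the png package cannot write indexed PNGs) and round-trip
  losslessly through `read_map()`.
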