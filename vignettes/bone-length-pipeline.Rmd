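---
title: "Automated murine bone-length measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated murine bone-length measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Skeletal phenotyping of genetic mouse models requires measuring the lengths of
the tibia, femur and pelvis on both sides of each animal across thousands of
dorsal-view radiographs. Measured lengths are compared to the length expected
for the animal's age and sex, and the residuals feed genetic association
analyses — so measurement *consistency* matters as much as accuracy: variance
added by the measurement process directly erodes mapping power.

bonemorph implements this measurement pipeline end to end: a two-stage
keypoint detector locates each mouse, classifies whether it is a top-view
animal, and predicts the twelve bone-endpoint landmarks (start and end of
tibia, femur, pelvis, left and right); post-processing converts landmarks to
lengths and flags implausible records; and a statistics layer provides the
evaluation metrics (objectness accuracy, keypoint mean squared error),
manual-versus-automated correlation, age/sex residualization and variance
comparison by F-test.

Because real radiograph cohorts are large and externally hosted, the package
ships a synthetic radiograph generator that renders stylized mouse skeletons
with exact ground-truth annotations. Every stage of the pipeline is trainable
and testable against that generator on a single CPU.

## The detector

The detector follows the two-stage keypoint R-CNN design: a shared
convolutional backbone with top-down multi-scale feature fusion, an
objectness/classification ROI head, and a heatmap keypoint head.

**Backbone.** The `tiny_fpn` profile has three conv–BatchNorm–ReLU stages at
strides 2, 4 and 8 (10/20/32 channels), fused top-down through 1×1 lateral
projections into a 12-channel pyramid. The stride-8 map feeds the ROI head;
the keypoint head consumes a stride-4 fine map that fuses the stride-4
lateral, the upsampled stride-8 context and the average-pooled stride-2
lateral (which carries pixel-level edge detail).
The full model holds ≈6×10⁴ parameters — deliberately small, since the
synthetic scenes are low-entropy compared to real radiographs. A wider
`efficientnet_b3_fpn` profile (same stage design, 40/80/128 channels) is
accepted by the configuration for larger problems; it is a scaled profile of
this package's backbone, not the original EfficientNet-B3.

**Proposals and classification.** A small convolutional objectness branch
scores every stride-8 cell; cells are labeled positive in training when their
centers fall inside a ground-truth mouse box. Proposals are formed at
inference from connected components of the thresholded objectness map — the
detection phase of the training protocol updates only with the objectness and
class losses, so the detector carries no box-regression branch, and component
extents (plus a fixed margin) serve as boxes. Each proposal is
bilinearly aligned to a 7×7 crop of the stride-8 features and classified
(background versus top-view mouse; an optional third non-top-view class is
config-gated). The softmax probability of the top-view class is the
detection's *top-view probability*; the post-processing filter retains
detections strictly above 0.5, as the measurement protocol specifies.

**Keypoint head.** For each retained detection, a square window of
`heatmap_size` pixels (default 160) is centred on the box, with its origin
snapped to the stride-4 grid. The head's input over this window combines
three sources on the 40×40 stride-4 grid: the cropped fine FPN features; the
window's raw pixels rearranged space-to-depth (each stride-4 cell carries its
16 exact intensities), giving the head lossless access to local image
evidence; and two constant channels holding each bin's window-normalized
(x, y) position so the head can learn window-anchored spatial priors. All
feature channels are multiplied by a box mask (bins outside the detection box
are zeroed — with two mice per image, the neighbouring animal's limbs are
otherwise indistinguishable distractors for the sided landmarks). Eight
convolution+BatchNorm+ReLU blocks follow, and a single transposed convolution
(kernel 4, stride 4) emits one heatmap per landmark at **one bin per image
pixel**; the raw-pixel and coordinate channels are also fed to the
transposed convolution through a skip connection, so sub-position selection
within each 4×4 block can act as a matched filter on the actual pixels.
The one-bin-per-pixel alignment is the key numerical choice: ground-truth
landmarks are integer pixels, so a correct argmax is exact, and sub-pixel
error comes only from refinement rather than bin quantization. A
normalized-box heatmap at 56 bins — the more common design — has bin sizes of
2–3 px for these mice, which alone exceeds the sub-pixel error this
application targets.

**Decoding.** Per landmark, the argmax bin is refined to sub-pixel
precision by the probability-mass centroid of the local softmax window
(radius 3 bins) around the argmax — for a symmetric learned peak the offset
vanishes, which is the right behaviour when ground truth sits at bin
centers. Two alternatives are config-gated: a clamped 1-D log-space parabola
through the argmax and its neighbours (`refine = "parabolic"`), and the
classical quarter-offset rule (`refine = "quarter"`). The quarter-offset
rule injects a deterministic ±0.25-bin error exactly where this pipeline's
precision target lives, which is why it is not the default; the centroid
measurably outperformed the parabola on trained models because the
transposed convolution's 4×4 block structure leaves small non-smooth
artefacts that a three-point parabola amplifies. Decoded coordinates are
clipped into the detection box; the softmax peak probability is kept as the
per-landmark confidence score.

## Losses and supervision

The training objective is the sum of three components, each implemented
exactly and unit-tested against hand-computed values:

* **objectness loss** — mean binary cross-entropy over predicted boxes (grid
  cells), `-(1/N) Σ yᵢ log pᵢ + (1-yᵢ) log(1-pᵢ)`;
* **class loss** — mean categorical cross-entropy of the ROI classifier
  against one-hot labels;
* **keypoint loss** — the coordinate mean squared error
  `(1/N) Σᵢ Σₖ ‖predᵢₖ − gtᵢₖ‖²`, divided by the number of boxes `N` (not
  `N·K`), with invisible landmarks excluded from the sum. The printed form of
  this quantity carries a leading minus sign in some descriptions of the
  method; a negated sum of squared norms is unbounded below and cannot be
  minimised, so the package implements the positive mean squared error.

Probabilities are clamped to `[1e-7, 1 − 1e-7]` before logarithms; the loss
layer never produces `log(0)`.

For *training* the keypoint head, the practical objective is per-landmark
spatial cross-entropy between the softmaxed heatmap and a Gaussian-smoothed
target (sd 1 px, truncated at 3 px) centred on the ground-truth bin — the
standard heatmap-regression supervision, and the only one of the two we found
to converge within a CPU epoch budget (`heat_target_sd = 0` recovers the
one-hot target). The coordinate mean squared error remains the
evaluation-facing metric throughout, and `kp_loss = "coordinate"` selects a
soft-argmax coordinate objective instead for training.

## The alternating training protocol

Mouse-position data and keypoint data carry different ground truth; mixing
them in one update destabilises training (in the worst case producing NaN
losses, which the trainer explicitly guards against — any non-finite loss
aborts with the offending phase and batch). Training therefore alternates by
phase:

1. **Detection phase** — the keypoint header is frozen (bit-identical before
   and after, enforced by tests); backbone and ROI header update with
   objectness + class loss. Stops early when validation objectness accuracy
   plateaus.
2. **Keypoint phase** — the ROI header is frozen; backbone and keypoint
   header update with objectness + keypoint loss. Stops when validation
   keypoint MSE plateaus.

The learning rate warm-starts at 0.0002 for one epoch, rises to the base
rate, and decays at milestones placed at 60% and 85% of the phase budget
(configurable). The optimiser is Adam; the batch size defaults to 4. The
schedule object defaults to the full-scale settings (base rate 0.001, 100
detection epochs, 1000 keypoint epochs); the desk-scale benchmark uses 10
detection and 30 keypoint epochs with a base rate of 0.0025 — scaled up for
its far smaller model — with 5× decays at 82% and 93% of the budget and
patience 6. Alternation is per phase-block (detection to plateau, then
keypoints), matching the sequential budgets; "plateau" means no improvement
of at least `1e-4` over `patience` validation checks. All stochastic
elements — scene sampling, weight initialisation, data order, window jitter,
augmentation — derive from one root seed, so a full run is reproducible.

## Augmentation

The augmentation module applies shift-scale-rotate, horizontal and vertical
flips and brightness/contrast jitter, with all geometric transforms applied
identically to raster, boxes and keypoints. A single mirror flips chirality,
so *both* flips swap the left/right landmark labels — without the swap, a
flipped image would teach the model anatomically wrong sides. Keypoints
leaving the frame are marked invisible; photometric transforms never touch
coordinates. Interpolation is bilinear with constant background fill.

The desk-scale benchmark trains with horizontal flips, photometric jitter
and exact integer-pixel translations (`integer_shift`, ±3 px). The integer
shifts are interpolation-free, preserve integer ground truth, and vary each
landmark's sub-cell phase relative to the stride-4 feature grid — the
variation the heatmap head must master for sub-pixel decoding. The generator
already randomizes body pose (±7° axis rotation), bone lengths and placement;
adding resampling-based rotation augmentation slowed convergence without
improving held-out precision, and vertical flips would introduce head-down
animals, which the generator's standardized head-up acquisition never
produces. Magnitude limits for the full affine transform set default to
0.0625 (shift), 0.1 (scale) and 15° (rotation).

## The synthetic generator

Each scene renders 0–2 non-overlapping stylized mice over Gaussian background
noise: a soft body ellipse, head ellipse and spine line, plus six bright
anti-aliased bone segments whose endpoints *are* the stored ground-truth
keypoints. Hind-limb geometry enforces anatomical adjacency (femur start
within a small jitter radius of the ipsilateral pelvis end; tibia start near
the femur end) with randomized segment angles and lengths
(pelvis/femur/tibia means 15/20/24 px at the 256-px reference frame, sd 1.4).
The rendered skeleton is Gaussian-blurred (sd 0.7 px) to mimic radiographic
softness. With `integer_keypoints` (the default) endpoints are snapped to
integer pixels — the bone's realized length then differs from its sampled
target by at most one pixel, and decoding error is cleanly separated from
generation error.

What the generator does *not* emulate: soft tissue and organ shadows,
overlapping animals, exposure gradients, forelimbs, oblique or lateral views
(a boneless non-top-view decoy body is available via `decoy_prob` but off by
default, since the realistic frequency of such animals is unknown).
Consequently, passing the desk-scale benchmark demonstrates that the
pipeline's machinery — detection, sided landmark localization, measurement,
statistics — is correct and precise on data satisfying its assumptions; it
does not certify performance on real radiographs, where the full-scale
backbone profile and real annotations would be needed.

The cohort simulator (`simulate_cohort()`) complements the image generator
for the statistics layer: per-mouse ages and sexes with lengths from a
saturating monoexponential growth curve (asymptotes 18/15.5/11 length units
for tibia/femur/pelvis, 4% male size advantage, Gaussian measurement noise).

## Measurement and quality flags

Lengths are Euclidean distances between the canonical start/end landmarks, in
pixels (multiply by `pixel_spacing` for mm). Records are flagged, never
deleted:

* `low_confidence` — either endpoint scored below the per-landmark threshold
  (default 0.2);
* `length_outlier` — `|length − median| > k·MAD` within the bone class
  (k = 5), with batch or user-supplied reference statistics; fewer than three
  clean lengths in a class skips the rule with a warning;
* `abnormal_geometry` — a missing or coincident endpoint, a violated
  adjacency (femur start farther than `r` from the ipsilateral pelvis end, or
  tibia start from the femur end; `r` defaults to half the median femur
  length), or left/right lengths of one bone differing by more than 25%.

The underlying outlier/abnormal-shape procedure in the source method is not
published in detail; this explicit median±MAD + adjacency + symmetry rule is
a deterministic, unit-testable formulation with every constant exposed
(`k`, `r`, `a`). Whether to drop flagged bones or whole animals is left to
the caller.

## Statistics

* `objectness_accuracy()` — fraction of images whose retained-detection count
  (after the strict >0.5 top-view filter) equals the true mouse count.
* `keypoint_mse()` — mean squared Euclidean pixel distance over matched
  visible landmarks; detections are matched to truth greedily by IoU > 0.5.
  The quantity is on a squared-pixel scale (reported here as "px²-scale"
  even where source conventions label it "pixels").
* `correlate()` — Pearson r with the two-sided p-value from the t transform
  (via `stats::cor.test`) plus the least-squares line; R² = r². p-values may
  underflow to 0 at large n.
* `residualize()` — per-sex penalized-spline smooth of length against age
  (`mgcv::gam`, basis dimension `df + 1`, default 6 effective df cap),
  residual = observed − fitted; per-sex residual means vanish to numerical
  precision. The spline stands in for the unpublished parametric growth model
  used with real cohorts and is deliberately behind a narrow interface so a
  parametric curve can replace it.
* `variance_f_test()` — `F = s²_a/s²_b` with `(n_a−1, n_b−1)` df and a
  two-sided p (via `stats::var.test`); used to compare residual variances
  between measurement methods.

## Desk-scale problem sizes

The bundled benchmark (`desk_benchmark()`, also driven by
`scripts/acceptance.R`) uses 100 training, 20 validation and 20 test images
at 256×256 px with one or two mice each; the tiny backbone trains for up to
10 detection and 30 keypoint epochs (one randomly sampled mouse per image
per keypoint step) with validation every 4 epochs. At these
sizes the detector reliably reaches perfect mouse-count accuracy on held-out
images, with mean landmark errors below one pixel; the residual keypoint
error is dominated by the keypoint head's generalization across skeleton
configurations and continues to shrink with longer training — controlled
overfitting probes reach squared errors below 0.01 px², so the remaining gap
at the benchmark budget is optimization time, not an architectural floor.
The statistics suites use n = 500 cohort records and 1000 simulation
replicates. The unit-test suite runs the same code paths at a further
reduced scale (128-px scenes, 64-px windows).

## Known limitations

* The neural-network layer is a compact, BLAS-backed implementation (im2col
  convolutions, BatchNorm, transposed convolution, Adam) designed for this
  detector's shapes; it is single-device, double-precision and has no
  autograd — gradients are hand-derived and finite-difference-tested.
* Proposal boxes come from objectness components, not learned regression;
  boxes are therefore accurate to roughly one stride-8 cell, which suffices
  for IoU-0.5 matching and window placement but is not a tight localizer.
* The synthetic cohort is far easier than real radiographs; results at desk
  scale bound what the machinery can do, not what real-data accuracy will be.
* Checkpoints are R serialization files; no cross-framework export.
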