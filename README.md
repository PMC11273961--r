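# bonemorph

Automated measurement of murine bone lengths in dorsal-view radiographs.

Genetic screens for skeletal phenotypes measure the tibia, femur and pelvis
of each mouse — left and right sides — across thousands of X-ray images, then
compare each length to the value expected for the animal's age and sex.
Manual measurement is slow and adds observer variance that directly weakens
downstream genetic association mapping. bonemorph automates the measurement:
a two-stage keypoint detector finds each mouse, scores the probability that
it is a top-view animal, and localizes the twelve bone-endpoint landmarks;
post-processing converts landmarks to per-bone lengths with quality flags;
and a statistics layer evaluates the result (objectness accuracy, keypoint
MSE, manual-versus-automated correlation, age/sex residualization, variance
F-tests).

The package is self-contained: a synthetic radiograph generator renders
stylized mouse skeletons with exact ground-truth annotations, so the full
pipeline trains and evaluates on one CPU with no external data. The neural
network (conv/BatchNorm/FPN backbone, ROI head, heatmap keypoint head, Adam)
is implemented in-package on BLAS matrix operations.

## The model

Detection is two-stage. A convolutional backbone with top-down feature
fusion feeds (i) an objectness/classification ROI head on the stride-8
feature map, and (ii) a keypoint head on the stride-4 map. The training
objective is the sum

```
L = L_objectness + L_class + L_keypoints
L_objectness = -(1/N) Σᵢ yᵢ log pᵢ + (1-yᵢ) log(1-pᵢ)
L_class      = -(1/N) Σᵢ Σ_c y_ic log p_ic
L_keypoints  =  (1/N) Σᵢ Σ_k ‖predᵢₖ - gtᵢₖ‖²
```

Training alternates between two phases: the detection phase freezes the
keypoint header and updates backbone + ROI header with objectness + class
loss; the keypoint phase freezes the ROI header and updates backbone +
keypoint header. The learning rate warm-starts at 0.0002 for one epoch, then
runs at 0.001 with multi-step decay; the optimiser is Adam with batch size 4.

Keypoints decode from per-landmark heatmaps whose bins map one-to-one onto
image pixels, with sub-pixel refinement of the argmax by the local
probability-mass centroid. Detections
with top-view probability ≤ 0.5 are discarded; bone length is the Euclidean
distance between a bone's start and end landmarks; refinement flags length
outliers (median ± 5·MAD), violated bone adjacency and left/right asymmetry.

## Worked example

```r
library(bonemorph)

# a synthetic two-mouse radiograph with exact ground truth
scene <- generate_scene(scene_config(n_mice = 2, seed = 7))
scene_lengths(scene)
#> # A tibble: 12 × 5
#>    mouse bone   side  target_px length_px
#>     <int> <chr>  <chr>     <dbl>     <dbl>
#>  1     1 pelvis L          15.4      15.3
#>  2     1 femur  L          19.8      20.0
#>  3     1 tibia  L          24.8      24.7
#>  # … one row per (mouse, bone, side)

# train + evaluate the full pipeline at desk scale (about 17 minutes on 1 CPU)
run <- desk_benchmark(seed = 0)
glance(run$eval)
#> # A tibble: 1 × 5
#>   objectness_accuracy keypoint_mse length_r_squared n_images n_truth_mice
#>                 <dbl>        <dbl>            <dbl>    <int>        <int>
#> 1                   1        0.641            0.946       20           33

# measure bones from detections and write the measurement table
det  <- detect_mice(run$model, lapply(run$test, `[[`, "image"))
meas <- det |> filter_detections(0.5) |> measure_bones() |> refine_measurements()
write_measurements(meas, "measurements.csv")

# cohort statistics: age/sex-adjusted residuals and method-variance comparison
cohort <- simulate_cohort(n = 500, seed = 1)
res <- residualize(cohort, bone = "tibia", side = "L")
variance_f_test(res$residual, res$residual * 1.2)
```

`glance(run$eval)` reads: on 20 held-out synthetic radiographs the trained
tiny model reports the correct number of mice in every image
(`objectness_accuracy = 1`), its landmark coordinates deviate from integer
ground truth by 0.64 squared pixels on average (`keypoint_mse`; about 0.6 px
RMS per coordinate pair at this desk-scale training budget — controlled
overfitting probes reach below 0.01, so precision here is bounded by the
short CPU schedule, not by the architecture), and automated lengths track
ground truth closely (`length_r_squared = 0.95` over all bones pooled).

A thin command-line wrapper is installed with the package
(`system.file("cli", "bonemorph", package = "bonemorph")`) exposing
`simulate`, `train`, `predict`, `measure` and `evaluate` subcommands over a
YAML config with `--set key.path=value` overrides.

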