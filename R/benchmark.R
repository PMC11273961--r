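# Desk-scale benchmark: the full pipeline — synthetic cohort generation,
# alternating two-header training with the tiny backbone, and held-out
# evaluation — at a problem size that runs on one CPU.

#' Run the desk-scale training and evaluation benchmark
#'
#' Generates a synthetic radiograph cohort (256 x 256 px, one or two mice per
#' image, integer ground-truth keypoints), trains the tiny-profile detector
#' with the alternating two-header protocol (keypoint-consistent augmentation
#' on), and evaluates on the held-out test images: mouse-count (objectness)
#' accuracy after the 0.5 top-view filter, keypoint mean squared error over
#' IoU-matched detections, and the correlation between automated and
#' ground-truth bone lengths.
#'
#' @param seed root seed driving scene generation, weight initialisation,
#'   data order and augmentation.
#' @param n_train,n_val,n_test images per split (defaults 100/20/20).
#' @param detection_epochs,keypoint_epochs phase epoch budgets for the
#'   desk-scale run (the full-scale budgets in [training_schedule()] are far
#'   beyond one CPU).
#' @param base_lr post-warm-start learning rate for the desk-scale run. The
#'   full-scale protocol uses 0.001; the desk profile uses a higher rate,
#'   scaled for its much smaller model, and keeps the warm-start and
#'   multi-step decay structure.
#' @param augment use training-time augmentation (default `TRUE`).
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained detector), `history` (training curve
#'   tibble), `eval` (a `bone_eval` report on the test split), the `train`,
#'   `val` and `test` sample lists, and `seed`.
#' @export
desk_benchmark <- function(seed = 0L, n_train = 100L, n_val = 20L,
                           n_test = 20L, detection_epochs = 10L,
                           keypoint_epochs = 30L, base_lr = 2.5e-3,
                           augment = TRUE, verbose = FALSE) {
  seed <- as.integer(seed) %% 100000L
  gen_split <- function(n, offset) {
    counts <- with_seed(seed + offset, sample(1:2, n, replace = TRUE))
    scenes_to_samples(lapply(seq_len(n), function(i) {
      generate_scene(scene_config(
        n_mice = counts[i],
        seed = (seed * 131L + offset * 7919L + i * 104729L) %% 2147483587L))
    }))
  }
  train <- gen_split(n_train, 1L)
  val <- gen_split(n_val, 2L)
  test <- gen_split(n_test, 3L)
  model <- build_model(model_config(), seed = seed)
  # mild profile: horizontal flips (with anatomical side swap) and small
  # geometric/photometric jitter; no vertical flips, since the generator
  # emulates the standardized head-up acquisition orientation
  aug <- if (augment) {
    augment_config(p_ssr = 0, p_hflip = 0.5, p_vflip = 0,
                   brightness_limit = 0.1, contrast_limit = 0.1,
                   integer_shift = 3L)
  }
  sched <- training_schedule(base_lr = base_lr,
                             detection_epochs = detection_epochs,
                             keypoint_epochs = keypoint_epochs,
                             milestones = c(floor(0.82 * keypoint_epochs),
                                            floor(0.93 * keypoint_epochs)),
                             decay_factor = 0.2, batch_size = 4L,
                             patience = 6L, val_every = 4L, seed = seed)
  fit <- alternate_train(model, train, train, sched, val_data = val,
                         augment_cfg = aug, verbose = verbose)
  det <- detect_mice(fit$model, lapply(test, `[[`, "image"))
  ev <- evaluate_detections(test, det, fit$model$config$score_threshold)
  list(model = fit$model, history = fit$history, eval = ev,
       train = train, val = val, test = test, seed = seed)
}
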