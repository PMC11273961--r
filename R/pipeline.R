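# Pipeline entry point: simulate / train / predict / measure / evaluate over
# a single YAML config with dotted-path overrides. The thin command-line
# wrapper in inst/cli/bonemorph forwards to run_pipeline().

#' Default pipeline configuration
#'
#' @return nested list with `seed`, `paths`, `scene`, `model`, `schedule`,
#'   `augment` and `measure` blocks; any field can be overridden from YAML or
#'   with dotted-path overrides in [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 0L,
    paths = list(data_dir = "data", checkpoint = "model.ckpt",
                 history = "history.csv", detections = "detections.json",
                 measurements = "measurements.csv", report = "report.json"),
    scene = list(n_images = 94L, split_fractions = c(64, 11, 19) / 94,
                 image_width = 256L, image_height = 256L,
                 background_noise_sd = 0.03, bone_intensity = 0.55,
                 bone_thickness = 2.4,
                 length_means = list(tibia = 24, femur = 20, pelvis = 15),
                 length_sd = 1.4, integer_keypoints = TRUE, decoy_prob = 0),
    model = list(backbone = "tiny_fpn", n_classes = 2L,
                 keypoint_head_blocks = 8L, heatmap_size = 160L,
                 score_threshold = 0.5),
    schedule = list(warm_lr = 2e-4, warm_epochs = 1L, base_lr = 1e-3,
                    detection_epochs = 12L, keypoint_epochs = 30L,
                    batch_size = 4L, patience = 3L),
    augment = list(enabled = FALSE, shift_limit = 0.0625, scale_limit = 0.1,
                   rotate_limit = 15, p_hflip = 0.5, p_vflip = 0.5,
                   brightness_limit = 0.2, contrast_limit = 0.2),
    measure = list(k = 5, a = 0.25, score_threshold = 0.2)
  )
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      modify_list(base[[nm]], new[[nm]])
    } else new[[nm]]
  }
  base
}

apply_override <- function(cfg, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  val <- utils::type.convert(value, as.is = TRUE)
  expr <- cfg
  # walk down, then rebuild
  setter <- function(lst, path, val) {
    if (length(path) == 1) { lst[[path]] <- val; return(lst) }
    lst[[path[1]]] <- setter(lst[[path[1]]] %||% list(), path[-1], val)
    lst
  }
  setter(cfg, path, val)
}

# stable config fingerprint (polynomial rolling hash; not cryptographic)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 7
  for (chunk in split(b, ceiling(seq_along(b) / 4096))) {
    for (x in chunk) h <- (h * 31 + x) %% 2147483647
  }
  sprintf("%08x", h)
}

load_pipeline_config <- function(config = NULL, overrides = character()) {
  cfg <- default_pipeline_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    cfg <- modify_list(cfg, yaml::read_yaml(config))
  } else if (is.list(config)) {
    cfg <- modify_list(cfg, config)
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must look like key.path=value: ", ov,
                              call. = FALSE)
    cfg <- apply_override(cfg, kv[1], kv[2])
  }
  cfg
}

scene_config_from <- function(cfg) {
  sc <- cfg$scene
  scene_config(
    image_width = sc$image_width, image_height = sc$image_height,
    n_mice = 2L, background_noise_sd = sc$background_noise_sd,
    bone_intensity = sc$bone_intensity, bone_thickness = sc$bone_thickness,
    length_means = unlist(sc$length_means),
    length_sd = sc$length_sd, integer_keypoints = sc$integer_keypoints,
    decoy_prob = sc$decoy_prob, seed = cfg$seed
  )
}

model_config_from <- function(cfg) {
  mc <- cfg$model
  model_config(backbone = mc$backbone, n_classes = mc$n_classes,
               keypoint_head_blocks = mc$keypoint_head_blocks,
               heatmap_size = mc$heatmap_size,
               score_threshold = mc$score_threshold)
}

schedule_from <- function(cfg) {
  sc <- cfg$schedule
  training_schedule(
    warm_lr = sc$warm_lr, warm_epochs = sc$warm_epochs, base_lr = sc$base_lr,
    detection_epochs = sc$detection_epochs, keypoint_epochs = sc$keypoint_epochs,
    batch_size = sc$batch_size, patience = sc$patience, seed = cfg$seed
  )
}

write_run_stamp <- function(cfg, dir, artifacts) {
  stamp <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                artifacts = artifacts, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(stamp, file.path(dir, "run.json"), auto_unbox = TRUE)
}

#' Run a pipeline stage
#'
#' Single programmatic entry point behind the command-line tool. Subcommands:
#' `simulate` writes a synthetic dataset; `train` trains the detector with the
#' alternating protocol and writes checkpoint + history; `predict` writes raw
#' detections JSON for the test split; `measure` writes the bone-length
#' measurement CSV; `evaluate` writes the evaluation report JSON. Every output
#' directory receives a `run.json` stamp with the config hash and seed.
#'
#' @param subcommand one of `"simulate"`, `"train"`, `"predict"`,
#'   `"measure"`, `"evaluate"`.
#' @param config `NULL` (defaults), a YAML file path, or a nested list merged
#'   over the defaults.
#' @param overrides character vector of `key.path=value` overrides.
#' @return the stage's main artifact, invisibly (manifest, trained model,
#'   detections, measurements or report).
#' @export
run_pipeline <- function(subcommand, config = NULL, overrides = character()) {
  if (!is.character(subcommand) ||
      !subcommand %in% c("simulate", "train", "predict", "measure", "evaluate")) {
    stop("unknown subcommand: ", paste(subcommand, collapse = " "),
         "; expected simulate/train/predict/measure/evaluate", call. = FALSE)
  }
  cfg <- load_pipeline_config(config, overrides)
  dir.create(cfg$paths$data_dir, showWarnings = FALSE, recursive = TRUE)
  switch(subcommand,
    simulate = pipeline_simulate(cfg),
    train = pipeline_train(cfg),
    predict = pipeline_predict(cfg),
    measure = pipeline_measure(cfg),
    evaluate = pipeline_evaluate(cfg)
  )
}

pipeline_simulate <- function(cfg) {
  manifest <- generate_dataset(cfg$scene$n_images, cfg$scene$split_fractions,
                               scene_config_from(cfg), cfg$paths$data_dir)
  write_run_stamp(cfg, cfg$paths$data_dir, list(manifest = "manifest.csv"))
  invisible(manifest)
}

augment_from <- function(cfg) {
  if (!isTRUE(cfg$augment$enabled)) return(NULL)
  au <- cfg$augment
  augment_config(shift_limit = au$shift_limit, scale_limit = au$scale_limit,
                 rotate_limit = au$rotate_limit, p_hflip = au$p_hflip,
                 p_vflip = au$p_vflip, brightness_limit = au$brightness_limit,
                 contrast_limit = au$contrast_limit)
}

pipeline_train <- function(cfg) {
  train <- load_samples(cfg$paths$data_dir, "train")
  val <- load_samples(cfg$paths$data_dir, "val")
  model <- build_model(model_config_from(cfg), seed = cfg$seed)
  fit <- alternate_train(model, train, train, schedule_from(cfg),
                         val_data = val, augment_cfg = augment_from(cfg),
                         checkpoint_path = file.path(cfg$paths$data_dir,
                                                     cfg$paths$checkpoint))
  readr::write_csv(fit$history, file.path(cfg$paths$data_dir, cfg$paths$history))
  write_run_stamp(cfg, cfg$paths$data_dir,
                  list(checkpoint = cfg$paths$checkpoint,
                       history = cfg$paths$history))
  invisible(fit)
}

pipeline_model <- function(cfg) {
  path <- file.path(cfg$paths$data_dir, cfg$paths$checkpoint)
  load_checkpoint(path)
}

pipeline_predict <- function(cfg, split = "test") {
  model <- pipeline_model(cfg)
  samples <- load_samples(cfg$paths$data_dir, split)
  det <- detect_mice(model, lapply(samples, `[[`, "image"))
  out <- file.path(cfg$paths$data_dir, cfg$paths$detections)
  det_json <- dplyr::mutate(det, keypoints = lapply(.data$keypoints, function(kp) {
    list(xy = kp$xy, visibility = kp$visibility, scores = kp$scores)
  }))
  jsonlite::write_json(list(config_hash = config_hash(cfg),
                            detections = det_json),
                       out, auto_unbox = TRUE, digits = NA)
  write_run_stamp(cfg, cfg$paths$data_dir, list(detections = cfg$paths$detections))
  invisible(det)
}

pipeline_measure <- function(cfg, split = "test") {
  model <- pipeline_model(cfg)
  samples <- load_samples(cfg$paths$data_dir, split)
  det <- detect_mice(model, lapply(samples, `[[`, "image"))
  kept <- filter_detections(det, cfg$model$score_threshold)
  meas <- measure_bones(kept, score_threshold = cfg$measure$score_threshold)
  meas <- refine_measurements(meas, k = cfg$measure$k, a = cfg$measure$a)
  out <- file.path(cfg$paths$data_dir, cfg$paths$measurements)
  write_measurements(meas, out)
  write_run_stamp(cfg, cfg$paths$data_dir,
                  list(measurements = cfg$paths$measurements))
  invisible(meas)
}

pipeline_evaluate <- function(cfg, split = "test") {
  model <- pipeline_model(cfg)
  samples <- load_samples(cfg$paths$data_dir, split)
  det <- detect_mice(model, lapply(samples, `[[`, "image"))
  ev <- evaluate_detections(samples, det, cfg$model$score_threshold)
  out <- file.path(cfg$paths$data_dir, cfg$paths$report)
  jsonlite::write_json(list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    objectness_accuracy = ev$objectness_accuracy,
    keypoint_mse = ev$keypoint_mse,
    correlations = ev$correlations
  ), out, auto_unbox = TRUE, digits = NA)
  write_run_stamp(cfg, cfg$paths$data_dir, list(report = cfg$paths$report))
  invisible(ev)
}
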