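# Shared fixtures: all synthetic, built in code at test time.

# reduced-scale scene for fast training tests: 128 px frame, one mouse
tiny_scene_config <- function(seed, n_mice = 1L) {
  scene_config(image_width = 128, image_height = 128, n_mice = n_mice,
               length_means = c(tibia = 12, femur = 10, pelvis = 8),
               length_sd = 0.8, bone_thickness = 1.8, seed = seed)
}

tiny_model_config <- function(...) {
  model_config(heatmap_size = 64L, ...)
}

gen_samples <- function(n, seed0, config_fun = tiny_scene_config, ...) {
  scenes_to_samples(lapply(seq_len(n), function(i) {
    generate_scene(config_fun(seed0 + i, ...))
  }))
}

# hand-written Pearson correlation oracle (direct formula evaluation)
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# the desk-scale benchmark model is trained once and reused by the
# acceptance tests (training is the expensive step)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (is.null(.acceptance_cache$run)) {
    .acceptance_cache$run <- desk_benchmark(seed = 0)
  }
  .acceptance_cache$run
}
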