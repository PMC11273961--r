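# Detector construction, parameter groups, inference contracts, decoding.

test_that("keypoint head has the configured block count plus one transposed conv", {
  m <- build_model(tiny_model_config(), seed = 1)
  expect_equal(bonemorph:::head_block_count(m), 8L)
  m3 <- build_model(tiny_model_config(keypoint_head_blocks = 3L), seed = 1)
  expect_equal(bonemorph:::head_block_count(m3), 3L)
  expect_true("keypoint_header.tconv.W" %in% names(m$params))
  expect_equal(sum(grepl("tconv", names(m$params))), 2L)  # weight + bias only
})

test_that("tiny profile stays under the documented parameter cap", {
  m <- build_model(model_config(backbone = "tiny_fpn"), seed = 0)
  expect_lt(n_parameters(m), 1e6)
})

test_that("unknown backbone names are rejected", {
  expect_error(model_config(backbone = "resnet50"), "unknown backbone")
})

test_that("weight initialisation is deterministic in the seed", {
  a <- build_model(tiny_model_config(), seed = 42)
  b <- build_model(tiny_model_config(), seed = 42)
  expect_identical(a$params, b$params)
  c <- build_model(tiny_model_config(), seed = 43)
  expect_false(identical(a$params, c$params))
})

test_that("parameter groups partition all parameters", {
  m <- build_model(tiny_model_config(), seed = 1)
  groups <- parameter_groups(m)
  expect_setequal(groups, c("backbone", "roi_header", "keypoint_header"))
  per_group <- lapply(groups, function(g) names(bonemorph:::param_group(m$params, g)))
  expect_equal(sort(unlist(per_group)), sort(names(m$params)))
  expect_equal(sum(lengths(per_group)), length(m$params))  # pairwise disjoint
})

test_that("inference contracts: empty input, shape errors, determinism", {
  m <- build_model(tiny_model_config(), seed = 1)
  expect_equal(nrow(detect_mice(m, list())), 0)
  expect_error(detect_mice(m, list(1:10)), "2-D")
  img <- generate_scene(tiny_scene_config(3))$image
  d1 <- detect_mice(m, img)
  d2 <- detect_mice(m, img)
  expect_identical(d1, d2)
  expect_identical(predict(m, img), d1)
})

test_that("detections are sorted by descending top-view probability", {
  m <- build_model(tiny_model_config(), seed = 1)
  imgs <- lapply(1:2, function(i) generate_scene(tiny_scene_config(i))$image)
  det <- detect_mice(m, imgs)
  if (nrow(det) > 1) {
    by_img <- split(det$top_view_prob, det$image)
    for (v in by_img) expect_true(all(diff(v) <= 0))
  }
  expect_true(all(det$top_view_prob >= 0 & det$top_view_prob <= 1))
})

test_that("decoded keypoints always fall inside the detection box", {
  run <- acceptance_run()
  det <- filter_detections(detect_mice(run$model,
                                       lapply(run$test[1:4], `[[`, "image")), 0.5)
  for (r in seq_len(nrow(det))) {
    kp <- det$keypoints[[r]]
    expect_true(all(kp$xy[, 1] >= det$x0[r] & kp$xy[, 1] <= det$x1[r]))
    expect_true(all(kp$xy[, 2] >= det$y0[r] & kp$xy[, 2] <= det$y1[r]))
  }
})

test_that("heatmap decoding recovers constructed peaks with sub-pixel offsets", {
  H <- 24; W <- 24; K <- 2
  # keypoint 1: an exactly symmetric quadratic peak at (row 11, col 8):
  # the parabolic refinement must return a zero offset
  mk_quad <- function(ci, cj, dx) {
    outer(seq_len(H), seq_len(W), function(i, j) {
      -0.5 * ((i - ci)^2 + (j - cj - dx)^2)
    })
  }
  logits <- cbind(as.vector(mk_quad(11, 8, 0)), as.vector(mk_quad(5, 17, 0.3)))
  dec <- bonemorph:::decode_heatmap_roi(logits, H, W, K, origin = c(100, 200),
                                        refine = "parabolic")
  expect_equal(dec$xy[1, ], c(100 + 7, 200 + 10), tolerance = 1e-9,
               ignore_attr = TRUE)
  # keypoint 2 has its true maximum 0.3 bins right of the argmax column
  expect_equal(dec$xy[2, 1], 100 + 16 + 0.3, tolerance = 1e-6)
  expect_equal(dec$xy[2, 2], 200 + 4, tolerance = 1e-9)
  # quarter-offset mode steps a fixed 0.25 toward the higher neighbour
  dec_q <- bonemorph:::decode_heatmap_roi(logits, H, W, K, origin = c(0, 0),
                                          refine = "quarter")
  expect_equal(dec_q$xy[2, 1], 16 + 0.25, tolerance = 1e-9)
})

test_that("checkpoints round-trip parameters, statistics and config", {
  m <- build_model(tiny_model_config(), seed = 5)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$bn, m$bn)
  expect_equal(unclass(back$config), unclass(m$config))
  img <- generate_scene(tiny_scene_config(9))$image
  expect_identical(detect_mice(back, img), detect_mice(m, img))
})

test_that("translating the input shifts trained-model keypoints accordingly", {
  run <- acceptance_run()
  s <- run$test[[1]]
  dx <- 8L; dy <- 8L   # multiples of the detector stride
  img <- s$image
  shifted <- matrix(median(img), nrow(img), ncol(img))
  shifted[(1 + dy):nrow(img), (1 + dx):ncol(img)] <-
    img[1:(nrow(img) - dy), 1:(ncol(img) - dx)]
  d0 <- filter_detections(detect_mice(run$model, img), 0.5)
  d1 <- filter_detections(detect_mice(run$model, shifted), 0.5)
  expect_equal(nrow(d0), nrow(d1))
  skip_if(nrow(d0) == 0)
  k0 <- d0$keypoints[[1]]$xy
  k1 <- d1$keypoints[[1]]$xy
  expect_lt(max(abs(k1 - (k0 + rep(c(dx, dy), each = 12)))), 2)
})
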