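# Synthetic radiograph generator: determinism, geometry, dataset splits.

test_that("empty scene is pure background noise", {
  sc <- generate_scene(scene_config(n_mice = 0, seed = 3))
  expect_length(sc$mice, 0)
  expect_equal(dim(sc$image), c(256, 256))
  expect_lt(max(sc$image), 0.35)  # no bright structures
  expect_gt(stats::sd(sc$image), 0.01)
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- scene_config(seed = 17)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mice, b$mice)
})

test_that("stored endpoint distances equal sampled target lengths within 1 px", {
  for (seed in 1:8) {
    sc <- generate_scene(scene_config(n_mice = 2, seed = seed))
    lens <- scene_lengths(sc)
    # oracle: recompute distances from the stored coordinates
    for (m in seq_along(sc$mice)) {
      kp <- sc$mice[[m]]$keypoints
      edges <- keypoint_skeleton()
      info <- keypoint_bones()
      recomputed <- tibble::tibble(
        bone = info$bone[edges[, 1]], side = info$side[edges[, 1]],
        recomputed = vapply(seq_len(nrow(edges)), function(i) {
          sqrt(sum((kp$xy[edges[i, 1], ] - kp$xy[edges[i, 2], ])^2))
        }, numeric(1))
      )
      joined <- dplyr::inner_join(recomputed, lens[lens$mouse == m, ],
                                  by = c("bone", "side"))
      expect_equal(nrow(joined), 6)
      expect_equal(joined$recomputed, joined$length_px, tolerance = 1e-12)
    }
    expect_true(all(abs(lens$length_px - lens$target_px) <= 1))
  }
})

test_that("integer keypoints are integers; continuous mode is not snapped", {
  sc <- generate_scene(scene_config(seed = 5, integer_keypoints = TRUE))
  for (m in sc$mice) expect_identical(m$keypoints$xy, round(m$keypoints$xy))
  sc2 <- generate_scene(scene_config(seed = 5, integer_keypoints = FALSE))
  frac <- unlist(lapply(sc2$mice, function(m) m$keypoints$xy %% 1))
  expect_gt(sum(frac != 0), 0)
})

test_that("keypoints lie inside their mouse's box and boxes never overlap", {
  for (seed in 1:6) {
    sc <- generate_scene(scene_config(n_mice = 2, seed = 100 + seed))
    expect_length(sc$mice, 2)
    for (m in sc$mice) {
      b <- m$box
      expect_true(all(m$keypoints$xy[, 1] >= b[1] & m$keypoints$xy[, 1] < b[3]))
      expect_true(all(m$keypoints$xy[, 2] >= b[2] & m$keypoints$xy[, 2] < b[4]))
    }
    b1 <- sc$mice[[1]]$box; b2 <- sc$mice[[2]]$box
    x_overlap <- max(0, min(b1[3], b2[3]) - max(b1[1], b2[1]))
    y_overlap <- max(0, min(b1[4], b2[4]) - max(b1[2], b2[2]))
    expect_equal(x_overlap * y_overlap, 0)
  }
})

test_that("bones satisfy anatomical adjacency", {
  for (seed in 1:5) {
    sc <- generate_scene(scene_config(seed = 300 + seed))
    for (m in sc$mice) {
      kp <- m$keypoints$xy
      nm <- keypoint_names()
      for (side in c("L", "R")) {
        g <- function(x) kp[paste0(x, "_", side, c("_start", "_end"))[2], ] # end
        s <- function(x) kp[paste0(x, "_", side, c("_start", "_end"))[1], ] # start
        # femur starts near pelvis end; tibia starts near femur end
        expect_lt(sqrt(sum((s("femur") - g("pelvis"))^2)), 4)
        expect_lt(sqrt(sum((s("tibia") - g("femur"))^2)), 4)
      }
    }
  }
})

test_that("bones render brighter than the body silhouette", {
  sc <- generate_scene(scene_config(seed = 9, background_noise_sd = 0))
  kp <- sc$mice[[1]]$keypoints$xy
  mid <- round((kp["tibia_L_start", ] + kp["tibia_L_end", ]) / 2)
  bone_val <- sc$image[mid[2] + 1, mid[1] + 1]
  expect_gt(bone_val, 0.5)
})

test_that("impossible placements are rejected", {
  cfg <- scene_config(image_width = 64, image_height = 64, n_mice = 2,
                      length_means = c(tibia = 24, femur = 20, pelvis = 15),
                      seed = 1)
  expect_error(generate_scene(cfg), "non-overlapping")
})

test_that("dataset splits use largest-remainder rounding", {
  expect_identical(bonemorph:::largest_remainder(94, c(64, 11, 19) / 94),
                   c(64L, 11L, 19L))
  expect_identical(bonemorph:::largest_remainder(3, rep(1 / 3, 3)),
                   c(1L, 1L, 1L))
  expect_identical(sum(bonemorph:::largest_remainder(97, c(0.5, 0.25, 0.25))), 97L)
})

test_that("generate_dataset writes the 64/11/19 split with exact annotations", {
  out <- withr::local_tempdir()
  cfg <- scene_config(seed = 7)
  manifest <- generate_dataset(94, c(64, 11, 19) / 94, cfg, out)
  expect_equal(as.vector(table(factor(manifest$split, c("train", "val", "test")))),
               c(64, 11, 19))
  expect_true(all(file.exists(file.path(out, manifest$image))))
  # round-trip: annotations reproduce ground truth coordinate-for-coordinate
  ann <- read_coco_keypoints(file.path(out, "train_annotations.json"))
  expect_length(ann, 64)
  n_mice_ann <- sum(vapply(ann, function(r) length(r$annotations), integer(1)))
  expect_equal(n_mice_ann, sum(manifest$n_mice[manifest$split == "train"]))
  # mouse-count conservation across the manifest
  expect_equal(sum(manifest$n_mice),
               sum(vapply(c("train", "val", "test"), function(s) {
                 a <- read_coco_keypoints(file.path(out, paste0(s, "_annotations.json")))
                 sum(vapply(a, function(r) length(r$annotations), integer(1)))
               }, integer(1))))
  # regeneration with the same seed gives an identical manifest
  out2 <- withr::local_tempdir()
  manifest2 <- generate_dataset(94, c(64, 11, 19) / 94, cfg, out2)
  expect_identical(manifest$split, manifest2$split)
  expect_identical(manifest$n_mice, manifest2$n_mice)
})

test_that("minimal three-image dataset splits 1/1/1", {
  out <- withr::local_tempdir()
  manifest <- generate_dataset(3, rep(1 / 3, 3), tiny_scene_config(1), out)
  expect_equal(sort(manifest$split), sort(c("train", "val", "test")))
})

test_that("cohort simulation produces plausible growth structure", {
  coh <- simulate_cohort(n = 100, seed = 2)
  expect_equal(nrow(coh), 100 * 6)
  expect_true(all(coh$length > 0))
  # older mice are longer on average (saturating growth)
  tib <- coh[coh$bone == "tibia" & coh$side == "L", ]
  young <- mean(tib$length[tib$age < 60]); old <- mean(tib$length[tib$age > 90])
  expect_gt(old, young)
  expect_identical(simulate_cohort(n = 50, seed = 9), simulate_cohort(n = 50, seed = 9))
})
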