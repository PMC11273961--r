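# Keypoint-consistent augmentation: identity, flips with side swaps,
# distance-preserving rotations, photometric independence.

aug_fixture <- function(seed = 1) {
  sc <- generate_scene(scene_config(seed = seed, n_mice = 2))
  list(image = sc$image,
       kps = lapply(sc$mice, `[[`, "keypoints"),
       boxes = lapply(sc$mice, `[[`, "box"))
}

identity_cfg <- augment_config(shift_limit = 0, scale_limit = 0,
                               rotate_limit = 0, p_ssr = 0, p_hflip = 0,
                               p_vflip = 0, brightness_limit = 0,
                               contrast_limit = 0, seed = 1)

test_that("degenerate configuration is the identity", {
  f <- aug_fixture()
  out <- augment(f$image, f$kps, f$boxes, identity_cfg)
  expect_identical(out$image, f$image)
  expect_identical(out$keypoint_sets, f$kps)
  expect_identical(out$boxes, f$boxes)
})

test_that("forced horizontal flip reflects x and swaps anatomical sides", {
  f <- aug_fixture()
  cfg <- augment_config(p_ssr = 0, p_hflip = 1, p_vflip = 0,
                        brightness_limit = 0, contrast_limit = 0, seed = 2)
  out <- augment(f$image, f$kps, f$boxes, cfg)
  W <- ncol(f$image)
  kp_in <- f$kps[[1]]; kp_out <- out$keypoint_sets[[1]]
  # tibia_L maps onto the tibia_R slot with x -> W - 1 - x
  expect_equal(kp_out$xy["tibia_R_start", "x"],
               W - 1 - kp_in$xy["tibia_L_start", "x"])
  expect_equal(kp_out$xy["tibia_R_start", "y"], kp_in$xy["tibia_L_start", "y"])
  expect_equal(kp_out$xy["femur_L_end", "x"], W - 1 - kp_in$xy["femur_R_end", "x"])
  expect_equal(kp_out$xy["pelvis_L_start", "x"],
               W - 1 - kp_in$xy["pelvis_R_start", "x"])
  # raster columns are reversed
  expect_equal(out$image[, 1], f$image[, W])
})

test_that("horizontal flip is an involution on coordinates and labels", {
  f <- aug_fixture(3)
  cfg <- augment_config(p_ssr = 0, p_hflip = 1, p_vflip = 0,
                        brightness_limit = 0, contrast_limit = 0, seed = 5)
  once <- augment(f$image, f$kps, f$boxes, cfg)
  twice <- augment(once$image, once$keypoint_sets, once$boxes, cfg)
  for (m in seq_along(f$kps)) {
    expect_equal(twice$keypoint_sets[[m]]$xy, f$kps[[m]]$xy, tolerance = 1)
  }
  expect_equal(twice$image, f$image, tolerance = 1e-9)
})

test_that("vertical flip also swaps sides (a single mirror flips chirality)", {
  f <- aug_fixture(4)
  cfg <- augment_config(p_ssr = 0, p_hflip = 0, p_vflip = 1,
                        brightness_limit = 0, contrast_limit = 0, seed = 2)
  out <- augment(f$image, f$kps, f$boxes, cfg)
  H <- nrow(f$image)
  expect_equal(out$keypoint_sets[[1]]$xy["tibia_R_end", "y"],
               H - 1 - f$kps[[1]]$xy["tibia_L_end", "y"])
  expect_equal(out$keypoint_sets[[1]]$xy["tibia_R_end", "x"],
               f$kps[[1]]$xy["tibia_L_end", "x"])
})

test_that("pure rotation preserves bone lengths within 0.5 px", {
  f <- aug_fixture(5)
  cfg <- augment_config(shift_limit = 0, scale_limit = 0, rotate_limit = 12,
                        p_ssr = 1, p_hflip = 0, p_vflip = 0,
                        brightness_limit = 0, contrast_limit = 0, seed = 11)
  out <- augment(f$image, f$kps, f$boxes, cfg)
  for (m in seq_along(f$kps)) {
    before <- bonemorph:::kp_bone_lengths(f$kps[[m]])$length_px
    after <- bonemorph:::kp_bone_lengths(out$keypoint_sets[[m]])$length_px
    expect_true(all(abs(before - after) < 0.5, na.rm = TRUE))
  }
})

test_that("pure scaling by s scales every bone length by s within 1%", {
  f <- aug_fixture(6)
  # force scale only: rotate and shift limits zero, scale in a narrow band
  cfg <- augment_config(shift_limit = 0, scale_limit = 0.2, rotate_limit = 0,
                        p_ssr = 1, p_hflip = 0, p_vflip = 0,
                        brightness_limit = 0, contrast_limit = 0, seed = 8)
  out <- augment(f$image, f$kps, f$boxes, cfg)
  before <- bonemorph:::kp_bone_lengths(f$kps[[1]])$length_px
  after <- bonemorph:::kp_bone_lengths(out$keypoint_sets[[1]])$length_px
  ratios <- after / before
  expect_lt(max(abs(ratios / mean(ratios) - 1)), 0.01)
})

test_that("photometric transforms leave coordinates untouched", {
  f <- aug_fixture(7)
  cfg <- augment_config(p_ssr = 0, p_hflip = 0, p_vflip = 0,
                        brightness_limit = 0.3, contrast_limit = 0.3, seed = 3)
  out <- augment(f$image, f$kps, f$boxes, cfg)
  expect_identical(out$keypoint_sets, f$kps)
  expect_identical(out$boxes, f$boxes)
  expect_false(identical(out$image, f$image))
})

test_that("keypoints pushed out of frame are marked invisible", {
  f <- aug_fixture(8)
  cfg <- augment_config(shift_limit = 0.45, scale_limit = 0, rotate_limit = 0,
                        p_ssr = 1, p_hflip = 0, p_vflip = 0,
                        brightness_limit = 0, contrast_limit = 0, seed = 4)
  out <- augment(f$image, f$kps, f$boxes, cfg)
  vis <- unlist(lapply(out$keypoint_sets, `[[`, "visibility"))
  expect_gt(sum(vis == 0), 0)
})
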