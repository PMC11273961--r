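# Post-processing: filtering, length measurement, quality flagging.

det_row <- function(xy, prob = 0.9, image = 1L, mouse = 1L,
                    visibility = rep(2L, 12), scores = NULL) {
  tibble::tibble(image = image, mouse = mouse, top_view_prob = prob,
                 x0 = 0, y0 = 0, x1 = 200, y1 = 200,
                 keypoints = list(keypoint_set(xy, visibility, scores)))
}

grid_kp <- function() cbind(seq(10, 120, by = 10), seq(20, 130, by = 10))

test_that("filter_detections applies a strict > 0.5 rule and preserves order", {
  det <- dplyr::bind_rows(det_row(grid_kp(), 0.9, mouse = 1L),
                          det_row(grid_kp(), 0.4, mouse = 2L),
                          det_row(grid_kp(), 0.5, mouse = 3L))
  kept <- filter_detections(det)
  expect_equal(kept$mouse, 1L)           # 0.4 dropped, exactly 0.5 dropped
  expect_identical(filter_detections(kept), kept)  # idempotent
  expect_equal(nrow(filter_detections(det[0, ])), 0)
  det2 <- dplyr::bind_rows(det_row(grid_kp(), 0.6, mouse = 1L),
                           det_row(grid_kp(), 0.8, mouse = 2L))
  expect_equal(filter_detections(det2)$mouse, c(1L, 2L))  # order preserved
})

test_that("measure_bones computes Euclidean lengths from canonical endpoints", {
  xy <- grid_kp()
  xy[1, ] <- c(0, 0); xy[2, ] <- c(3, 4)   # left tibia is a 3-4-5 triangle
  meas <- measure_bones(det_row(xy))
  expect_equal(nrow(meas), 6)
  expect_setequal(unique(meas$bone), c("tibia", "femur", "pelvis"))
  tib <- meas[meas$bone == "tibia" & meas$side == "L", ]
  expect_equal(tib$length_px, 5)
  expect_equal(c(tib$x_start, tib$y_start, tib$x_end, tib$y_end), c(0, 0, 3, 4))
  # length always equals endpoint distance
  ok <- !is.na(meas$length_px)
  expect_equal(meas$length_px[ok],
               sqrt((meas$x_end - meas$x_start)^2 +
                    (meas$y_end - meas$y_start)^2)[ok], tolerance = 1e-12)
})

test_that("degenerate keypoints yield flags, not exceptions", {
  xy <- grid_kp()
  xy[2, ] <- xy[1, ]                      # coincident tibia endpoints
  vis <- rep(2L, 12); vis[3] <- 0L        # femur start missing
  meas <- measure_bones(det_row(xy, visibility = vis))
  tib <- meas[meas$bone == "tibia" & meas$side == "L", ]
  expect_equal(tib$length_px, 0)
  expect_true("abnormal_geometry" %in% tib$flags[[1]])
  fem <- meas[meas$bone == "femur" & meas$side == "L", ]
  expect_true(is.na(fem$length_px))
  expect_true("abnormal_geometry" %in% fem$flags[[1]])
})

test_that("low keypoint scores flag low_confidence", {
  sc <- rep(0.9, 12); sc[5] <- 0.05       # pelvis_L_start
  meas <- measure_bones(det_row(grid_kp(), scores = sc), score_threshold = 0.2)
  pel <- meas[meas$bone == "pelvis" & meas$side == "L", ]
  expect_true("low_confidence" %in% pel$flags[[1]])
  expect_false("low_confidence" %in%
                 meas$flags[[which(meas$bone == "tibia" & meas$side == "L")]])
})

test_that("lengths are translation invariant and scale exactly", {
  xy <- grid_kp()
  m0 <- measure_bones(det_row(xy))
  m1 <- measure_bones(det_row(xy + 37.5))
  expect_equal(m0$length_px, m1$length_px, tolerance = 1e-12)
  m2 <- measure_bones(det_row(xy * 2.5))
  expect_equal(m2$length_px, 2.5 * m0$length_px, tolerance = 1e-12)
})

# a clean cohort of n identical, anatomically consistent, left/right
# symmetric mice (the right side is the translated left side)
clean_measurements <- function(n = 10) {
  sc <- generate_scene(scene_config(seed = 31, n_mice = 1))
  xy <- sc$mice[[1]]$keypoints$xy
  xy[7:12, ] <- xy[1:6, ] + rep(c(60, 0), each = 6)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    measure_bones(det_row(xy, image = i))
  }))
}

test_that("identical cohorts gain no flags", {
  m <- refine_measurements(clean_measurements())
  expect_true(all(lengths(m$flags) == 0))
})

test_that("a 10x femur length is flagged as outlier, lengths unchanged", {
  m <- clean_measurements()
  i <- which(m$bone == "femur" & m$side == "L" & m$image == 5)
  m$length_px[i] <- 10 * stats::median(m$length_px[m$bone == "femur"])
  out <- refine_measurements(m)
  expect_true("length_outlier" %in% out$flags[[i]])
  others <- which(m$bone == "femur" & m$image != 5)
  expect_false(any(vapply(out$flags[others], function(f)
    "length_outlier" %in% f, logical(1))))
  expect_identical(out$length_px, m$length_px)  # flags only, never values
})

test_that("violated adjacency flags abnormal_geometry on the affected bones", {
  m <- clean_measurements()
  # drag one mouse's tibia_L start far from its femur end
  i <- which(m$bone == "tibia" & m$side == "L" & m$image == 3)
  m$x_start[i] <- m$x_start[i] + 60
  m$length_px[i] <- sqrt((m$x_end[i] - m$x_start[i])^2 +
                         (m$y_end[i] - m$y_start[i])^2)
  out <- refine_measurements(m)
  expect_true("abnormal_geometry" %in% out$flags[[i]])
  j <- which(m$bone == "femur" & m$side == "L" & m$image == 3)
  expect_true("abnormal_geometry" %in% out$flags[[j]])
})

test_that("left/right asymmetry beyond the tolerance is flagged", {
  m <- clean_measurements()
  i <- which(m$bone == "pelvis" & m$side == "R" & m$image == 7)
  m$length_px[i] <- m$length_px[i] * 1.6
  out <- refine_measurements(m, k = 50)   # disable the outlier rule
  j <- which(m$bone == "pelvis" & m$image == 7)
  expect_true(all(vapply(out$flags[j], function(f)
    "abnormal_geometry" %in% f, logical(1))))
})

test_that("sparse bone classes skip the outlier rule with a warning", {
  m <- clean_measurements(1)
  w <- testthat::capture_warnings(refine_measurements(m))
  expect_true(any(grepl("fewer than 3", w)))   # one warning per sparse class
})
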