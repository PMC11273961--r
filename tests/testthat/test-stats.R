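# Evaluation statistics: keypoint MSE, count accuracy, correlation,
# residualization, variance F-test.

rand_kp <- function(seed) {
  set.seed(seed)
  keypoint_set(cbind(runif(12, 0, 100), runif(12, 0, 100)))
}

test_that("keypoint MSE on simple constructed cases", {
  g <- rand_kp(1)
  expect_equal(keypoint_mse(list(g), list(g)), 0)
  p <- g
  p$xy[1, ] <- p$xy[1, ] + c(0.1, 0.2)
  # only keypoint 1 differs: mean over 12 keypoints of (0.01 + 0.04)
  expect_equal(keypoint_mse(list(g), list(p)), 0.05 / 12, tolerance = 1e-12)
  # a single visible keypoint offset by (0.1, 0.2) gives 0.05 exactly
  g1 <- g; g1$visibility <- c(2L, rep(0L, 11))
  expect_equal(keypoint_mse(list(g1), list(p)), 0.05, tolerance = 1e-12)
})

test_that("keypoint MSE is symmetric and rejects empty matchings", {
  g <- rand_kp(2); p <- rand_kp(3)
  expect_equal(keypoint_mse(list(g), list(p)), keypoint_mse(list(p), list(g)))
  expect_error(keypoint_mse(list(g), list(p),
                            matching = matrix(integer(), 0, 2)), "no matched")
})

test_that("Monte-Carlo: Gaussian perturbation of sd sigma gives MSE ~ 2 sigma^2", {
  set.seed(7)
  sigma <- 0.8
  n <- 1000
  gt <- lapply(seq_len(n), function(i)
    keypoint_set(matrix(runif(24, 0, 200), 12, 2)))
  pred <- lapply(gt, function(kp) {
    kp$xy <- kp$xy + matrix(rnorm(24, 0, sigma), 12, 2)
    kp
  })
  mse <- keypoint_mse(gt, pred)
  expect_equal(mse, 2 * sigma^2, tolerance = 0.1)
})

test_that("objectness accuracy counts images with the correct mouse count", {
  det <- tibble::tibble(
    image = c(1L, 1L, 2L, 3L, 4L),
    mouse = c(1L, 2L, 1L, 1L, 1L),
    top_view_prob = c(0.9, 0.8, 0.9, 0.3, 0.9),
    x0 = 0, y0 = 0, x1 = 10, y1 = 10, keypoints = list(rand_kp(1))
  )
  # truth: 2, 1, 1, 1 mice -> image 3's only detection is filtered out
  expect_equal(objectness_accuracy(c(2L, 1L, 1L, 1L), det), 0.75)
  expect_equal(objectness_accuracy(c(2L, 1L, 0L, 1L), det), 1.0)
  expect_equal(objectness_accuracy(c(2L, 1L, 2L, 1L), det), 0.75)
  expect_equal(objectness_accuracy(c(9L, 9L, 9L, 9L), det), 0)
  det$top_view_prob[4] <- 0.8
  expect_equal(objectness_accuracy(c(2L, 1L, 1L, 1L), det), 1.0)
})

test_that("greedy IoU matching pairs best-overlapping boxes once", {
  truth <- list(c(0, 0, 10, 10), c(20, 20, 30, 30))
  pred <- list(c(21, 21, 31, 31), c(1, 1, 11, 11), c(100, 100, 110, 110))
  mm <- match_detections(truth, pred)
  expect_equal(nrow(mm), 2)
  expect_equal(mm[order(mm[, "truth"]), "pred"], c(2L, 1L), ignore_attr = TRUE)
})

test_that("correlation matches the direct-formula oracle and cor.test p-value", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  res <- correlate(x, y)
  expect_equal(res$r, pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(res$r_squared, res$r^2, tolerance = 1e-12)
  # two-sided p from the t transform, evaluated independently
  tstat <- res$r * sqrt((res$n - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), res$n - 2),
               tolerance = 1e-12)
})

test_that("correlation is exact under identity and affine maps", {
  set.seed(12)
  x <- rnorm(40)
  expect_equal(correlate(x, x)$r, 1, tolerance = 1e-12)
  res <- correlate(x, 2 * x + 3)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$slope, 2, tolerance = 1e-9)
  expect_equal(res$intercept, 3, tolerance = 1e-9)
  # invariance to positive affine transforms of either argument
  y <- x + rnorm(40, 0, 0.3)
  expect_equal(correlate(x, y)$r, correlate(10 * x - 2, 0.5 * y + 7)$r,
               tolerance = 1e-12)
  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("residualization removes the age/sex trend", {
  coh <- simulate_cohort(n = 300, seed = 4, noise_sd = 0.3)
  res <- residualize(coh, "tibia", "L")
  expect_equal(nrow(res), 300)
  for (sx in c("M", "F")) {
    expect_lt(abs(mean(res$residual[res$sex == sx])), 1e-8)
  }
  # residuals no longer correlate with age
  expect_lt(abs(cor(res$residual, res$age)), 0.1)
})

test_that("constant lengths within sex give all-zero residuals", {
  coh <- simulate_cohort(n = 60, seed = 5)
  coh$length <- ifelse(coh$sex == "M", 17, 15.5)
  res <- residualize(coh, "femur", "R")
  expect_lt(max(abs(res$residual)), 1e-8)
})

test_that("residualization recovers the injected noise sd within 10%", {
  coh <- simulate_cohort(n = 500, seed = 6, noise_sd = 0.4)
  res <- residualize(coh, "femur", "L")
  expect_equal(stats::sd(res$residual), 0.4, tolerance = 0.1)
})

test_that("residualization errors name the deficient stratum", {
  coh <- simulate_cohort(n = 100, seed = 7)
  expect_error(residualize(coh[coh$sex == "M", ], "tibia", "L"),
               "stratum 'F'")
})

test_that("variance F-test matches its definition and inverts cleanly", {
  set.seed(9)
  a <- rnorm(50)
  expect_equal(variance_f_test(a, a)$F, 1, tolerance = 1e-12)
  b <- 2 * a
  expect_equal(variance_f_test(a, b)$F, 0.25, tolerance = 1e-12)
  x <- rnorm(30); y <- rnorm(40, sd = 1.5)
  fw <- variance_f_test(x, y); bw <- variance_f_test(y, x)
  expect_equal(fw$F * bw$F, 1, tolerance = 1e-12)
  expect_equal(fw$p_value, bw$p_value, tolerance = 1e-12)
  expect_equal(fw$df1, 29); expect_equal(fw$df2, 39)
  expect_error(variance_f_test(x, rep(1, 10)), "zero variance")
  expect_error(variance_f_test(1:2, 1:5), "n >= 3")
})
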