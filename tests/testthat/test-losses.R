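# The combined detection objective against hand-computed oracles.

test_that("objectness loss matches hand-computed cross-entropy", {
  # perfect prediction at the clamp limit
  b <- loss_batch(y = 1, p = 1 - 1e-7)
  expect_lt(objectness_loss(b), 1e-6)
  # -(1/2) * (ln 0.8 + ln 0.7)
  b <- loss_batch(y = c(1, 0), p = c(0.8, 0.3))
  expect_equal(objectness_loss(b), -(log(0.8) + log(0.7)) / 2, tolerance = 1e-12)
  expect_equal(objectness_loss(b), 0.28990925, tolerance = 1e-7)
})

test_that("objectness loss is symmetric under label/score complement", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    y <- sample(0:1, n, replace = TRUE)
    p <- runif(n, 0.01, 0.99)
    expect_equal(objectness_loss(loss_batch(y = y, p = p)),
                 objectness_loss(loss_batch(y = 1 - y, p = 1 - p)),
                 tolerance = 1e-12)
  }
})

test_that("class loss matches hand-computed cross-entropy", {
  # one-hot prediction matching the label
  b <- loss_batch(Y = rbind(c(1, 0)), P = rbind(c(1 - 1e-7, 1e-7)))
  expect_lt(class_loss(b), 1e-6)
  # uniform distribution gives ln C exactly
  for (C in 2:5) {
    Y <- diag(C)
    P <- matrix(1 / C, C, C)
    expect_equal(class_loss(loss_batch(Y = Y, P = P)), log(C), tolerance = 1e-12)
  }
  # -(1/2) * (ln 0.9 + ln 0.8)
  b <- loss_batch(Y = rbind(c(1, 0), c(0, 1)),
                  P = rbind(c(0.9, 0.1), c(0.2, 0.8)))
  expect_equal(class_loss(b), -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_equal(class_loss(b), 0.16425203, tolerance = 1e-7)
})

test_that("keypoint loss is the per-box-normalised squared error", {
  mk <- function(pred, gt) {
    loss_batch(pred = array(pred, c(dim(pred)[1], dim(pred)[2], 2)),
               gt = array(gt, c(dim(gt)[1], dim(gt)[2], 2)))
  }
  p0 <- array(c(5, 7), c(1, 1, 2))
  expect_equal(keypoint_loss(loss_batch(pred = p0, gt = p0)), 0)
  # single keypoint offset by (3, 4) -> 25
  gt <- array(c(5, 7), c(1, 1, 2))
  pred <- array(c(5 + 3, 7 + 4), c(1, 1, 2))
  expect_equal(keypoint_loss(loss_batch(pred = pred, gt = gt)), 25)
  # N=2, K=2 with offsets {(1,0),(0,1)} and {(0,0),(2,0)} -> 3
  gt <- array(0, c(2, 2, 2))
  pred <- array(0, c(2, 2, 2))
  pred[1, 1, ] <- c(1, 0); pred[1, 2, ] <- c(0, 1); pred[2, 2, ] <- c(2, 0)
  expect_equal(keypoint_loss(loss_batch(pred = pred, gt = gt)), 3)
})

test_that("invisible keypoints are excluded while the divisor stays N", {
  gt <- array(0, c(1, 2, 2))
  pred <- array(0, c(1, 2, 2))
  pred[1, 1, ] <- c(3, 4)   # visible, contributes 25
  pred[1, 2, ] <- c(100, 100)  # masked out
  vis <- matrix(c(TRUE, FALSE), 1, 2)
  expect_equal(keypoint_loss(loss_batch(pred = pred, gt = gt, visible = vis)), 25)
})

test_that("total loss is the exact sum of its three components", {
  b <- loss_batch(
    y = c(1, 0), p = c(0.8, 0.3),
    Y = rbind(c(1, 0), c(0, 1)), P = rbind(c(0.9, 0.1), c(0.2, 0.8)),
    pred = array(c(1, 0, 0, 2, 0, 1, 0, 0), c(2, 2, 2)),
    gt = array(0, c(2, 2, 2))
  )
  expect_equal(total_loss(b),
               objectness_loss(b) + class_loss(b) + keypoint_loss(b),
               tolerance = 1e-15)
  expect_equal(total_loss(b),
               -(log(0.8) + log(0.7)) / 2 - (log(0.9) + log(0.8)) / 2 + 3,
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(1:5, 1)
    P <- matrix(runif(2 * n, 0.05, 1), n)
    P <- P / rowSums(P)
    Y <- t(vapply(seq_len(n), function(j) {
      z <- c(0, 0); z[sample(2, 1)] <- 1; z
    }, numeric(2)))
    b <- loss_batch(y = sample(0:1, n, TRUE), p = runif(n, 0.01, 0.99),
                    Y = Y, P = P,
                    pred = array(rnorm(n * 3 * 2), c(n, 3, 2)),
                    gt = array(rnorm(n * 3 * 2), c(n, 3, 2)))
    expect_equal(total_loss(b),
                 objectness_loss(b) + class_loss(b) + keypoint_loss(b))
    expect_gte(objectness_loss(b), 0)
    expect_gte(class_loss(b), 0)
    expect_gte(keypoint_loss(b), 0)
  }
})

test_that("objectness loss equals binary class loss on matching encodings", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(1:6, 1)
    y <- sample(0:1, n, replace = TRUE)
    p <- runif(n, 0.05, 0.95)
    Y <- cbind(1 - y, y)
    P <- cbind(1 - p, p)
    expect_equal(objectness_loss(loss_batch(y = y, p = p)),
                 class_loss(loss_batch(Y = Y, P = P)), tolerance = 1e-12)
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(41)
  fd <- function(f, x, eps = 1e-6) {
    vapply(seq_along(x), function(i) {
      x1 <- x; x1[i] <- x1[i] + eps
      x2 <- x; x2[i] <- x2[i] - eps
      (f(x1) - f(x2)) / (2 * eps)
    }, numeric(1))
  }
  n <- 4
  y <- sample(0:1, n, replace = TRUE)
  p <- runif(n, 0.1, 0.9)
  g <- bonemorph:::objectness_loss_grad(loss_batch(y = y, p = p))
  expect_equal(g, fd(function(v) objectness_loss(loss_batch(y = y, p = v)), p),
               tolerance = 1e-4)
  P <- matrix(runif(n * 3, 0.1, 1), n); P <- P / rowSums(P)
  Y <- t(apply(P, 1, function(z) { o <- numeric(3); o[which.max(z)] <- 1; o }))
  gP <- bonemorph:::class_loss_grad(loss_batch(Y = Y, P = P))
  # perturb entries without renormalising: the gradient is of the raw formula
  fP <- function(v) {
    b <- loss_batch(Y = Y, P = P)
    b$P <- matrix(v, n)
    class_loss(b)
  }
  expect_equal(as.vector(gP), fd(fP, as.vector(P)), tolerance = 1e-4)
  pred <- array(rnorm(n * 2 * 2), c(n, 2, 2))
  gt <- array(rnorm(n * 2 * 2), c(n, 2, 2))
  b <- loss_batch(pred = pred, gt = gt)
  gk <- bonemorph:::keypoint_loss_grad(b)
  fk <- function(v) keypoint_loss(loss_batch(pred = array(v, dim(pred)), gt = gt))
  expect_equal(as.vector(gk), fd(fk, as.vector(pred)), tolerance = 1e-4)
})

test_that("degenerate batches are rejected", {
  expect_error(loss_batch(), "N >= 1")
  expect_error(loss_batch(y = c(1, 0.5), p = c(0.5, 0.5)), "0 or 1")
  expect_error(loss_batch(Y = rbind(c(1, 1)), P = rbind(c(0.5, 0.5))), "one-hot")
  expect_error(loss_batch(Y = rbind(c(1, 0)), P = rbind(c(0.9, 0.3))), "sum to 1")
  b <- loss_batch(y = 1, p = 0.5)
  expect_error(class_loss(b), "no class labels")
  expect_error(keypoint_loss(b), "no keypoint")
})
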