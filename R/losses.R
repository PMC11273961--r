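# Combined detection objective: objectness cross-entropy over predicted boxes,
# per-class cross-entropy, and coordinate mean squared keypoint error. Each
# component is implemented exactly as defined and unit-tested against
# hand-computed oracles; probabilities are clamped to [eps, 1-eps] before logs.

LOSS_EPS <- 1e-7

#' Assemble a loss batch
#'
#' Houses every quantity of the combined detection loss for `N` predicted
#' boxes: binary objectness labels and scores, one-hot class labels with
#' predicted class probabilities, and predicted/ground-truth keypoint
#' coordinates.
#'
#' @param y numeric vector of `N` objectness labels in `{0, 1}`.
#' @param p numeric vector of `N` predicted objectness scores in `(0, 1)`
#'   (clamped to `[1e-7, 1 - 1e-7]`).
#' @param Y `N x C` one-hot class label matrix.
#' @param P `N x C` predicted class probability matrix (rows sum to 1).
#' @param pred,gt `N x K x 2` arrays of predicted and ground-truth keypoint
#'   coordinates.
#' @param visible optional `N x K` logical matrix; invisible keypoints are
#'   excluded from the keypoint sum (the divisor stays `N`).
#' @return object of class `loss_batch`.
#' @export
loss_batch <- function(y = NULL, p = NULL, Y = NULL, P = NULL,
                       pred = NULL, gt = NULL, visible = NULL) {
  n <- max(length(y), NROW(Y), if (is.null(pred)) 0 else dim(pred)[1])
  if (n < 1) stop("a loss batch needs N >= 1 predicted boxes", call. = FALSE)
  if (!is.null(y)) {
    if (any(!y %in% c(0, 1))) stop("objectness labels must be 0 or 1", call. = FALSE)
    if (length(p) != length(y)) stop("`p` must match `y` in length", call. = FALSE)
    p <- pmin(pmax(p, LOSS_EPS), 1 - LOSS_EPS)
  }
  if (!is.null(Y)) {
    Y <- as.matrix(Y); P <- as.matrix(P)
    if (!all(dim(Y) == dim(P))) stop("`Y` and `P` must have equal dimensions", call. = FALSE)
    if (any(abs(rowSums(P) - 1) > 1e-6)) {
      stop("rows of `P` must sum to 1 within 1e-6", call. = FALSE)
    }
    if (any(rowSums(Y == 1) != 1) || any(!Y %in% c(0, 1))) {
      stop("rows of `Y` must be one-hot", call. = FALSE)
    }
    P <- pmin(pmax(P, LOSS_EPS), 1 - LOSS_EPS)
  }
  if (!is.null(pred)) {
    if (length(dim(pred)) != 3 || !all(dim(pred) == dim(gt)) || dim(pred)[3] != 2) {
      stop("`pred` and `gt` must be N x K x 2 arrays of equal shape", call. = FALSE)
    }
    if (is.null(visible)) visible <- matrix(TRUE, dim(pred)[1], dim(pred)[2])
  }
  structure(list(N = n, y = y, p = p, Y = Y, P = P,
                 pred = pred, gt = gt, visible = visible),
            class = "loss_batch")
}

#' Objectness loss
#'
#' Mean binary cross-entropy between objectness labels and predicted
#' objectness scores over the `N` predicted boxes:
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`.
#'
#' @param batch a [loss_batch()] with `y` and `p` set.
#' @return non-negative scalar.
#' @export
objectness_loss <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  if (is.null(batch$y)) stop("batch has no objectness labels", call. = FALSE)
  -mean(batch$y * log(batch$p) + (1 - batch$y) * log(1 - batch$p))
}

# d objectness_loss / d p
objectness_loss_grad <- function(batch) {
  (-batch$y / batch$p + (1 - batch$y) / (1 - batch$p)) / length(batch$y)
}

#' Class loss
#'
#' Mean categorical cross-entropy between one-hot class labels and predicted
#' class probabilities: `-(1/N) * sum_i sum_c Y[i,c] * log(P[i,c])`.
#'
#' @param batch a [loss_batch()] with `Y` and `P` set.
#' @return non-negative scalar.
#' @export
class_loss <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  if (is.null(batch$Y)) stop("batch has no class labels", call. = FALSE)
  -sum(batch$Y * log(batch$P)) / nrow(batch$Y)
}

# d class_loss / d P
class_loss_grad <- function(batch) {
  -(batch$Y / batch$P) / nrow(batch$Y)
}

#' Keypoint loss
#'
#' Coordinate mean squared error: `(1/N) * sum_i sum_k ||pred[i,k] -
#' gt[i,k]||^2` over supervised (visible) keypoints; the divisor is the number
#' of boxes `N`, not `N * K`. Implemented with positive sign.
#'
#' @param batch a [loss_batch()] with `pred`, `gt` (and optionally `visible`).
#' @return non-negative scalar.
#' @export
keypoint_loss <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  if (is.null(batch$pred)) stop("batch has no keypoint coordinates", call. = FALSE)
  d2 <- (batch$pred - batch$gt)^2
  sq <- d2[, , 1, drop = FALSE] + d2[, , 2, drop = FALSE]
  sum(sq[, , 1][batch$visible]) / dim(batch$pred)[1]
}

# d keypoint_loss / d pred (N x K x 2 array)
keypoint_loss_grad <- function(batch) {
  g <- 2 * (batch$pred - batch$gt) / dim(batch$pred)[1]
  mask <- array(rep(batch$visible, 2), dim = dim(g))
  g * mask
}

#' Total loss
#'
#' Sum of the objectness, class and keypoint losses; components whose inputs
#' are absent from the batch contribute zero.
#'
#' @param batch a [loss_batch()].
#' @return scalar.
#' @export
total_loss <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  total <- 0
  if (!is.null(batch$y)) total <- total + objectness_loss(batch)
  if (!is.null(batch$Y)) total <- total + class_loss(batch)
  if (!is.null(batch$pred)) total <- total + keypoint_loss(batch)
  total
}
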