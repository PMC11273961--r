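# Training-time augmentation applied identically to image, boxes and
# keypoints. Horizontal and vertical flips mirror the image and therefore
# exchange anatomical left and right: the sided keypoint labels are swapped
# so supervision stays anatomically correct.

#' Augmentation configuration
#'
#' @param shift_limit maximum |shift| as a fraction of the image side.
#' @param scale_limit maximum |scale - 1|.
#' @param rotate_limit maximum |rotation| in degrees.
#' @param p_ssr probability of applying the shift-scale-rotate transform.
#' @param p_hflip,p_vflip flip probabilities.
#' @param brightness_limit,contrast_limit maximum photometric adjustments.
#' @param integer_shift maximum absolute integer pixel translation applied as
#'   an exact (interpolation-free) shift; diversifies the sub-cell phase of
#'   keypoints relative to the detector's feature grid. 0 disables.
#' @param fill constant intensity used outside the source frame.
#' @param seed optional integer; when given, the augmentation draws from a
#'   private deterministic stream.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(shift_limit = 0.0625, scale_limit = 0.1,
                           rotate_limit = 15, p_ssr = 0.5,
                           p_hflip = 0.5, p_vflip = 0.5,
                           brightness_limit = 0.2, contrast_limit = 0.2,
                           integer_shift = 0L, fill = 0, seed = NULL) {
  probs <- c(p_ssr, p_hflip, p_vflip)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  lims <- c(shift_limit, scale_limit, rotate_limit, brightness_limit, contrast_limit)
  if (any(lims < 0)) stop("limits must be >= 0", call. = FALSE)
  structure(list(shift_limit = shift_limit, scale_limit = scale_limit,
                 rotate_limit = rotate_limit, p_ssr = p_ssr,
                 p_hflip = p_hflip, p_vflip = p_vflip,
                 brightness_limit = brightness_limit,
                 contrast_limit = contrast_limit,
                 integer_shift = as.integer(integer_shift),
                 fill = fill, seed = seed),
            class = "augment_config")
}

# inverse-affine bilinear warp; M maps output pixel coords to source coords
warp_affine <- function(img, M, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), w)
  sx <- M[1, 1] * xs + M[1, 2] * ys + M[1, 3]
  sy <- M[2, 1] * xs + M[2, 2] * ys + M[2, 3]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  get_px <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
    v <- rep(fill, length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  v <- get_px(x0, y0) * (1 - fx) * (1 - fy) + get_px(x0 + 1, y0) * fx * (1 - fy) +
    get_px(x0, y0 + 1) * (1 - fx) * fy + get_px(x0 + 1, y0 + 1) * fx * fy
  matrix(v, h, w)
}

affine_apply <- function(A, xy) {
  cbind(A[1, 1] * xy[, 1] + A[1, 2] * xy[, 2] + A[1, 3],
        A[2, 1] * xy[, 1] + A[2, 2] * xy[, 2] + A[2, 3])
}

transform_box <- function(A, box) {
  corners <- rbind(c(box[1], box[2]), c(box[3], box[2]),
                   c(box[1], box[4]), c(box[3], box[4]))
  tc <- affine_apply(A, corners)
  c(min(tc[, 1]), min(tc[, 2]), max(tc[, 1]), max(tc[, 2]))
}

#' Augment an image with its annotations
#'
#' Applies (with the configured probabilities) a shift-scale-rotate affine
#' transform, horizontal and vertical flips and photometric brightness /
#' contrast jitter. Geometric transforms act identically on the raster, the
#' boxes and the keypoints; flips additionally swap the left/right landmark
#' labels; keypoints transformed outside the frame are marked invisible;
#' photometric transforms never touch coordinates. A degenerate configuration
#' (all limits and probabilities zero) is the identity.
#'
#' @param image `[0, 1]` grayscale matrix.
#' @param keypoint_sets list of [keypoint_set()] objects.
#' @param boxes list of `c(x0, y0, x1, y1)` boxes.
#' @param config an [augment_config()].
#' @return list with elements `image`, `keypoint_sets`, `boxes`.
#' @export
augment <- function(image, keypoint_sets, boxes, config = augment_config()) {
  stopifnot(inherits(config, "augment_config"))
  run <- function() augment_impl(image, keypoint_sets, boxes, config)
  if (!is.null(config$seed)) with_seed(config$seed, run()) else run()
}

augment_impl <- function(image, kps, boxes, cfg) {
  h <- nrow(image); w <- ncol(image)
  # forward affine accumulated over flips and shift-scale-rotate
  A <- diag(3)
  swap_sides <- FALSE
  if (cfg$p_hflip > 0 && stats::runif(1) < cfg$p_hflip) {
    A <- rbind(c(-1, 0, w - 1), c(0, 1, 0), c(0, 0, 1)) %*% A
    swap_sides <- !swap_sides
  }
  if (cfg$p_vflip > 0 && stats::runif(1) < cfg$p_vflip) {
    A <- rbind(c(1, 0, 0), c(0, -1, h - 1), c(0, 0, 1)) %*% A
    swap_sides <- !swap_sides
  }
  if (cfg$p_ssr > 0 && stats::runif(1) < cfg$p_ssr) {
    ang <- deg2rad(stats::runif(1, -cfg$rotate_limit, cfg$rotate_limit))
    s <- 1 + stats::runif(1, -cfg$scale_limit, cfg$scale_limit)
    tx <- stats::runif(1, -cfg$shift_limit, cfg$shift_limit) * w
    ty <- stats::runif(1, -cfg$shift_limit, cfg$shift_limit) * h
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    R <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang))) * s
    t_vec <- c(cx + tx, cy + ty) - R %*% c(cx, cy)
    A <- rbind(cbind(R, t_vec), c(0, 0, 1)) %*% A
  }
  identity_A <- all(abs(A - diag(3)) < 1e-12)
  if (!identity_A) {
    image <- warp_affine(image, solve(A), fill = cfg$fill)
    boxes <- lapply(boxes, transform_box, A = A)
    kps <- lapply(kps, function(kp) {
      xy <- affine_apply(A, kp$xy)
      vis <- kp$visibility
      out <- xy[, 1] < 0 | xy[, 1] > (w - 1) | xy[, 2] < 0 | xy[, 2] > (h - 1)
      vis[out] <- 0L
      xy[out, ] <- 0
      keypoint_set(xy, vis, kp$scores)
    })
  }
  if ((cfg$integer_shift %||% 0L) > 0L) {
    # exact translation: no interpolation, integer ground truth preserved
    dx <- sample(-cfg$integer_shift:cfg$integer_shift, 1)
    dy <- sample(-cfg$integer_shift:cfg$integer_shift, 1)
    if (dx != 0 || dy != 0) {
      shifted <- matrix(cfg$fill, h, w)
      src_r <- max(1, 1 - dy):min(h, h - dy)
      src_c <- max(1, 1 - dx):min(w, w - dx)
      shifted[src_r + dy, src_c + dx] <- image[src_r, src_c]
      image <- shifted
      boxes <- lapply(boxes, function(b) b + c(dx, dy, dx, dy))
      kps <- lapply(kps, function(kp) {
        xy <- kp$xy + rep(c(dx, dy), each = 12)
        vis <- kp$visibility
        out <- xy[, 1] < 0 | xy[, 1] > (w - 1) | xy[, 2] < 0 | xy[, 2] > (h - 1)
        vis[out] <- 0L
        xy[out, ] <- 0
        keypoint_set(xy, vis, kp$scores)
      })
    }
  }
  if (swap_sides) {
    perm <- kp_side_swap()
    kps <- lapply(kps, function(kp) {
      keypoint_set(kp$xy[perm, , drop = FALSE], kp$visibility[perm],
                   if (is.null(kp$scores)) NULL else kp$scores[perm])
    })
  }
  if (cfg$brightness_limit > 0) {
    image <- image + stats::runif(1, -cfg$brightness_limit, cfg$brightness_limit)
  }
  if (cfg$contrast_limit > 0) {
    a <- 1 + stats::runif(1, -cfg$contrast_limit, cfg$contrast_limit)
    image <- (image - 0.5) * a + 0.5
  }
  image <- pmin(pmax(image, 0), 1)
  list(image = image, keypoint_sets = kps, boxes = boxes)
}
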