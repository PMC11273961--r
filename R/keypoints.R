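#' Canonical keypoint scheme
#'
#' Twelve named anatomical landmarks per mouse: the start and end of the
#' tibia, femur and pelvis on the left and right side, in a fixed canonical
#' order (all left-side landmarks first). All pixel coordinates in the package
#' are 0-based, origin at the top-left corner, x rightward, y downward; boxes
#' are half-open `[x0, x1) x [y0, y1)`.
#'
#' @return `keypoint_names()` returns the character vector of the 12 canonical
#'   landmark names in order.
#' @export
keypoint_names <- function() {
  as.vector(vapply(c("L", "R"), function(side) {
    vapply(c("tibia", "femur", "pelvis"), function(bone) {
      paste0(bone, "_", side, c("_start", "_end"))
    }, character(2))
  }, character(6)))
}

#' @rdname keypoint_names
#' @return `keypoint_bones()` returns a tibble mapping each landmark index to
#'   its bone, side and endpoint role.
#' @export
keypoint_bones <- function() {
  tibble::tibble(
    index = 1:12,
    name  = keypoint_names(),
    bone  = rep(rep(c("tibia", "femur", "pelvis"), each = 2), 2),
    side  = rep(c("L", "R"), each = 6),
    role  = rep(c("start", "end"), 6)
  )
}

# index permutation that exchanges left and right landmarks
kp_side_swap <- function() c(7:12, 1:6)

#' Skeleton edge list for COCO export
#'
#' Edges connect the start and end landmark of each bone (1-based indices
#' into the canonical order).
#' @return integer matrix with one row per bone, columns `from` and `to`.
#' @export
keypoint_skeleton <- function() {
  m <- cbind(from = seq(1, 11, by = 2), to = seq(2, 12, by = 2))
  m
}

#' Construct a keypoint set
#'
#' A `keypoint_set` holds the 12 canonical landmark coordinates of one mouse,
#' their visibility flags and (optionally) per-landmark confidence scores.
#' Visibility follows the COCO convention: 0 = absent, 1 = labeled but not
#' visible, 2 = visible; flags 1 and 2 are both treated as supervised.
#'
#' @param xy numeric 12 x 2 matrix of (x, y) pixel coordinates.
#' @param visibility integer vector of length 12 with values in 0:2.
#' @param scores optional numeric vector of length 12 with values in `[0, 1]`.
#' @return an object of class `keypoint_set`.
#' @export
keypoint_set <- function(xy, visibility = rep(2L, 12), scores = NULL) {
  xy <- as.matrix(xy)
  if (!is.numeric(xy) || nrow(xy) != 12 || ncol(xy) != 2) {
    stop("`xy` must be a numeric 12 x 2 matrix", call. = FALSE)
  }
  visibility <- as.integer(visibility)
  if (length(visibility) != 12 || any(!visibility %in% 0:2)) {
    stop("`visibility` must be 12 flags in {0, 1, 2}", call. = FALSE)
  }
  vis <- visibility > 0
  if (any(vis & (!is.finite(xy[, 1]) | !is.finite(xy[, 2])))) {
    stop("visible keypoints must have finite coordinates", call. = FALSE)
  }
  if (any(vis & (xy[, 1] < 0 | xy[, 2] < 0))) {
    stop("visible keypoints must have non-negative coordinates", call. = FALSE)
  }
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != 12 || any(scores < 0 | scores > 1, na.rm = TRUE)) {
      stop("`scores` must be 12 confidences in [0, 1]", call. = FALSE)
    }
  }
  dimnames(xy) <- list(keypoint_names(), c("x", "y"))
  structure(list(xy = xy, visibility = visibility, scores = scores),
            class = "keypoint_set")
}

#' @export
format.keypoint_set <- function(x, ...) {
  n_vis <- sum(x$visibility > 0)
  sprintf("<keypoint_set: %d/12 visible>", n_vis)
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(format(x), "\n")
  df <- as_tibble(x)
  print(df, n = 12)
  invisible(x)
}

#' Convert a keypoint set to a tibble
#'
#' @param x a `keypoint_set`.
#' @param ... unused.
#' @return tibble with one row per landmark: name, bone, side, role, x, y,
#'   visibility and score.
#' @method as_tibble keypoint_set
#' @export
as_tibble.keypoint_set <- function(x, ...) {
  out <- keypoint_bones()
  out$x <- x$xy[, 1]
  out$y <- x$xy[, 2]
  out$visibility <- x$visibility
  out$score <- if (is.null(x$scores)) NA_real_ else x$scores
  out
}

# Euclidean lengths of the six bones of a keypoint_set; NA where an endpoint
# is not supervised.
kp_bone_lengths <- function(kp) {
  info <- keypoint_skeleton()
  lengths <- vapply(seq_len(nrow(info)), function(i) {
    a <- info[i, 1]; b <- info[i, 2]
    if (kp$visibility[a] == 0 || kp$visibility[b] == 0) return(NA_real_)
    sqrt(sum((kp$xy[a, ] - kp$xy[b, ])^2))
  }, numeric(1))
  tibble::tibble(
    bone = rep(c("tibia", "femur", "pelvis"), 2),
    side = rep(c("L", "R"), each = 3),
    length_px = lengths
  )
}
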