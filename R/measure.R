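# Post-processing: keep confident top-view detections, map keypoints to bone
# endpoints, compute lengths, and flag (never delete) suspicious records.

#' Filter detections by top-view probability
#'
#' Retains exactly the detections whose top-view probability is strictly
#' greater than the threshold; order is preserved and the operation is
#' idempotent.
#'
#' @param detections detections tibble from [detect_mice()].
#' @param threshold probability threshold in `[0, 1]` (default 0.5).
#' @return filtered detections tibble.
#' @export
filter_detections <- function(detections, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  }
  dplyr::filter(detections, .data$top_view_prob > threshold)
}

#' Measure bone lengths from detected keypoints
#'
#' Produces one measurement per (detection, bone, side) using the canonical
#' keypoint ordering: length is the Euclidean distance between the bone's
#' start and end landmarks. Keypoints scored below `score_threshold` flag the
#' measurement `low_confidence`; a missing (invisible) endpoint yields a
#' record with `NA` length and the `abnormal_geometry` flag; coincident
#' endpoints yield length 0 with `abnormal_geometry`.
#'
#' @param detections detections tibble from [detect_mice()] (typically after
#'   [filter_detections()]).
#' @param score_threshold per-keypoint confidence below which a measurement is
#'   flagged `low_confidence`.
#' @return tibble with one row per (image, mouse, bone, side): endpoint
#'   coordinates, `length_px`, `top_view_prob` and list-column `flags`.
#' @export
measure_bones <- function(detections, score_threshold = 0.2) {
  if (!nrow(detections)) return(empty_measurements())
  purrr::pmap_dfr(
    list(detections$image, detections$mouse, detections$top_view_prob,
         detections$keypoints),
    function(image, mouse, tvp, kp) {
      info <- keypoint_bones()
      starts <- which(info$role == "start")
      purrr::map_dfr(starts, function(i) {
        j <- i + 1L
        vis_ok <- kp$visibility[i] > 0 && kp$visibility[j] > 0
        p0 <- kp$xy[i, ]; p1 <- kp$xy[j, ]
        flags <- character(0)
        if (!is.null(kp$scores) &&
            any(c(kp$scores[i], kp$scores[j]) < score_threshold, na.rm = TRUE)) {
          flags <- c(flags, "low_confidence")
        }
        if (!vis_ok) {
          len <- NA_real_
          flags <- c(flags, "abnormal_geometry")
          p0 <- c(NA_real_, NA_real_); p1 <- c(NA_real_, NA_real_)
        } else {
          len <- sqrt(sum((p1 - p0)^2))
          if (len == 0) flags <- c(flags, "abnormal_geometry")
        }
        tibble::tibble(
          image = image, mouse = mouse, bone = info$bone[i], side = info$side[i],
          x_start = unname(p0[1]), y_start = unname(p0[2]),
          x_end = unname(p1[1]), y_end = unname(p1[2]),
          length_px = unname(len), top_view_prob = tvp,
          flags = list(unique(flags))
        )
      })
    }
  )
}

empty_measurements <- function() {
  tibble::tibble(image = integer(), mouse = integer(), bone = character(),
                 side = character(), x_start = numeric(), y_start = numeric(),
                 x_end = numeric(), y_end = numeric(), length_px = numeric(),
                 top_view_prob = numeric(), flags = list())
}

add_flag <- function(flags, idx, flag) {
  flags[idx] <- lapply(flags[idx], function(f) unique(c(f, flag)))
  flags
}

#' Flag outliers and abnormal bone geometry
#'
#' Applies three reproducible quality rules without ever altering length
#' values or deleting records:
#' * `length_outlier`: `|length - median| > k * MAD` within a bone class
#'   (median/MAD from the batch's unflagged records, or from `reference`);
#'   skipped with a warning when fewer than 3 unflagged lengths exist.
#' * `abnormal_geometry` (adjacency): a femur whose start lies farther than
#'   `r` pixels from the ipsilateral pelvis end, or a tibia farther than `r`
#'   from the femur end (default `r` = half the median femur length).
#' * `abnormal_geometry` (symmetry): left/right lengths of the same bone in
#'   the same mouse differing by more than fraction `a` of their mean.
#'
#' @param measurements tibble from [measure_bones()].
#' @param reference optional tibble (`bone`, `median`, `mad`) of per-bone
#'   reference statistics; computed from the batch when `NULL`.
#' @param k MAD multiplier for the outlier rule.
#' @param r adjacency radius in pixels (`NULL` = `0.5 *` median femur length).
#' @param a maximal tolerated left/right relative difference.
#' @return the measurements tibble with updated `flags`.
#' @export
refine_measurements <- function(measurements, reference = NULL, k = 5,
                                r = NULL, a = 0.25) {
  m <- measurements
  if (!nrow(m)) return(m)
  flags <- m$flags
  pre_flagged <- vapply(flags, function(f) length(f) > 0, logical(1))

  if (is.null(reference)) {
    ok <- !pre_flagged & !is.na(m$length_px)
    reference <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(bone = m$bone[ok], length = m$length_px[ok]),
                      .data$bone),
      n = dplyr::n(), median = stats::median(.data$length),
      mad = stats::mad(.data$length), .groups = "drop")
  } else {
    reference$n <- Inf
  }
  for (b in unique(m$bone)) {
    ref <- reference[reference$bone == b, ]
    idx <- which(m$bone == b & !is.na(m$length_px))
    if (!nrow(ref) || ref$n < 3) {
      warning("fewer than 3 unflagged ", b,
              " lengths: outlier rule skipped for this bone class")
      next
    }
    out <- idx[abs(m$length_px[idx] - ref$median) > k * ref$mad]
    flags <- add_flag(flags, out, "length_outlier")
  }

  med_femur <- stats::median(m$length_px[m$bone == "femur"], na.rm = TRUE)
  if (is.null(r)) r <- 0.5 * med_femur
  key <- paste(m$image, m$mouse, m$side)
  for (gk in unique(key)) {
    rows <- which(key == gk)
    get_row <- function(bone) rows[m$bone[rows] == bone]
    pe <- get_row("pelvis"); fe <- get_row("femur"); ti <- get_row("tibia")
    dist_ok <- function(i_end, j_start) {
      p <- c(m$x_end[i_end], m$y_end[i_end])
      q <- c(m$x_start[j_start], m$y_start[j_start])
      if (any(is.na(c(p, q)))) return(TRUE)   # handled by missing-endpoint flag
      sqrt(sum((p - q)^2)) <= r
    }
    if (length(pe) && length(fe) && is.finite(r) && !dist_ok(pe, fe)) {
      flags <- add_flag(flags, c(pe, fe), "abnormal_geometry")
    }
    if (length(fe) && length(ti) && is.finite(r) && !dist_ok(fe, ti)) {
      flags <- add_flag(flags, c(fe, ti), "abnormal_geometry")
    }
  }

  mouse_key <- paste(m$image, m$mouse)
  for (gk in unique(mouse_key)) {
    for (b in unique(m$bone)) {
      rows <- which(mouse_key == gk & m$bone == b)
      lens <- m$length_px[rows]
      if (length(rows) == 2 && !any(is.na(lens)) && mean(lens) > 0) {
        if (abs(lens[1] - lens[2]) / mean(lens) > a) {
          flags <- add_flag(flags, rows, "abnormal_geometry")
        }
      }
    }
  }
  m$flags <- flags
  m
}
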