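# Evaluation and cohort statistics: keypoint MSE, objectness (mouse-count)
# accuracy, manual-versus-automated correlation, age/sex residualization and
# variance comparison by F-test.

#' Greedy IoU matching of predicted to ground-truth boxes
#'
#' @param truth_boxes,pred_boxes lists of `c(x0, y0, x1, y1)` boxes.
#' @param iou_threshold minimum intersection-over-union for a match.
#' @return integer matrix with columns `truth`, `pred` (indices), one row per
#'   matched pair; pairs are assigned greedily by descending IoU.
#' @export
match_detections <- function(truth_boxes, pred_boxes, iou_threshold = 0.5) {
  if (!length(truth_boxes) || !length(pred_boxes)) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("truth", "pred"))))
  }
  iou <- outer(seq_along(truth_boxes), seq_along(pred_boxes),
               Vectorize(function(i, j) box_iou(truth_boxes[[i]], pred_boxes[[j]])))
  pairs <- which(iou > iou_threshold, arr.ind = TRUE)
  if (!nrow(pairs)) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("truth", "pred"))))
  }
  pairs <- pairs[order(iou[pairs], decreasing = TRUE), , drop = FALSE]
  used_t <- logical(length(truth_boxes)); used_p <- logical(length(pred_boxes))
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs[r, 1]; pi <- pairs[r, 2]
    if (!used_t[ti] && !used_p[pi]) {
      used_t[ti] <- TRUE; used_p[pi] <- TRUE
      out[[length(out) + 1]] <- c(ti, pi)
    }
  }
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("truth", "pred"))
  m
}

#' Keypoint mean squared error
#'
#' Mean, over all matched visible keypoints, of the squared Euclidean pixel
#' distance between ground-truth and predicted coordinates. Symmetric in its
#' two arguments.
#'
#' @param gt,pred lists of [keypoint_set()] objects. When `matching` is
#'   `NULL`, `gt[[i]]` is paired with `pred[[i]]`.
#' @param matching optional 2-column index matrix (`truth`, `pred`) as
#'   returned by [match_detections()].
#' @return non-negative scalar.
#' @export
keypoint_mse <- function(gt, pred, matching = NULL) {
  if (is.null(matching)) {
    if (length(gt) != length(pred)) {
      stop("`gt` and `pred` must have equal length when `matching` is NULL",
           call. = FALSE)
    }
    matching <- cbind(seq_along(gt), seq_along(pred))
  }
  if (!nrow(matching)) stop("no matched pairs: keypoint MSE undefined", call. = FALSE)
  sq <- numeric(0)
  for (r in seq_len(nrow(matching))) {
    g <- gt[[matching[r, 1]]]; p <- pred[[matching[r, 2]]]
    vis <- g$visibility > 0 & p$visibility > 0
    d <- (g$xy[vis, , drop = FALSE] - p$xy[vis, , drop = FALSE])^2
    sq <- c(sq, rowSums(d))
  }
  if (!length(sq)) stop("no visible matched keypoints", call. = FALSE)
  mean(sq)
}

# keypoint MSE of a detections tibble against ground-truth samples,
# matching detections to truth by IoU > 0.5; mean over all matched visible
# keypoints across the whole set
keypoint_mse_samples <- function(samples, detections, iou_threshold = 0.5) {
  total <- 0; n <- 0
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    det_i <- detections[detections$image == i, , drop = FALSE]
    if (!length(s$boxes) || !nrow(det_i)) next
    pred_boxes <- lapply(seq_len(nrow(det_i)), function(r) {
      c(det_i$x0[r], det_i$y0[r], det_i$x1[r], det_i$y1[r])
    })
    mm <- match_detections(s$boxes, pred_boxes, iou_threshold)
    for (r in seq_len(nrow(mm))) {
      g <- s$keypoint_sets[[mm[r, 1]]]; p <- det_i$keypoints[[mm[r, 2]]]
      vis <- g$visibility > 0 & p$visibility > 0
      d <- rowSums((g$xy[vis, , drop = FALSE] - p$xy[vis, , drop = FALSE])^2)
      total <- total + sum(d); n <- n + length(d)
    }
  }
  if (n == 0) stop("no matched detections: keypoint MSE undefined", call. = FALSE)
  total / n
}

#' Objectness (mouse-count) accuracy
#'
#' Fraction of images whose retained-detection count — after
#' [filter_detections()] at the given threshold — equals the true mouse
#' count.
#'
#' @param truth either a list of `synthetic_scene`s / training samples, or an
#'   integer vector of per-image true mouse counts.
#' @param detections detections tibble from [detect_mice()] (unfiltered).
#' @param threshold top-view probability threshold.
#' @return fraction in `[0, 1]`.
#' @export
objectness_accuracy <- function(truth, detections, threshold = 0.5) {
  counts <- if (is.numeric(truth)) as.integer(truth) else {
    vapply(truth, function(s) {
      if (inherits(s, "synthetic_scene")) length(s$mice)
      else sum((s$views %||% "top") == "top")
    }, integer(1))
  }
  kept <- filter_detections(detections, threshold)
  pred <- integer(length(counts))
  if (nrow(kept)) {
    tab <- dplyr::count(kept, .data$image)
    pred[tab$image] <- tab$n
  }
  mean(pred == counts)
}

#' Correlation between manual and automated lengths
#'
#' Pearson correlation with the two-sided p-value from the t transform, plus
#' the least-squares regression line for reporting.
#'
#' @param manual,automated paired numeric vectors (n >= 3, finite).
#' @return one-row tibble: `r`, `r_squared`, `p_value`, `n`, `slope`,
#'   `intercept`.
#' @export
correlate <- function(manual, automated) {
  ok <- is.finite(manual) & is.finite(automated)
  manual <- manual[ok]; automated <- automated[ok]
  if (length(manual) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(manual) == 0 || stats::sd(automated) == 0) {
    stop("correlation undefined: zero variance in one of the inputs",
         call. = FALSE)
  }
  ct <- stats::cor.test(manual, automated, method = "pearson")
  fit <- stats::lm.fit(cbind(1, manual), automated)
  tibble::tibble(
    r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value, n = length(manual),
    slope = unname(fit$coefficients[2]), intercept = unname(fit$coefficients[1])
  )
}

#' Age- and sex-adjusted bone-length residuals
#'
#' Fits, separately per sex, a penalized-spline smooth of length against age
#' and returns the residual (observed minus expected-for-age-and-sex) for
#' every record. Residuals have mean zero within each sex.
#'
#' @param records cohort tibble with columns `age`, `sex`, `bone`, `side`,
#'   `length` (as from [simulate_cohort()]).
#' @param bone,side the bone class to residualize.
#' @param df spline basis dimension (upper bound on the smooth's degrees of
#'   freedom).
#' @param min_per_sex minimum records required per sex.
#' @return the selected records with added columns `expected` and `residual`.
#' @export
residualize <- function(records, bone, side, df = 6, min_per_sex = 20) {
  sel <- records[records$bone == bone & records$side == side, , drop = FALSE]
  out <- list()
  for (sx in c("M", "F")) {
    part <- sel[sel$sex == sx, , drop = FALSE]
    if (nrow(part) < min_per_sex) {
      stop("insufficient records for sex stratum '", sx, "' (",
           nrow(part), " < ", min_per_sex, ")", call. = FALSE)
    }
    n_age <- length(unique(part$age))
    if (n_age < 2) stop("ages must span at least 2 distinct values", call. = FALSE)
    k <- min(df + 1, n_age)
    fit <- if (k >= 3) {
      mgcv::gam(length ~ s(age, k = k), data = part)
    } else {
      stats::lm(length ~ age, data = part)
    }
    part$expected <- as.numeric(stats::fitted(fit))
    part$residual <- part$length - part$expected
    out[[sx]] <- part
  }
  dplyr::bind_rows(out)
}

#' F-test for equality of variances
#'
#' `F = var(a) / var(b)` with `(n_a - 1, n_b - 1)` degrees of freedom and a
#' two-sided p-value.
#'
#' @param residuals_a,residuals_b numeric samples (n >= 3 each).
#' @return one-row tibble: `F`, `p_value`, `ratio` (the variance ratio,
#'   equal to `F`), `df1`, `df2`.
#' @export
variance_f_test <- function(residuals_a, residuals_b) {
  if (length(residuals_a) < 3 || length(residuals_b) < 3) {
    stop("both samples must have n >= 3", call. = FALSE)
  }
  if (stats::var(residuals_b) == 0) {
    stop("zero variance in denominator sample", call. = FALSE)
  }
  vt <- stats::var.test(residuals_a, residuals_b)
  tibble::tibble(
    F = unname(vt$statistic), p_value = vt$p.value,
    ratio = unname(vt$estimate),
    df1 = unname(vt$parameter[1]), df2 = unname(vt$parameter[2])
  )
}

#' Evaluate a detections table against ground truth
#'
#' Computes the evaluation report: mouse-count (objectness) accuracy at the
#' 0.5 top-view filter, keypoint MSE over IoU-matched detections, and the
#' per-bone correlation between automated lengths and ground-truth lengths.
#'
#' @param samples ground-truth samples (see [scenes_to_samples()]).
#' @param detections detections tibble from [detect_mice()].
#' @param threshold top-view probability filter threshold.
#' @return object of class `bone_eval` with fields `objectness_accuracy`,
#'   `keypoint_mse`, `correlations` (per-bone tibble), `lengths` (matched
#'   ground-truth/automated length pairs), `n_images`, `n_truth_mice`.
#' @export
evaluate_detections <- function(samples, detections, threshold = 0.5) {
  kept <- filter_detections(detections, threshold)
  acc <- objectness_accuracy(samples, detections, threshold)
  mse <- tryCatch(keypoint_mse_samples(samples, kept), error = function(e) NA_real_)
  pairs <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    det_i <- kept[kept$image == i, , drop = FALSE]
    if (!length(s$boxes) || !nrow(det_i)) next
    pred_boxes <- lapply(seq_len(nrow(det_i)), function(r) {
      c(det_i$x0[r], det_i$y0[r], det_i$x1[r], det_i$y1[r])
    })
    mm <- match_detections(s$boxes, pred_boxes)
    for (r in seq_len(nrow(mm))) {
      truth_len <- kp_bone_lengths(s$keypoint_sets[[mm[r, 1]]])
      auto_len <- kp_bone_lengths(det_i$keypoints[[mm[r, 2]]])
      pairs[[length(pairs) + 1]] <- dplyr::bind_cols(
        truth_len,
        tibble::tibble(automated_px = auto_len$length_px, image = i,
                       truth_mouse = mm[r, 1])
      )
    }
  }
  lengths <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(bone = character(), side = character(),
                   length_px = numeric(), automated_px = numeric())
  correlations <- if (nrow(lengths) >= 3) {
    dplyr::group_modify(dplyr::group_by(lengths, .data$bone), function(d, g) {
      if (nrow(d) >= 3 && stats::sd(d$length_px) > 0) {
        correlate(d$length_px, d$automated_px)
      } else tibble::tibble()
    })
  } else tibble::tibble(bone = character())
  overall <- if (nrow(lengths) >= 3 && stats::sd(lengths$length_px) > 0) {
    correlate(lengths$length_px, lengths$automated_px)
  } else NULL
  structure(list(
    objectness_accuracy = acc, keypoint_mse = mse,
    correlations = dplyr::ungroup(correlations), overall_correlation = overall,
    lengths = lengths, n_images = length(samples),
    n_truth_mice = sum(vapply(samples, function(s) length(s$boxes), integer(1)))
  ), class = "bone_eval")
}

#' @export
print.bone_eval <- function(x, ...) {
  cat("<bone_eval>\n")
  cat(sprintf("  images: %d  mice: %d\n", x$n_images, x$n_truth_mice))
  cat(sprintf("  objectness accuracy: %.4f\n", x$objectness_accuracy))
  cat(sprintf("  keypoint MSE: %s  (px^2-scale)\n",
              format(x$keypoint_mse, digits = 4)))
  if (!is.null(x$overall_correlation)) {
    cat(sprintf("  length R^2 (all bones): %.4f\n",
                x$overall_correlation$r_squared))
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x a `bone_eval` object.
#' @param ... unused.
#' @return per-bone correlation tibble.
#' @method tidy bone_eval
#' @export
tidy.bone_eval <- function(x, ...) x$correlations

#' One-row summary of an evaluation report
#'
#' @param x a `bone_eval` object.
#' @param ... unused.
#' @return one-row tibble with accuracy, keypoint MSE and overall length R².
#' @method glance bone_eval
#' @export
glance.bone_eval <- function(x, ...) {
  tibble::tibble(
    objectness_accuracy = x$objectness_accuracy,
    keypoint_mse = x$keypoint_mse,
    length_r_squared = if (is.null(x$overall_correlation)) NA_real_ else
      x$overall_correlation$r_squared,
    n_images = x$n_images, n_truth_mice = x$n_truth_mice
  )
}

#' One-row summary of a training history
#'
#' @param x a `training_history` tibble.
#' @param ... unused.
#' @return one-row tibble with epochs per phase and final validation metrics.
#' @method glance training_history
#' @export
glance.training_history <- function(x, ...) {
  det <- x[x$phase == "detection", ]
  kp <- x[x$phase == "keypoint", ]
  tibble::tibble(
    detection_epochs = nrow(det), keypoint_epochs = nrow(kp),
    final_val_objectness_accuracy =
      if (nrow(det)) utils::tail(det$val_objectness_accuracy, 1) else NA_real_,
    final_val_keypoint_mse =
      if (nrow(kp)) utils::tail(kp$val_keypoint_mse, 1) else NA_real_
  )
}
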