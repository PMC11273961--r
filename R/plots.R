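# ggplot2 visualisations for scenes, training histories and evaluations.

#' Plot a synthetic scene with its ground truth
#'
#' @param object a `synthetic_scene`.
#' @param show_keypoints overlay ground-truth keypoints and skeleton edges.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot synthetic_scene
#' @export
autoplot.synthetic_scene <- function(object, show_keypoints = TRUE, ...) {
  img <- object$image
  df <- tidyr::expand_grid(y = seq_len(nrow(img)) - 1L,
                           x = seq_len(ncol(img)) - 1L)
  df$intensity <- as.vector(t(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_keypoints && length(object$mice)) {
    kp <- purrr::imap_dfr(object$mice, function(m, i) {
      d <- as_tibble(m$keypoints); d$mouse <- factor(i); d
    })
    p <- p + ggplot2::geom_point(
      data = kp, ggplot2::aes(colour = .data$bone), size = 1.2) +
      ggplot2::geom_segment(
        data = dplyr::bind_cols(
          kp[kp$role == "start", c("x", "y", "bone", "side", "mouse")],
          stats::setNames(kp[kp$role == "end", c("x", "y")], c("xend", "yend"))),
        ggplot2::aes(xend = .data$xend, yend = .data$yend,
                     colour = .data$bone), linewidth = 0.4)
  }
  p
}

#' Plot training curves
#'
#' Component losses and validation metrics per epoch, faceted by phase.
#'
#' @param object a `training_history` tibble from [alternate_train()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot training_history
#' @export
autoplot.training_history <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object,
    cols = dplyr::any_of(c("loss_objectness", "loss_class", "loss_keypoint",
                           "val_objectness_accuracy", "val_keypoint_mse")),
    names_to = "metric", values_to = "value")
  long <- long[is.finite(long$value), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$metric),
                        cols = ggplot2::vars(.data$phase), scales = "free") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot automated versus ground-truth lengths
#'
#' Scatter of matched length pairs per bone with the identity line, in the
#' style of a manual-versus-automated agreement plot.
#'
#' @param object a `bone_eval` from [evaluate_detections()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bone_eval
#' @export
autoplot.bone_eval <- function(object, ...) {
  d <- object$lengths
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length_px, y = .data$automated_px)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "red") +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::facet_wrap(ggplot2::vars(.data$bone), scales = "free") +
    ggplot2::labs(x = "ground-truth length (px)", y = "automated length (px)") +
    ggplot2::theme_minimal()
}
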