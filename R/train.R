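# Alternating two-header training: the detection phase updates backbone +
# ROI header with objectness + class loss while the keypoint header is frozen;
# the keypoint phase updates backbone + keypoint header with objectness +
# keypoint loss while the ROI header is frozen. Learning rate warm-starts low
# for one epoch, then steps down from the base rate at milestone epochs.

#' Training schedule
#'
#' @param warm_lr warm-start learning rate used for the first
#'   `warm_epochs` epochs (default 0.0002).
#' @param warm_epochs number of warm-start epochs (default 1).
#' @param base_lr learning rate after warm-start (default 0.001); must exceed
#'   `warm_lr`.
#' @param milestones epoch indices (0-based) at which the rate is multiplied
#'   by `decay_factor`; `NULL` places them at 60% and 85% of the phase budget.
#' @param decay_factor multiplicative decay at each milestone.
#' @param detection_epochs epoch budget for the detection phase (paper-scale
#'   default 100).
#' @param keypoint_epochs epoch budget for the keypoint phase (paper-scale
#'   default 1000).
#' @param batch_size images per optimisation step (default 4).
#' @param patience validation checks without improvement before a phase is
#'   declared plateaued.
#' @param min_improve minimum metric improvement that resets patience.
#' @param val_every run validation every `val_every` epochs (the last epoch
#'   is always validated when validation data are supplied).
#' @param optimizer `"adam"` (the supported optimiser; exposed so the choice
#'   is config-gated).
#' @param seed root seed for data order and any stochastic step.
#' @return object of class `training_schedule`.
#' @export
training_schedule <- function(warm_lr = 2e-4, warm_epochs = 1L, base_lr = 1e-3,
                              milestones = NULL, decay_factor = 0.1,
                              detection_epochs = 100L, keypoint_epochs = 1000L,
                              batch_size = 4L, patience = 10L,
                              min_improve = 1e-4, val_every = 1L,
                              optimizer = "adam", seed = 0L) {
  if (warm_lr >= base_lr) stop("`warm_lr` must be below `base_lr`", call. = FALSE)
  if (detection_epochs < 1 || keypoint_epochs < 1) {
    stop("epoch budgets must be >= 1", call. = FALSE)
  }
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (!identical(optimizer, "adam")) {
    stop("only the Adam optimiser is supported", call. = FALSE)
  }
  structure(list(warm_lr = warm_lr, warm_epochs = as.integer(warm_epochs),
                 base_lr = base_lr, milestones = milestones,
                 decay_factor = decay_factor,
                 detection_epochs = as.integer(detection_epochs),
                 keypoint_epochs = as.integer(keypoint_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), min_improve = min_improve,
                 val_every = as.integer(val_every),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "training_schedule")
}

#' Learning rate at a given epoch
#'
#' @param schedule a [training_schedule()].
#' @param epoch 0-based epoch index within the phase.
#' @param budget the phase's epoch budget (used to place default milestones).
#' @return numeric learning rate.
#' @export
lr_at <- function(schedule, epoch, budget) {
  if (epoch < schedule$warm_epochs) return(schedule$warm_lr)
  ms <- schedule$milestones %||% floor(c(0.6, 0.85) * budget)
  schedule$base_lr * schedule$decay_factor^sum(epoch >= ms)
}

#' Convert synthetic scenes to training samples
#'
#' @param scenes list of `synthetic_scene` objects.
#' @return list of samples, each `list(image, boxes, keypoint_sets, views)`.
#' @export
scenes_to_samples <- function(scenes) {
  lapply(scenes, function(sc) {
    list(image = sc$image,
         boxes = lapply(sc$mice, `[[`, "box"),
         keypoint_sets = lapply(sc$mice, `[[`, "keypoints"),
         views = vapply(sc$mice, `[[`, character(1), "view"))
  })
}

#' Load training samples from a generated dataset directory
#'
#' @param dir directory written by [generate_dataset()].
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return list of samples as in [scenes_to_samples()].
#' @export
load_samples <- function(dir, split) {
  ann <- read_coco_keypoints(file.path(dir, paste0(split, "_annotations.json")))
  lapply(ann, function(rec) {
    list(image = read_image(file.path(dir, rec$file_name)),
         boxes = lapply(rec$annotations, `[[`, "box"),
         keypoint_sets = lapply(rec$annotations, `[[`, "keypoints"),
         views = rep("top", length(rec$annotations)))
  })
}

# stride-8 cell-center objectness labels for a batch of samples; positive
# boxes are shrunk so the corridor between adjacent mice stays confidently
# negative and their components separate at inference
objectness_labels <- function(samples, h4, w4, stride = 8L, shrink = 6) {
  ys <- (seq_len(h4) - 1) * stride + (stride - 1) / 2
  xs <- (seq_len(w4) - 1) * stride + (stride - 1) / 2
  unlist(lapply(samples, function(s) {
    lab <- matrix(0, h4, w4)
    for (b in s$boxes) {
      inside_y <- ys >= b[2] + shrink & ys < b[4] - shrink
      inside_x <- xs >= b[1] + shrink & xs < b[3] - shrink
      lab[inside_y, inside_x] <- 1
    }
    as.vector(lab)
  }), use.names = FALSE)
}

random_negative_box <- function(img_w, img_h, gt_boxes, n = 2L) {
  out <- list()
  for (i in seq_len(10 * n)) {
    bw <- stats::runif(1, 40, 100); bh <- stats::runif(1, 60, 140)
    x0 <- stats::runif(1, 0, max(1, img_w - bw))
    y0 <- stats::runif(1, 0, max(1, img_h - bh))
    box <- c(x0, y0, x0 + bw, y0 + bh)
    ious <- vapply(gt_boxes, box_iou, numeric(1), box)
    if (!length(ious) || max(ious) < 0.25) out[[length(out) + 1]] <- box
    if (length(out) >= n) break
  }
  out
}

# Gaussian-smoothed heatmap training target around bin (tx, ty), truncated
# at 3 bins; sigma = 0 reduces to a one-hot target.
heat_target <- function(tx, ty, H, W, sigma) {
  if (sigma <= 0) return(list(idx = tx * H + ty + 1L, w = 1))
  r <- 3L
  dxs <- max(0L, tx - r):min(W - 1L, tx + r)
  dys <- max(0L, ty - r):min(H - 1L, ty + r)
  gx <- rep(dxs, each = length(dys)); gy <- rep(dys, length(dxs))
  w <- exp(-((gx - tx)^2 + (gy - ty)^2) / (2 * sigma^2))
  list(idx = gx * H + gy + 1L, w = w / sum(w))
}

check_finite_loss <- function(loss, phase, epoch, batch_idx) {
  if (!all(is.finite(unlist(loss)))) {
    stop(sprintf("NaN/Inf loss in %s phase at epoch %d, batch starting at sample %d",
                 phase, epoch, batch_idx), call. = FALSE)
  }
}

apply_augment <- function(samples, augment_cfg) {
  if (is.null(augment_cfg)) return(samples)
  lapply(samples, function(s) {
    a <- augment(s$image, s$keypoint_sets, s$boxes, augment_cfg)
    list(image = a$image, boxes = a$boxes, keypoint_sets = a$keypoint_sets,
         views = s$views)
  })
}

# forward + backward for the detection objective; returns ctx with grads
detection_grads <- function(model, samples, cfg) {
  ctx <- model_ctx(model, training = TRUE)
  t <- nt_from_images(lapply(samples, `[[`, "image"))
  bb <- backbone_fwd(ctx, t)
  if (!all(is.finite(bb$P4$x))) {   # diverged parameters: surface as NaN loss
    return(list(ctx = ctx, losses = list(objectness = NaN)))
  }
  rp <- rpn_fwd(ctx, bb$P4)
  h4 <- rp$logits$h; w4 <- rp$logits$w
  y <- objectness_labels(samples, h4, w4)
  p_raw <- sigmoid(as.vector(rp$logits$x))
  lb_obj <- loss_batch(y = y, p = p_raw)
  l_obj <- objectness_loss(lb_obj)
  dlogit <- nt(matrix((lb_obj$p - y) / length(y), ncol = 1), h4, w4, t$n)

  # classifier ROIs: ground truth, jittered ground truth, random negatives
  rois <- list(); labels <- integer(); roi_img <- integer()
  for (bi in seq_along(samples)) {
    s <- samples[[bi]]
    img_h <- nrow(s$image); img_w <- ncol(s$image)
    for (mi in seq_along(s$boxes)) {
      cls <- if (s$views[mi] == "top") 2L else 1L
      rois <- c(rois, list(s$boxes[[mi]]))
      labels <- c(labels, cls); roi_img <- c(roi_img, bi)
      jit <- s$boxes[[mi]] + stats::runif(4, -6, 6)
      jit <- c(max(0, jit[1]), max(0, jit[2]), min(img_w, jit[3]), min(img_h, jit[4]))
      rois <- c(rois, list(jit)); labels <- c(labels, cls); roi_img <- c(roi_img, bi)
    }
    neg <- random_negative_box(img_w, img_h, s$boxes)
    rois <- c(rois, neg)
    labels <- c(labels, rep(1L, length(neg)))
    roi_img <- c(roi_img, rep(bi, length(neg)))
  }
  l_cls <- 0
  dP4_acc <- NULL
  if (length(rois)) {
    crops <- lapply(seq_along(rois), function(ri) {
      b <- rois[[ri]]
      roi_crop_fwd(bb$P4, roi_img[ri], 8L, b[1], b[2], b[3] - b[1], 7L, b[4] - b[2])
    })
    flat <- do.call(rbind, lapply(crops, function(cr) nt_flatten(cr$out)))
    cl <- classifier_fwd(ctx, flat)
    Y <- matrix(0, length(labels), cfg$n_classes)
    Y[cbind(seq_along(labels), labels)] <- 1
    lb_cls <- loss_batch(Y = Y, P = cl$probs)
    l_cls <- class_loss(lb_cls)
    dlog_cls <- (cl$probs - Y) / length(labels)
    dflat <- classifier_bwd(ctx, dlog_cls, cl$cache)
    dP4_acc <- matrix(0, nrow(bb$P4$x), ncol(bb$P4$x))
    per_roi <- 7L * 7L * ncol(bb$P4$x)
    for (ri in seq_along(rois)) {
      dcrop_flat <- dflat[ri, , drop = FALSE]
      m <- t(dcrop_flat)
      a <- array(m, c(7L, 7L, ncol(bb$P4$x), 1L))
      dcrop <- nt(matrix(aperm(a, c(1, 2, 4, 3)), ncol = ncol(bb$P4$x)), 7L, 7L, 1L)
      dP4_acc <- roi_crop_bwd(dcrop, crops[[ri]]$cache, dP4_acc)
    }
  }
  dP4_rpn <- rpn_bwd(ctx, dlogit, rp$cache)
  dP4 <- if (is.null(dP4_acc)) dP4_rpn else
    nt(dP4_rpn$x + dP4_acc, dP4_rpn$h, dP4_rpn$w, dP4_rpn$n)
  dP2 <- nt(matrix(0, nrow(bb$P2$x), ncol(bb$P2$x)), bb$P2$h, bb$P2$w, bb$P2$n)
  backbone_bwd(ctx, dP2, dP4, bb$cache)
  list(ctx = ctx, losses = list(objectness = l_obj, class = l_cls))
}

detection_step <- function(model, samples, lr, adam, cfg) {
  fg <- detection_grads(model, samples, cfg)
  upd <- adam_step(fg$ctx$params, fg$ctx$grads, adam, lr,
                   groups = c("backbone", "roi_header"))
  model$params <- upd$params
  model <- ctx_writeback(model, fg$ctx)
  list(model = model, adam = upd$state, losses = fg$losses)
}

# forward + backward for the keypoint objective; returns ctx with grads
keypoint_grads <- function(model, samples, cfg) {
  ctx <- model_ctx(model, training = TRUE)
  t <- nt_from_images(lapply(samples, `[[`, "image"))
  bb <- backbone_fwd(ctx, t)
  if (!all(is.finite(bb$P2$x))) {   # diverged parameters: surface as NaN loss
    return(list(ctx = ctx, losses = list(objectness = NaN)))
  }
  rp <- rpn_fwd(ctx, bb$P4)
  h4 <- rp$logits$h; w4 <- rp$logits$w
  y <- objectness_labels(samples, h4, w4)
  lb_obj <- loss_batch(y = y, p = sigmoid(as.vector(rp$logits$x)))
  l_obj <- objectness_loss(lb_obj)
  dlogit <- nt(matrix((lb_obj$p - y) / length(y), ncol = 1), h4, w4, t$n)

  heat <- cfg$heatmap_size; nb <- heat %/% KP_STRIDE
  crops <- list(); targets <- list()
  for (bi in seq_along(samples)) {
    s <- samples[[bi]]
    img_h <- nrow(s$image); img_w <- ncol(s$image)
    top_idx <- which(s$views == "top")
    # stochastic ROI subsampling: one mouse per image per step
    if (length(top_idx) > 1) top_idx <- sample(top_idx, 1)
    for (mi in top_idx) {
      box <- s$boxes[[mi]] + rep(KP_STRIDE * sample(-1:1, 2, replace = TRUE), 2)  # jitter window
      win <- kp_window(box, heat, img_w, img_h)
      kp <- s$keypoint_sets[[mi]]
      tx <- round(kp$xy[, 1]) - win[1]
      ty <- round(kp$xy[, 2]) - win[2]
      ok <- kp$visibility > 0 & tx >= 0 & tx < heat & ty >= 0 & ty < heat
      tgt <- ifelse(ok, tx * heat + ty + 1, NA_integer_)
      crops <- c(crops, list(masked_kp_crop(bb$P2, bi, win, heat, box,
                                            image = s$image)))
      targets <- c(targets, list(list(idx = tgt, tx = tx, ty = ty)))
    }
  }
  l_kp <- 0
  dP2_acc <- matrix(0, nrow(bb$P2$x), ncol(bb$P2$x))
  if (length(crops)) {
    stack <- nt(do.call(rbind, lapply(crops, function(cr) cr$out$x)), nb, nb,
                length(crops))
    kh <- kp_head_fwd(ctx, stack)
    hm <- kh$heatmap
    HW <- hm$h * hm$w
    n_roi <- length(crops)
    dHeat <- matrix(0, nrow(hm$x), ncol(hm$x))
    for (ri in seq_len(n_roi)) {
      blk_rows <- ((ri - 1) * HW + 1):(ri * HW)
      L <- hm$x[blk_rows, , drop = FALSE]
      mx <- apply(L, 2, max)
      E <- exp(L - matrix(mx, HW, ncol(L), byrow = TRUE))
      P <- E / matrix(colSums(E), HW, ncol(L), byrow = TRUE)
      tgt <- targets[[ri]]
      sigma <- cfg$heat_target_sd %||% 0
      for (k in which(!is.na(tgt$idx))) {
        tvec <- heat_target(tgt$tx[k], tgt$ty[k], hm$h, hm$w, sigma)
        l_kp <- l_kp +
          (-sum(tvec$w * log(pmax(P[tvec$idx, k], 1e-12)))) / n_roi
        dcol <- P[, k] / n_roi
        dcol[tvec$idx] <- dcol[tvec$idx] - tvec$w / n_roi
        dHeat[blk_rows, k] <- dcol
      }
    }
    dcrops <- kp_head_bwd(ctx, nt(dHeat, hm$h, hm$w, hm$n), kh$cache)
    nbin <- nb * nb
    for (ri in seq_len(n_roi)) {
      rows <- ((ri - 1) * nbin + 1):(ri * nbin)
      dcrop <- nt(dcrops$x[rows, , drop = FALSE] * crops[[ri]]$mask, nb, nb, 1L)
      dP2_acc <- roi_crop_bwd(dcrop, crops[[ri]]$cache, dP2_acc)
    }
  }
  dP4 <- rpn_bwd(ctx, dlogit, rp$cache)
  dP2 <- nt(dP2_acc, bb$P2$h, bb$P2$w, bb$P2$n)
  backbone_bwd(ctx, dP2, dP4, bb$cache)
  list(ctx = ctx, losses = list(objectness = l_obj, keypoint = l_kp))
}

keypoint_step <- function(model, samples, lr, adam, cfg) {
  fg <- keypoint_grads(model, samples, cfg)
  upd <- adam_step(fg$ctx$params, fg$ctx$grads, adam, lr,
                   groups = c("backbone", "keypoint_header"))
  model$params <- upd$params
  model <- ctx_writeback(model, fg$ctx)
  list(model = model, adam = upd$state, losses = fg$losses)
}

history_row <- function(phase, epoch, lr, losses, val_acc = NA_real_,
                        val_mse = NA_real_) {
  tibble::tibble(
    phase = phase, epoch = epoch, lr = lr,
    loss_objectness = losses$objectness %||% NA_real_,
    loss_class = losses$class %||% NA_real_,
    loss_keypoint = losses$keypoint %||% NA_real_,
    val_objectness_accuracy = val_acc, val_keypoint_mse = val_mse
  )
}

run_phase <- function(model, data, schedule, val_data, phase, augment_cfg,
                      verbose) {
  budget <- if (phase == "detection") schedule$detection_epochs else
    schedule$keypoint_epochs
  step_fun <- if (phase == "detection") detection_step else keypoint_step
  adam <- adam_init(model$params)
  history <- list()
  best <- Inf; stale <- 0L
  for (epoch in 0:(budget - 1L)) {
    lr <- lr_at(schedule, epoch, budget)
    order_idx <- sample(length(data))
    losses_acc <- list()
    for (start in seq(1, length(data), by = schedule$batch_size)) {
      bidx <- order_idx[start:min(length(data), start + schedule$batch_size - 1L)]
      batch <- apply_augment(data[bidx], augment_cfg)
      st <- step_fun(model, batch, lr, adam, model$config)
      check_finite_loss(st$losses, phase, epoch, start)
      model <- st$model; adam <- st$adam
      losses_acc[[length(losses_acc) + 1]] <- unlist(st$losses)
    }
    mean_losses <- as.list(colMeans(do.call(rbind, losses_acc)))
    val_acc <- NA_real_; val_mse <- NA_real_
    metric <- NA_real_
    do_val <- !is.null(val_data) &&
      (epoch %% (schedule$val_every %||% 1L) == 0L || epoch == budget - 1L)
    if (do_val) {
      ev <- validate_model(model, val_data, keypoints = (phase == "keypoint"))
      val_acc <- ev$objectness_accuracy; val_mse <- ev$keypoint_mse
      metric <- if (phase == "detection") -val_acc else val_mse
    }
    history[[length(history) + 1]] <-
      history_row(phase, epoch, lr, mean_losses, val_acc, val_mse)
    if (verbose) {
      message(sprintf("[%s] epoch %d lr %.2g losses %s val_acc %.3f val_mse %s",
                      phase, epoch, lr,
                      paste(sprintf("%.4f", unlist(mean_losses)), collapse = "/"),
                      val_acc, format(val_mse, digits = 4)))
    }
    if (!is.na(metric)) {
      if (metric < best - schedule$min_improve) {
        best <- metric; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= schedule$patience) break
      }
    }
  }
  list(model = model, history = dplyr::bind_rows(history))
}

# validation metrics: detection-count accuracy and (optionally) keypoint MSE
validate_model <- function(model, samples, keypoints = TRUE) {
  det <- detect_mice(model, lapply(samples, `[[`, "image"), keypoints = keypoints)
  kept <- filter_detections(det, model$config$score_threshold)
  truth_counts <- vapply(samples, function(s) sum(s$views == "top"), integer(1))
  pred_counts <- integer(length(samples))
  if (nrow(kept)) {
    tab <- dplyr::count(kept, .data$image)
    pred_counts[tab$image] <- tab$n
  }
  acc <- mean(pred_counts == truth_counts)
  mse <- if (!keypoints) NA_real_ else tryCatch(
    keypoint_mse_samples(samples, kept),
    error = function(e) NA_real_
  )
  list(objectness_accuracy = acc, keypoint_mse = mse)
}

#' Train the detection stage
#'
#' Updates the backbone and ROI-header parameters with the objectness and
#' class losses; the keypoint header is frozen (bit-identical before and
#' after). Training halts early when validation objectness accuracy plateaus.
#'
#' @param model a `bone_detector`.
#' @param data list of training samples (see [scenes_to_samples()]).
#' @param schedule a [training_schedule()].
#' @param val_data optional validation samples for plateau stopping.
#' @param augment_cfg optional [augment_config()] applied to each batch.
#' @param verbose print per-epoch progress.
#' @return list with the updated `model` and the `history` tibble (one row
#'   per epoch: phase, epoch, learning rate, component losses, validation
#'   metrics).
#' @export
train_detection_phase <- function(model, data, schedule = training_schedule(),
                                  val_data = NULL, augment_cfg = NULL,
                                  verbose = FALSE) {
  stopifnot(inherits(model, "bone_detector"), length(data) > 0)
  with_seed(schedule$seed + 1L,
            run_phase(model, data, schedule, val_data, "detection",
                      augment_cfg, verbose))
}

#' Train the keypoint stage
#'
#' Updates the backbone and keypoint-header parameters with the objectness and
#' keypoint losses; the ROI header is frozen. Halts early when validation
#' keypoint MSE plateaus.
#'
#' @inheritParams train_detection_phase
#' @return list with the updated `model` and the `history` tibble.
#' @export
train_keypoint_phase <- function(model, data, schedule = training_schedule(),
                                 val_data = NULL, augment_cfg = NULL,
                                 verbose = FALSE) {
  stopifnot(inherits(model, "bone_detector"), length(data) > 0)
  with_seed(schedule$seed + 2L,
            run_phase(model, data, schedule, val_data, "keypoint",
                      augment_cfg, verbose))
}

#' Alternating two-header training
#'
#' Runs the detection phase to plateau (or budget), then the keypoint phase,
#' optionally repeating the pair; each phase freezes the other header.
#'
#' @inheritParams train_detection_phase
#' @param detection_data,keypoint_data training samples for each phase (may be
#'   the same list when one dataset carries both annotations).
#' @param val_data optional validation samples used by both phases.
#' @param rounds number of detection/keypoint phase pairs.
#' @param checkpoint_path optional path; when given, the final model is saved
#'   there with its configuration embedded.
#' @return list with the trained `model` and the merged `history` tibble.
#' @export
alternate_train <- function(model, detection_data, keypoint_data,
                            schedule = training_schedule(), val_data = NULL,
                            augment_cfg = NULL, rounds = 1L,
                            checkpoint_path = NULL, verbose = FALSE) {
  if (!length(detection_data) || !length(keypoint_data)) {
    stop("both datasets must be nonempty", call. = FALSE)
  }
  histories <- list()
  for (r in seq_len(rounds)) {
    det <- train_detection_phase(model, detection_data, schedule, val_data,
                                 augment_cfg, verbose)
    model <- det$model
    kp <- train_keypoint_phase(model, keypoint_data, schedule, val_data,
                               augment_cfg, verbose)
    model <- kp$model
    histories[[length(histories) + 1]] <- dplyr::mutate(
      dplyr::bind_rows(det$history, kp$history), round = r)
  }
  history <- dplyr::bind_rows(histories)
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  list(model = model, history = structure(history,
                                          class = c("training_history",
                                                    class(history))))
}
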