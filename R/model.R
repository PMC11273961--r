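# The two-stage keypoint detector: convolutional backbone with top-down
# multi-scale fusion, an objectness/classification ROI head operating on the
# stride-8 map, and a heatmap keypoint head operating on a stride-2 crop
# around each detection. Heatmap bins map one-to-one onto image pixels so
# sub-pixel decoding error is not dominated by quantization.

#' Detector configuration
#'
#' @param backbone `"tiny_fpn"` (a 4-stage conv-BN-ReLU backbone small enough
#'   for CPU training) or `"efficientnet_b3_fpn"` (a wider, deeper profile of
#'   the same stage design, named for config compatibility with the
#'   paper-scale setting; it is not the original EfficientNet-B3).
#' @param n_classes background + top-view mouse (2, default); set 3 to add a
#'   non-top-view class.
#' @param n_keypoints fixed at 12.
#' @param keypoint_head_blocks number of conv+BatchNorm+ReLU blocks in the
#'   keypoint head before the transposed-convolution layer (default 8).
#' @param heatmap_size side of the square per-keypoint heatmap, in pixels; the
#'   keypoint window spans `heatmap_size` image pixels so each heatmap bin
#'   corresponds to exactly one pixel.
#' @param score_threshold top-view probability below which detections are
#'   discarded by [filter_detections()].
#' @param rpn_threshold objectness probability at which a stride-8 cell is
#'   considered foreground when forming proposals.
#' @param rpn_min_cells minimum number of foreground cells for a proposal.
#' @param rpn_core_threshold higher objectness level used to split a merged
#'   foreground component: a component containing two or more cores above
#'   this level is divided by nearest-core assignment.
#' @param box_margin pixels added around a proposal's cell extent.
#' @param kp_channels channel width of the keypoint head.
#' @param refine sub-pixel refinement around the argmax: `"centroid"`
#'   (probability-mass centroid of the local softmax window, default),
#'   `"parabolic"` (clamped log-space parabola through the argmax and its
#'   neighbours) or `"quarter"` (quarter-bin shift toward the higher
#'   neighbour).
#' @param kp_loss keypoint training objective: `"heatmap"` (per-keypoint
#'   spatial cross-entropy, default) or `"coordinate"` (the decoded-coordinate
#'   mean squared error).
#' @param heat_target_sd standard deviation, in pixels, of the
#'   Gaussian-smoothed heatmap training target centred on the ground-truth
#'   bin (0 gives a one-hot target).
#' @return an object of class `model_config`.
#' @export
model_config <- function(backbone = c("tiny_fpn", "efficientnet_b3_fpn"),
                         n_classes = 2L, n_keypoints = 12L,
                         keypoint_head_blocks = 8L, heatmap_size = 160L,
                         score_threshold = 0.5, rpn_threshold = 0.5,
                         rpn_min_cells = 2L, rpn_core_threshold = 0.8,
                         box_margin = 4,
                         kp_channels = NULL,
                         refine = c("centroid", "parabolic", "quarter"),
                         kp_loss = c("heatmap", "coordinate"),
                         heat_target_sd = 1.0) {
  if (is.character(backbone) && length(backbone) >= 1 &&
      !backbone[1] %in% c("tiny_fpn", "efficientnet_b3_fpn")) {
    stop("unknown backbone name: ", backbone[1], call. = FALSE)
  }
  backbone <- match.arg(backbone)
  if (n_keypoints != 12L) stop("`n_keypoints` must be 12", call. = FALSE)
  if (keypoint_head_blocks < 1L) stop("`keypoint_head_blocks` must be >= 1", call. = FALSE)
  if (score_threshold < 0 || score_threshold > 1) {
    stop("`score_threshold` must be in [0, 1]", call. = FALSE)
  }
  if (heatmap_size %% 4L != 0L) stop("`heatmap_size` must be a multiple of 4", call. = FALSE)
  widths <- switch(backbone,
    tiny_fpn = list(stages = c(10L, 20L, 32L), fpn = 12L, kp = 16L),
    efficientnet_b3_fpn = list(stages = c(40L, 80L, 128L), fpn = 48L, kp = 32L)
  )
  structure(list(
    backbone = backbone, n_classes = as.integer(n_classes),
    n_keypoints = as.integer(n_keypoints),
    keypoint_head_blocks = as.integer(keypoint_head_blocks),
    heatmap_size = as.integer(heatmap_size),
    score_threshold = score_threshold, rpn_threshold = rpn_threshold,
    rpn_min_cells = as.integer(rpn_min_cells),
    rpn_core_threshold = rpn_core_threshold, box_margin = box_margin,
    stage_channels = widths$stages, fpn_channels = widths$fpn,
    kp_channels = as.integer(kp_channels %||% widths$kp),
    refine = match.arg(refine), kp_loss = match.arg(kp_loss),
    heat_target_sd = heat_target_sd
  ), class = "model_config")
}

#' Build the detector
#'
#' Initialises all trainable parameters (He-scaled Gaussian weights,
#' unit-gamma BatchNorm) deterministically from `seed`. Parameters are
#' partitioned into three separately addressable groups required by the
#' alternating training protocol: `backbone`, `roi_header` and
#' `keypoint_header`.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `bone_detector`.
#' @export
build_model <- function(config = model_config(), seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, build_model_impl(config))
}

build_model_impl <- function(cfg) {
  params <- list(); bn <- list()
  rng <- function(n) stats::rnorm(n)
  add_conv <- function(name, cin, cout, k, with_bn = TRUE) {
    params[[paste0(name, ".W")]] <<- he_init(k * k * cin, c(k * k * cin, cout), rng)
    params[[paste0(name, ".b")]] <<- numeric(cout)
    if (with_bn) {
      params[[paste0(name, ".gamma")]] <<- rep(1, cout)
      params[[paste0(name, ".beta")]] <<- numeric(cout)
      bn[[name]] <<- list(mean = numeric(cout), var = rep(1, cout))
    }
  }
  add_dense <- function(name, din, dout) {
    params[[paste0(name, ".W")]] <<- he_init(din, c(din, dout), rng)
    params[[paste0(name, ".b")]] <<- numeric(dout)
  }
  st <- cfg$stage_channels; Fc <- cfg$fpn_channels
  add_conv("backbone.c1", 1L, st[1], 3L)
  add_conv("backbone.c2", st[1], st[2], 3L)
  add_conv("backbone.c3", st[2], st[3], 3L)
  add_conv("backbone.lat1", st[1], Fc, 1L, with_bn = FALSE)
  add_conv("backbone.lat2", st[2], Fc, 1L, with_bn = FALSE)
  add_conv("backbone.lat3", st[3], Fc, 1L, with_bn = FALSE)
  add_conv("roi_header.rpn1", Fc, 16L, 3L)
  add_conv("roi_header.rpnlogit", 16L, 1L, 1L, with_bn = FALSE)
  add_dense("roi_header.fc1", 7L * 7L * Fc, 64L)
  add_dense("roi_header.fc2", 64L, cfg$n_classes)
  kc <- cfg$kp_channels
  for (i in seq_len(cfg$keypoint_head_blocks)) {
    # block 1 sees the FPN crop, 16 space-to-depth raw-pixel channels and
    # two window-relative coordinate channels
    add_conv(paste0("keypoint_header.block", i),
             if (i == 1) Fc + 16L + 2L else kc, kc, 3L)
  }
  # the transposed conv also sees the 16 raw-pixel channels and 2 coordinate
  # channels via a skip connection, so sub-position selection can act as a
  # matched filter on the actual window pixels
  params[["keypoint_header.tconv.W"]] <-
    he_init(kc + 18L, c(kc + 18L, 16L * cfg$n_keypoints), rng)
  params[["keypoint_header.tconv.b"]] <- numeric(cfg$n_keypoints)
  structure(list(config = cfg, params = params, bn = bn),
            class = "bone_detector")
}

#' @export
print.bone_detector <- function(x, ...) {
  cat(sprintf("<bone_detector: %s, %d parameters, %d keypoint-head blocks>\n",
              x$config$backbone, n_parameters(x),
              x$config$keypoint_head_blocks))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `bone_detector`.
#' @param group optional group name (`"backbone"`, `"roi_header"`,
#'   `"keypoint_header"`).
#' @return integer count.
#' @export
n_parameters <- function(model, group = NULL) {
  p <- model$params
  if (!is.null(group)) p <- param_group(p, group)
  sum(vapply(p, length, integer(1)))
}

#' Names of the detector's parameter groups
#' @param model a `bone_detector`.
#' @return character vector of group prefixes covering all parameters.
#' @export
parameter_groups <- function(model) {
  unique(sub("\\..*$", "", names(model$params)))
}

# introspect the keypoint head: conv blocks before the transposed conv
head_block_count <- function(model) {
  sum(grepl("^keypoint_header\\.block[0-9]+\\.W$", names(model$params)))
}

# --- forward / backward ------------------------------------------------------

model_ctx <- function(model, training) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- model$params
  ctx$bn <- model$bn
  ctx$grads <- list()
  ctx$training <- training
  ctx
}

ctx_writeback <- function(model, ctx) {
  model$bn <- ctx$bn
  model
}

gadd <- function(ctx, name, val) {
  cur <- ctx$grads[[name]]
  ctx$grads[[name]] <- if (is.null(cur)) val else cur + val
}

cbr_fwd <- function(ctx, t, name, k, stride) {
  cf <- conv2d_fwd(t, ctx$params[[paste0(name, ".W")]],
                   ctx$params[[paste0(name, ".b")]], k, stride)
  bf <- bn_fwd(cf$out, ctx$params[[paste0(name, ".gamma")]],
               ctx$params[[paste0(name, ".beta")]],
               ctx$bn[[name]], ctx$training)
  ctx$bn[[name]] <- bf$running
  rf <- relu_fwd(bf$out)
  list(out = rf$out, cache = list(conv = cf$cache, bn = bf$cache,
                                  relu = rf$cache, name = name))
}

cbr_bwd <- function(ctx, dY, cache) {
  nm <- cache$name
  dr <- relu_bwd(dY, cache$relu)
  bb <- bn_bwd(dr, cache$bn)
  gadd(ctx, paste0(nm, ".gamma"), bb$dgamma)
  gadd(ctx, paste0(nm, ".beta"), bb$dbeta)
  cb <- conv2d_bwd(bb$dx, cache$conv, ctx$params[[paste0(nm, ".W")]])
  gadd(ctx, paste0(nm, ".W"), cb$dW)
  gadd(ctx, paste0(nm, ".b"), cb$db)
  cb$dx
}

conv1_fwd <- function(ctx, t, name) {
  W <- ctx$params[[paste0(name, ".W")]]
  y <- t$x %*% W
  y <- y + matrix(rep(ctx$params[[paste0(name, ".b")]], each = nrow(y)), nrow(y))
  list(out = nt(y, t$h, t$w, t$n), cache = list(x = t$x, name = name))
}

conv1_bwd <- function(ctx, dY, cache) {
  nm <- cache$name
  gadd(ctx, paste0(nm, ".W"), crossprod(cache$x, dY$x))
  gadd(ctx, paste0(nm, ".b"), colSums(dY$x))
  nt(dY$x %*% t(ctx$params[[paste0(nm, ".W")]]), dY$h, dY$w, dY$n)
}

# Backbone: three stride-2 conv-BN-ReLU stages (strides 2, 4, 8). The fused
# fine map P2 (stride 4) used by the keypoint head combines the stride-4
# lateral, the upsampled stride-8 context, and the average-pooled stride-2
# lateral (which carries the pixel-level endpoint detail); the coarse map P4
# (stride 8) feeds the ROI head.
KP_STRIDE <- 4L

backbone_fwd <- function(ctx, t) {
  c1 <- cbr_fwd(ctx, t, "backbone.c1", 3L, 2L)
  c2 <- cbr_fwd(ctx, c1$out, "backbone.c2", 3L, 2L)
  c3 <- cbr_fwd(ctx, c2$out, "backbone.c3", 3L, 2L)
  l3 <- conv1_fwd(ctx, c3$out, "backbone.lat3")
  l2 <- conv1_fwd(ctx, c2$out, "backbone.lat2")
  l1 <- conv1_fwd(ctx, c1$out, "backbone.lat1")
  p4 <- l3$out
  p2 <- nt(l2$out$x + upsample2_fwd(p4)$x + avgpool2_fwd(l1$out)$x,
           l2$out$h, l2$out$w, l2$out$n)
  list(P2 = p2, P4 = p4,
       cache = list(c1 = c1$cache, c2 = c2$cache, c3 = c3$cache,
                    l1 = l1$cache, l2 = l2$cache, l3 = l3$cache, p4 = p4))
}

backbone_bwd <- function(ctx, dP2, dP4, cache) {
  p4 <- cache$p4
  dP4t <- nt(dP4$x + upsample2_bwd(dP2, p4$h, p4$w, p4$n)$x, p4$h, p4$w, p4$n)
  dC3 <- conv1_bwd(ctx, dP4t, cache$l3)
  dC2a <- conv1_bwd(ctx, dP2, cache$l2)
  dC1a <- conv1_bwd(ctx, avgpool2_bwd(dP2), cache$l1)
  dC2b <- cbr_bwd(ctx, dC3, cache$c3)
  dC2 <- nt(dC2a$x + dC2b$x, dC2a$h, dC2a$w, dC2a$n)
  dC1b <- cbr_bwd(ctx, dC2, cache$c2)
  dC1 <- nt(dC1a$x + dC1b$x, dC1a$h, dC1a$w, dC1a$n)
  invisible(cbr_bwd(ctx, dC1, cache$c1))
}

rpn_fwd <- function(ctx, P4) {
  r1 <- cbr_fwd(ctx, P4, "roi_header.rpn1", 3L, 1L)
  lg <- conv1_fwd(ctx, r1$out, "roi_header.rpnlogit")
  list(logits = lg$out, cache = list(r1 = r1$cache, lg = lg$cache))
}

rpn_bwd <- function(ctx, dLogits, cache) {
  d1 <- conv1_bwd(ctx, dLogits, cache$lg)
  cbr_bwd(ctx, d1, cache$r1)
}

classifier_fwd <- function(ctx, crops_flat) {
  f1 <- dense_fwd(crops_flat, ctx$params[["roi_header.fc1.W"]],
                  ctx$params[["roi_header.fc1.b"]])
  a1 <- pmax(f1$out, 0)
  f2 <- dense_fwd(a1, ctx$params[["roi_header.fc2.W"]],
                  ctx$params[["roi_header.fc2.b"]])
  probs <- softmax_rows(f2$out)
  list(probs = probs, logits = f2$out,
       cache = list(x = crops_flat, a1 = a1, mask = f1$out > 0))
}

classifier_bwd <- function(ctx, dLogits, cache) {
  d2 <- dense_bwd(dLogits, cache$a1, ctx$params[["roi_header.fc2.W"]])
  gadd(ctx, "roi_header.fc2.W", d2$dW); gadd(ctx, "roi_header.fc2.b", d2$db)
  da1 <- d2$dx * cache$mask
  d1 <- dense_bwd(da1, cache$x, ctx$params[["roi_header.fc1.W"]])
  gadd(ctx, "roi_header.fc1.W", d1$dW); gadd(ctx, "roi_header.fc1.b", d1$db)
  d1$dx
}

# two constant channels holding the bin's normalised (x, y) position within
# the window, so the head can learn window-anchored spatial priors
coord_channels <- function(nb, n) {
  cx <- rep(rep((seq_len(nb) - 0.5) / nb * 2 - 1, each = nb), n)
  cy <- rep(rep((seq_len(nb) - 0.5) / nb * 2 - 1, nb), n)
  cbind(cy, cx)
}

kp_head_fwd <- function(ctx, crops) {
  cfg_blocks <- sum(grepl("^keypoint_header\\.block[0-9]+\\.W$", names(ctx$params)))
  caches <- vector("list", cfg_blocks)
  n_in <- ncol(crops$x)
  crops <- nt(cbind(crops$x, coord_channels(crops$h, crops$n)),
              crops$h, crops$w, crops$n)
  t <- crops
  for (i in seq_len(cfg_blocks)) {
    cb <- cbr_fwd(ctx, t, paste0("keypoint_header.block", i), 3L, 1L)
    t <- cb$out; caches[[i]] <- cb$cache
  }
  # skip connection: raw-pixel + coordinate channels join the learned
  # features at the transposed-conv input
  skip <- crops$x[, (n_in - 15L):(n_in + 2L), drop = FALSE]
  t_in <- nt(cbind(t$x, skip), t$h, t$w, t$n)
  tc <- tconv_fwd(t_in, ctx$params[["keypoint_header.tconv.W"]],
                  ctx$params[["keypoint_header.tconv.b"]], KP_STRIDE)
  list(heatmap = tc$out,
       cache = list(blocks = caches, tconv = tc$cache, kc = ncol(t$x)))
}

kp_head_bwd <- function(ctx, dHeat, cache) {
  tb <- tconv_bwd(dHeat, cache$tconv, ctx$params[["keypoint_header.tconv.W"]])
  gadd(ctx, "keypoint_header.tconv.W", tb$dW)
  gadd(ctx, "keypoint_header.tconv.b", tb$db)
  # drop the skip-channel gradients (raw pixels and coordinates are inputs)
  d <- nt(tb$dx$x[, seq_len(cache$kc), drop = FALSE], tb$dx$h, tb$dx$w, tb$dx$n)
  for (i in rev(seq_along(cache$blocks))) {
    d <- cbr_bwd(ctx, d, cache$blocks[[i]])
  }
  # strip gradients of the raw-pixel and coordinate channels: only the
  # learned FPN channels propagate into the backbone
  nt(d$x[, seq_len(ncol(d$x) - 18L), drop = FALSE], d$h, d$w, d$n)
}

softmax_rows <- function(m) {
  mx <- apply(m, 1, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- proposals ---------------------------------------------------------------

# 4-connected components of a logical matrix; returns integer label matrix.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(i, j), 1)
      lab[i, j] <- cur
      while (nrow(queue)) {
        q <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          ni <- q[1] + d[1]; nj <- q[2] + d[2]
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue <- rbind(queue, c(ni, nj))
          }
        }
      }
    }
  }
  lab
}

# Proposal boxes from the thresholded objectness map of one image.
# A foreground component that contains two or more high-confidence cores is
# split by assigning its cells to the nearest core centroid (hysteresis),
# so adjacent mice bridged by marginal cells still yield separate proposals.
proposals_from_objectness <- function(obj, stride, threshold, min_cells,
                                      margin, img_w, img_h,
                                      core_threshold = 0.8) {
  lab <- label_components(obj > threshold)
  n <- max(lab)
  out <- list()
  cells_to_box <- function(cells) {
    c(max(0, (min(cells[, 2]) - 1) * stride - margin),
      max(0, (min(cells[, 1]) - 1) * stride - margin),
      min(img_w, max(cells[, 2]) * stride + margin),
      min(img_h, max(cells[, 1]) * stride + margin))
  }
  for (k in seq_len(n)) {
    comp_mask <- lab == k
    cells <- which(comp_mask, arr.ind = TRUE)
    if (nrow(cells) < min_cells) next
    core_lab <- label_components(comp_mask & obj > core_threshold)
    n_cores <- max(core_lab)
    core_sizes <- tabulate(core_lab[core_lab > 0], nbins = max(1, n_cores))
    keep_cores <- which(core_sizes >= min_cells)
    if (length(keep_cores) >= 2) {
      centroids <- t(vapply(keep_cores, function(cid) {
        cc <- which(core_lab == cid, arr.ind = TRUE)
        colMeans(cc)
      }, numeric(2)))
      d2 <- outer(cells[, 1], centroids[, 1], "-")^2 +
        outer(cells[, 2], centroids[, 2], "-")^2
      assign_to <- max.col(-d2)
      for (g in seq_len(nrow(centroids))) {
        sub <- cells[assign_to == g, , drop = FALSE]
        if (nrow(sub) >= min_cells) out[[length(out) + 1]] <- cells_to_box(sub)
      }
    } else {
      out[[length(out) + 1]] <- cells_to_box(cells)
    }
  }
  out
}

box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

# square keypoint window with origin aligned to the feature stride
kp_window <- function(box, heat, img_w, img_h, stride = KP_STRIDE) {
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  x0 <- stride * round((cx - heat / 2) / stride)
  y0 <- stride * round((cy - heat / 2) / stride)
  x0 <- min(max(x0, 0), max(0, img_w - heat))
  y0 <- min(max(y0, 0), max(0, img_h - heat))
  c(x0 = x0, y0 = y0)
}

# Crop the fine feature map over a keypoint window and zero all bins whose
# centers fall outside the detection box, so neighbouring mice in the same
# window cannot act as distractors (the crop is box-shaped, as in a
# box-aligned ROI crop).
masked_kp_crop <- function(P2, sample, win, heat, box, image = NULL,
                           mask_pad = 4) {
  nb <- heat %/% KP_STRIDE
  cr <- roi_crop_fwd(P2, sample, KP_STRIDE, win[1], win[2], heat, nb)
  centers <- (seq_len(nb) - 0.5) * KP_STRIDE - 0.5
  in_x <- (win[1] + centers) >= box[1] - mask_pad &
    (win[1] + centers) < box[3] + mask_pad
  in_y <- (win[2] + centers) >= box[2] - mask_pad &
    (win[2] + centers) < box[4] + mask_pad
  mask <- as.numeric(outer(in_y, in_x, "&"))   # h fastest, matches row order
  cr$out$x <- cr$out$x * mask
  if (!is.null(image)) {
    # lossless raw-pixel channels: the window rearranged space-to-depth so
    # each stride-4 cell carries its 16 exact pixel intensities
    cr$out$x <- cbind(cr$out$x, space_to_depth_window(image, win, heat) * mask)
  }
  cr$mask <- mask
  cr
}

# crop the heat x heat window from a [0,1] image (constant 0 padding outside
# the frame) and rearrange 4x4 pixel blocks into 16 channels on the stride-4
# grid; rows (h, w) h-fastest, channel order (a, b) with a (row offset) fastest
space_to_depth_window <- function(image, win, heat) {
  h <- nrow(image); w <- ncol(image)
  crop <- matrix(0, heat, heat)
  rows <- (win[2] + 1):(win[2] + heat); cols <- (win[1] + 1):(win[1] + heat)
  ok_r <- rows >= 1 & rows <= h; ok_c <- cols >= 1 & cols <= w
  crop[ok_r, ok_c] <- image[rows[ok_r], cols[ok_c]]
  nb <- heat %/% 4L
  out <- matrix(0, nb * nb, 16L)
  col <- 0L
  for (b in 0:3) for (a in 0:3) {
    col <- col + 1L
    out[, col] <- crop[seq(a + 1L, by = 4L, length.out = nb),
                       seq(b + 1L, by = 4L, length.out = nb)]
  }
  out
}

# Decode one ROI's heatmap logits (H x W x K slab) to coordinates + scores.
decode_heatmap_roi <- function(logits_block, H, W, K, origin, refine) {
  xy <- matrix(NA_real_, K, 2)
  sc <- numeric(K)
  for (k in seq_len(K)) {
    L <- matrix(logits_block[, k], H, W)
    am <- arrayInd(which.max(L), dim(L))
    i <- am[1]; j <- am[2]
    # softmax peak probability as the keypoint score
    p <- exp(L - max(L)); sc[k] <- 1 / sum(p)
    dx <- 0; dy <- 0
    if (refine == "centroid") {
      # probability-mass centroid in a local window around the argmax
      r <- 3L
      ii <- max(1, i - r):min(H, i + r)
      jj <- max(1, j - r):min(W, j + r)
      w <- exp(L[ii, jj] - L[i, j])
      w <- w / sum(w)
      dy <- sum(rowSums(w) * (ii - i))
      dx <- sum(colSums(w) * (jj - j))
    } else if (refine == "parabolic") {
      if (j > 1 && j < W) {
        den <- 2 * (2 * L[i, j] - L[i, j - 1] - L[i, j + 1])
        if (den > 1e-12) dx <- max(-0.5, min(0.5, (L[i, j + 1] - L[i, j - 1]) / den))
      }
      if (i > 1 && i < H) {
        den <- 2 * (2 * L[i, j] - L[i - 1, j] - L[i + 1, j])
        if (den > 1e-12) dy <- max(-0.5, min(0.5, (L[i + 1, j] - L[i - 1, j]) / den))
      }
    } else {
      if (j > 1 && j < W) dx <- 0.25 * sign(L[i, j + 1] - L[i, j - 1])
      if (i > 1 && i < H) dy <- 0.25 * sign(L[i + 1, j] - L[i - 1, j])
    }
    xy[k, ] <- c(origin[1] + (j - 1) + dx, origin[2] + (i - 1) + dy)
  }
  list(xy = xy, scores = sc)
}

# --- prediction --------------------------------------------------------------

#' Run the detector on images
#'
#' Full two-stage inference: backbone features, objectness map, proposal
#' extraction, ROI classification into a top-view probability, and per-ROI
#' heatmap keypoint decoding with sub-pixel refinement. Deterministic in
#' evaluation mode.
#'
#' @param model a trained `bone_detector`.
#' @param images a single `[0, 1]` grayscale matrix or a list of them.
#' @param batch_size images per forward batch.
#' @param keypoints decode keypoints (`TRUE`, default); `FALSE` skips the
#'   keypoint head and returns detections with empty keypoint sets, for
#'   detection-only evaluation.
#' @return a detections tibble with one row per detected mouse: `image`
#'   (index into `images`), `mouse` (rank by descending top-view probability),
#'   `top_view_prob`, box corners `x0, y0, x1, y1`, and list-column
#'   `keypoints` of [keypoint_set()] objects carrying per-keypoint scores.
#'   Images with no detections contribute no rows.
#' @export
detect_mice <- function(model, images, batch_size = 8L, keypoints = TRUE) {
  stopifnot(inherits(model, "bone_detector"))
  if (is.matrix(images)) images <- list(images)
  if (length(images) == 0) return(empty_detections())
  lapply(images, function(im) {
    if (!is.matrix(im) || length(dim(im)) != 2) {
      stop("each image must be a 2-D numeric matrix", call. = FALSE)
    }
  })
  cfg <- model$config
  rows <- list()
  for (start in seq(1, length(images), by = batch_size)) {
    idx <- start:min(length(images), start + batch_size - 1L)
    batch <- images[idx]
    ctx <- model_ctx(model, training = FALSE)
    t <- nt_from_images(batch)
    bb <- backbone_fwd(ctx, t)
    rp <- rpn_fwd(ctx, bb$P4)
    h4 <- rp$logits$h; w4 <- rp$logits$w
    obj <- array(sigmoid(rp$logits$x), c(h4, w4, length(batch)))
    for (bi in seq_along(batch)) {
      img_h <- nrow(batch[[bi]]); img_w <- ncol(batch[[bi]])
      props <- proposals_from_objectness(obj[, , bi], 8L, cfg$rpn_threshold,
                                         cfg$rpn_min_cells, cfg$box_margin,
                                         img_w, img_h,
                                         cfg$rpn_core_threshold %||% 0.8)
      if (!length(props)) next
      crops <- lapply(props, function(b) {
        roi_crop_fwd(bb$P4, bi, 8L, b[1], b[2], b[3] - b[1], 7L, b[4] - b[2])$out
      })
      flat <- do.call(rbind, lapply(crops, nt_flatten))
      cl <- classifier_fwd(ctx, flat)
      tv_prob <- cl$probs[, 2]
      if (!keypoints) {
        for (pi in seq_along(props)) {
          box <- props[[pi]]
          rows[[length(rows) + 1]] <- tibble::tibble(
            image = idx[bi], top_view_prob = tv_prob[pi],
            x0 = box[1], y0 = box[2], x1 = box[3], y1 = box[4],
            keypoints = list(keypoint_set(matrix(0, 12, 2),
                                          visibility = rep(0L, 12))))
        }
        next
      }
      wins <- lapply(props, kp_window, heat = cfg$heatmap_size,
                     img_w = img_w, img_h = img_h)
      nb <- cfg$heatmap_size %/% KP_STRIDE
      kp_crops <- lapply(seq_along(props), function(pi) {
        masked_kp_crop(bb$P2, bi, wins[[pi]], cfg$heatmap_size,
                       props[[pi]], image = batch[[bi]])$out
      })
      stack <- nt(do.call(rbind, lapply(kp_crops, `[[`, "x")), nb, nb,
                  length(kp_crops))
      hm <- kp_head_fwd(ctx, stack)$heatmap
      HW <- hm$h * hm$w
      for (pi in seq_along(props)) {
        blk <- hm$x[((pi - 1) * HW + 1):(pi * HW), , drop = FALSE]
        dec <- decode_heatmap_roi(blk, hm$h, hm$w, cfg$n_keypoints,
                                  wins[[pi]], cfg$refine)
        box <- props[[pi]]
        # clip decoded coordinates into the (clipped) detection box
        xy <- cbind(pmin(pmax(dec$xy[, 1], box[1]), box[3] - 1e-9),
                    pmin(pmax(dec$xy[, 2], box[2]), box[4] - 1e-9))
        rows[[length(rows) + 1]] <- tibble::tibble(
          image = idx[bi], top_view_prob = tv_prob[pi],
          x0 = box[1], y0 = box[2], x1 = box[3], y1 = box[4],
          keypoints = list(keypoint_set(xy, scores = pmin(1, pmax(0, dec$scores))))
        )
      }
    }
  }
  if (!length(rows)) return(empty_detections())
  det <- dplyr::bind_rows(rows)
  det <- dplyr::arrange(det, .data$image, dplyr::desc(.data$top_view_prob))
  det <- dplyr::mutate(dplyr::group_by(det, .data$image),
                       mouse = dplyr::row_number())
  dplyr::relocate(dplyr::ungroup(det), "image", "mouse")
}

empty_detections <- function() {
  tibble::tibble(image = integer(), mouse = integer(),
                 top_view_prob = numeric(), x0 = numeric(), y0 = numeric(),
                 x1 = numeric(), y1 = numeric(), keypoints = list())
}

#' @rdname detect_mice
#' @param object a `bone_detector`.
#' @param newdata images, as in `detect_mice()`.
#' @param ... passed to `detect_mice()`.
#' @export
predict.bone_detector <- function(object, newdata, ...) {
  detect_mice(object, newdata, ...)
}

# --- checkpointing -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive file embedding the model configuration,
#' all parameters and BatchNorm running statistics.
#'
#' @param model a `bone_detector`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "bone_detector"))
  saveRDS(list(config = unclass(model$config), params = model$params,
               bn = model$bn, format = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the restored `bone_detector`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  structure(list(config = structure(obj$config, class = "model_config"),
                 params = obj$params, bn = obj$bn),
            class = "bone_detector")
}
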