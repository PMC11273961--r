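# Minimal BLAS-backed neural-network engine used by the detector.
#
# Feature maps are "tensors": list(x = matrix (H*W*N) x C, h, w, n) with rows
# ordered h-fastest, then w, then sample. All convolutions are im2col gathers
# followed by a single GEMM; backward passes scatter with rowsum(). Gather
# index tables are memoised per geometry.

nt <- function(x, h, w, n) list(x = x, h = h, w = w, n = n)

# stack a list of H x W matrices into a single-channel tensor
nt_from_images <- function(images) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  x <- matrix(unlist(images, use.names = FALSE), ncol = 1)
  nt(x, h, w, length(images))
}

nt_as_array <- function(t, channels = ncol(t$x)) {
  array(t$x, c(t$h, t$w, t$n, channels))
}

# rows = samples, cols = h*w*c (for dense heads)
nt_flatten <- function(t) {
  a <- array(t$x, c(t$h, t$w, t$n, ncol(t$x)))
  m <- matrix(aperm(a, c(1, 2, 4, 3)), ncol = t$n)
  t(m)
}

.nn_cache <- new.env(parent = emptyenv())

# im2col by k*k*C strided slice copies of the padded activation array; rows
# ordered (h, w, n) to match the tensor layout, columns ordered kernel-row
# fastest, then kernel-col, then channel (the weight layout).
im2col_slices <- function(t, k, stride, pad) {
  C <- ncol(t$x); H <- t$h; Wd <- t$w; N <- t$n
  hp <- H + 2L * pad; wp <- Wd + 2L * pad
  ho <- (hp - k) %/% stride + 1L; wo <- (wp - k) %/% stride + 1L
  ap <- array(0, c(hp, wp, N, C))
  ap[pad + seq_len(H), pad + seq_len(Wd), , ] <- t$x
  G <- matrix(0, ho * wo * N, k * k * C)
  col <- 0L
  for (cc in seq_len(C)) for (b in 0:(k - 1L)) for (a in 0:(k - 1L)) {
    col <- col + 1L
    G[, col] <- ap[seq(a + 1L, by = stride, length.out = ho),
                   seq(b + 1L, by = stride, length.out = wo), , cc]
  }
  list(G = G, ho = ho, wo = wo, hp = hp, wp = wp)
}

conv2d_fwd <- function(t, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  ic <- im2col_slices(t, k, stride, pad)
  Y <- ic$G %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(out = nt(Y, ic$ho, ic$wo, t$n),
       cache = list(G = ic$G, ho = ic$ho, wo = ic$wo, hp = ic$hp, wp = ic$wp,
                    h = t$h, w = t$w, n = t$n, C = ncol(t$x),
                    k = k, stride = stride, pad = pad))
}

# col2im: scatter-add by the same k*k*C strided slices (offsets never collide
# within one slice, so plain `+` accumulation is exact)
conv2d_bwd <- function(dY, cache, W) {
  ca <- cache
  dW <- crossprod(ca$G, dY$x)
  db <- colSums(dY$x)
  dG <- dY$x %*% t(W)
  dap <- array(0, c(ca$hp, ca$wp, ca$n, ca$C))
  col <- 0L
  k <- ca$k
  for (cc in seq_len(ca$C)) for (b in 0:(k - 1L)) for (a in 0:(k - 1L)) {
    col <- col + 1L
    ih <- seq(a + 1L, by = ca$stride, length.out = ca$ho)
    iw <- seq(b + 1L, by = ca$stride, length.out = ca$wo)
    dap[ih, iw, , cc] <- dap[ih, iw, , cc] + dG[, col]
  }
  p <- ca$pad
  da <- if (p > 0) dap[p + seq_len(ca$h), p + seq_len(ca$w), , , drop = FALSE] else dap
  list(dx = nt(matrix(da, ncol = ca$C), ca$h, ca$w, ca$n), dW = dW, db = db)
}

bn_fwd <- function(t, gamma, beta, running, training, momentum = 0.1, eps = 1e-5) {
  x <- t$x; R <- nrow(x); C <- ncol(x)
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v * R / max(1, R - 1)
  } else {
    mu <- running$mean; v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - matrix(mu, R, C, byrow = TRUE)) * matrix(inv, R, C, byrow = TRUE)
  y <- xhat * matrix(gamma, R, C, byrow = TRUE) + matrix(beta, R, C, byrow = TRUE)
  list(out = nt(y, t$h, t$w, t$n), running = running,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, training = training))
}

bn_bwd <- function(dY, cache) {
  xhat <- cache$xhat; R <- nrow(xhat); C <- ncol(xhat)
  dgamma <- colSums(dY$x * xhat)
  dbeta <- colSums(dY$x)
  if (cache$training) {
    m1 <- matrix(dbeta / R, R, C, byrow = TRUE)
    m2 <- xhat * matrix(dgamma / R, R, C, byrow = TRUE)
    dx <- (dY$x - m1 - m2) *
      matrix(cache$gamma * cache$inv, R, C, byrow = TRUE)
  } else {
    dx <- dY$x * matrix(cache$gamma * cache$inv, R, C, byrow = TRUE)
  }
  list(dx = nt(dx, dY$h, dY$w, dY$n), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(t) {
  mask <- t$x > 0
  list(out = nt(t$x * mask, t$h, t$w, t$n), cache = mask)
}

relu_bwd <- function(dY, mask) nt(dY$x * mask, dY$h, dY$w, dY$n)

upsample2_index <- function(h, w, n) {
  key <- paste("up", h, w, n, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  ho <- rep(seq_len(2L * h), 2L * w * n)
  wo <- rep(rep(seq_len(2L * w), each = 2L * h), n)
  no <- rep(seq_len(n), each = 4L * h * w)
  hi <- (ho + 1L) %/% 2L; wi <- (wo + 1L) %/% 2L
  idx <- hi + (wi - 1L) * h + (no - 1L) * h * w
  .nn_cache[[key]] <- idx
  idx
}

upsample2_fwd <- function(t) {
  idx <- upsample2_index(t$h, t$w, t$n)
  nt(t$x[idx, , drop = FALSE], 2L * t$h, 2L * t$w, t$n)
}

upsample2_bwd <- function(dY, h, w, n) {
  idx <- upsample2_index(h, w, n)
  r <- rowsum(dY$x, idx)
  dx <- matrix(0, h * w * n, ncol(dY$x))
  dx[as.integer(rownames(r)), ] <- r
  nt(dx, h, w, n)
}

# 2x2 average pooling (stride 2); backward spreads gradients evenly
avgpool2_fwd <- function(t) {
  idx <- upsample2_index(t$h %/% 2L, t$w %/% 2L, t$n)
  r <- rowsum(t$x, idx)
  nt(r / 4, t$h %/% 2L, t$w %/% 2L, t$n)
}

avgpool2_bwd <- function(dY) {
  idx <- upsample2_index(dY$h, dY$w, dY$n)
  nt(dY$x[idx, , drop = FALSE] / 4, 2L * dY$h, 2L * dY$w, dY$n)
}

# transposed convolution with kernel = stride = `up` (each input bin emits a
# non-overlapping up x up block); weight layout: C x (up^2 * K) with the
# sub-position (a, b) index fastest within each output channel k.
tconv_scatter_index <- function(h, w, n, up) {
  key <- paste("tc", h, w, n, up, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  hh <- rep(seq_len(h) - 1L, w * n)
  ww <- rep(rep(seq_len(w) - 1L, each = h), n)
  nn_ <- rep(seq_len(n) - 1L, each = h * w)
  u2 <- up * up
  idx <- matrix(0L, h * w * n, u2)
  ab <- 1L
  for (b in 0:(up - 1L)) for (a in 0:(up - 1L)) {
    idx[, ab] <- (up * hh + a) + (up * ww + b) * (up * h) + nn_ * u2 * h * w + 1L
    ab <- ab + 1L
  }
  .nn_cache[[key]] <- idx
  idx
}

tconv_fwd <- function(t, W, b, up) {
  u2 <- up * up
  K <- ncol(W) / u2
  Y0 <- t$x %*% W
  idx <- tconv_scatter_index(t$h, t$w, t$n, up)
  O <- matrix(0, u2 * t$h * t$w * t$n, K)
  for (ab in seq_len(u2)) {
    O[idx[, ab], ] <- Y0[, (seq_len(K) - 1L) * u2 + ab, drop = FALSE]
  }
  O <- O + rep(b, each = nrow(O))
  list(out = nt(O, up * t$h, up * t$w, t$n),
       cache = list(x = t$x, idx = idx, K = K, up = up))
}

tconv_bwd <- function(dY, cache, W) {
  K <- cache$K; up <- cache$up; u2 <- up * up
  dY0 <- matrix(0, nrow(cache$x), u2 * K)
  for (ab in seq_len(u2)) {
    dY0[, (seq_len(K) - 1L) * u2 + ab] <- dY$x[cache$idx[, ab], , drop = FALSE]
  }
  dW <- crossprod(cache$x, dY0)
  db <- colSums(dY$x)
  dx <- dY0 %*% t(W)
  list(dx = nt(dx, dY$h / up, dY$w / up, dY$n), dW = dW, db = db)
}

dense_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- y + matrix(rep(b, each = nrow(y)), nrow(y))
  list(out = y, cache = x)
}

dense_bwd <- function(dY, cache, W) {
  list(dx = dY %*% t(W), dW = crossprod(cache, dY), db = colSums(dY))
}

# Bilinear crop of `nb x nb` bins spanning the image-space window
# [x0, x0+winx) x [y0, y0+winy) from a single-sample feature tensor with the
# given pixel stride. Feature cell f has its center at image coordinate
# f*stride + (stride-1)/2, so aligned windows sample cell centers exactly.
roi_crop_fwd <- function(t, sample, stride, x0, y0, winx, nb, winy = winx) {
  stopifnot(t$n >= sample)
  fh <- t$h; fw <- t$w; C <- ncol(t$x)
  fx <- (x0 + (seq_len(nb) - 0.5) * winx / nb - 0.5 - (stride - 1) / 2) / stride
  fy <- (y0 + (seq_len(nb) - 0.5) * winy / nb - 0.5 - (stride - 1) / 2) / stride
  gx0 <- pmin(pmax(floor(fx), 0), fw - 1); gy0 <- pmin(pmax(floor(fy), 0), fh - 1)
  gx1 <- pmin(gx0 + 1, fw - 1); gy1 <- pmin(gy0 + 1, fh - 1)
  wx <- pmin(pmax(fx - gx0, 0), 1); wy <- pmin(pmax(fy - gy0, 0), 1)
  # expand to the nb x nb grid, h (y) fastest to match tensor row order
  WY <- rep(wy, nb); WX <- rep(wx, each = nb)
  base <- (sample - 1L) * fh * fw
  r00 <- base + rep(gy0, nb) + rep(gx0, each = nb) * fh + 1L
  r01 <- base + rep(gy0, nb) + rep(gx1, each = nb) * fh + 1L
  r10 <- base + rep(gy1, nb) + rep(gx0, each = nb) * fh + 1L
  r11 <- base + rep(gy1, nb) + rep(gx1, each = nb) * fh + 1L
  w00 <- (1 - WY) * (1 - WX); w01 <- (1 - WY) * WX
  w10 <- WY * (1 - WX); w11 <- WY * WX
  out <- t$x[r00, , drop = FALSE] * w00 + t$x[r01, , drop = FALSE] * w01 +
    t$x[r10, , drop = FALSE] * w10 + t$x[r11, , drop = FALSE] * w11
  list(out = nt(out, nb, nb, 1L),
       cache = list(rows = cbind(r00, r01, r10, r11),
                    weights = cbind(w00, w01, w10, w11),
                    nrow_feat = nrow(t$x), C = C))
}

# accumulate the crop gradient into a (nrow_feat x C) matrix
roi_crop_bwd <- function(dY, cache, acc = NULL) {
  if (is.null(acc)) acc <- matrix(0, cache$nrow_feat, cache$C)
  vals <- rbind(dY$x * cache$weights[, 1], dY$x * cache$weights[, 2],
                dY$x * cache$weights[, 3], dY$x * cache$weights[, 4])
  rows <- c(cache$rows[, 1], cache$rows[, 2], cache$rows[, 3], cache$rows[, 4])
  r <- rowsum(vals, rows)
  tgt <- as.integer(rownames(r))
  acc[tgt, ] <- acc[tgt, , drop = FALSE] + r
  acc
}

# --- parameter store and Adam ------------------------------------------------

he_init <- function(fan_in, dims, rng) {
  array(rng(prod(dims)) * sqrt(2 / fan_in), dims)
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Update parameters in `groups` only (prefix before the first dot); frozen
# parameters are left untouched, bit for bit.
adam_step <- function(params, grads, state, lr, groups,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    grp <- sub("\\..*$", "", nm)
    if (!grp %in% groups) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

param_group <- function(params, group) {
  params[startsWith(names(params), paste0(group, "."))]
}

param_checksum <- function(params, group = NULL) {
  if (!is.null(group)) params <- param_group(params, group)
  sum(vapply(params, function(p) sum(as.numeric(p)), numeric(1)))
}
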