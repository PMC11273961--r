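# Synthetic radiograph generation: stylized dorsal-view mouse skeletons with
# exact ground-truth keypoint annotations, so the detector is trainable and
# testable without external data.

# Run code with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Synthetic scene configuration
#'
#' Parameters of the synthetic radiograph generator. Images emulate dorsal-view
#' murine X-rays: one or two bright mouse silhouettes on a noisy background,
#' each with six bright bone segments (left/right tibia, femur, pelvis) whose
#' endpoints are the stored ground-truth keypoints.
#'
#' @param image_width,image_height image dimensions in pixels (>= 64).
#' @param n_mice number of mice in the scene (0, 1 or 2).
#' @param background_noise_sd standard deviation of the Gaussian background
#'   noise, on the `[0, 1]` intensity scale.
#' @param bone_intensity added intensity of a bone segment.
#' @param bone_thickness bone segment thickness in pixels.
#' @param length_means named numeric vector of mean bone lengths in pixels for
#'   `tibia`, `femur` and `pelvis`. Each mean must exceed `2 * bone_thickness`.
#' @param length_sd standard deviation of sampled bone lengths (pixels).
#' @param integer_keypoints snap ground-truth endpoints to integer pixel
#'   coordinates (default `TRUE`), so decoding error can be isolated from
#'   generation error.
#' @param blur_sd Gaussian blur applied to the rendered skeleton before noise,
#'   emulating radiographic softness (pixels).
#' @param decoy_prob probability of adding one non-top-view decoy silhouette
#'   (a boneless, obliquely posed body) to the scene; decoys are not counted in
#'   `n_mice` and carry no keypoints.
#' @param seed integer seed making generation deterministic.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_width = 256, image_height = 256, n_mice = 2,
                         background_noise_sd = 0.03, bone_intensity = 0.55,
                         bone_thickness = 2.4,
                         length_means = c(tibia = 24, femur = 20, pelvis = 15),
                         length_sd = 1.4, integer_keypoints = TRUE,
                         blur_sd = 0.7, decoy_prob = 0, seed = 1L) {
  cfg <- list(
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    n_mice = as.integer(n_mice), background_noise_sd = background_noise_sd,
    bone_intensity = bone_intensity, bone_thickness = bone_thickness,
    length_means = length_means, length_sd = length_sd,
    integer_keypoints = isTRUE(integer_keypoints), blur_sd = blur_sd,
    decoy_prob = decoy_prob, seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (!cfg$n_mice %in% 0:2) stop("`n_mice` must be 0, 1 or 2", call. = FALSE)
  if (cfg$image_width < 64 || cfg$image_height < 64) {
    stop("image dimensions must be at least 64 pixels", call. = FALSE)
  }
  if (cfg$length_sd < 0) stop("`length_sd` must be >= 0", call. = FALSE)
  need <- c("tibia", "femur", "pelvis")
  if (!all(need %in% names(cfg$length_means))) {
    stop("`length_means` must name tibia, femur and pelvis", call. = FALSE)
  }
  if (any(cfg$length_means[need] <= 2 * cfg$bone_thickness)) {
    stop("all bone length means must exceed 2 * bone_thickness", call. = FALSE)
  }
  if (cfg$decoy_prob < 0 || cfg$decoy_prob > 1) {
    stop("`decoy_prob` must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# --- low-level rasterisation -------------------------------------------------

# Add an anti-aliased filled ellipse. center = (x, y), semi-axes (a, b),
# theta = rotation of the a-axis (radians, clockwise in pixel coords).
render_ellipse <- function(img, center, a, b, theta, value) {
  h <- nrow(img); w <- ncol(img)
  ca <- cos(theta); sa <- sin(theta)
  ext <- max(a, b) + 2
  xs <- max(0, floor(center[1] - ext)):min(w - 1, ceiling(center[1] + ext))
  ys <- max(0, floor(center[2] - ext)):min(h - 1, ceiling(center[2] + ext))
  if (!length(xs) || !length(ys)) return(img)
  dx <- outer(rep(1, length(ys)), xs - center[1])
  dy <- outer(ys - center[2], rep(1, length(xs)))
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  q <- sqrt((u / a)^2 + (v / b)^2)
  # signed edge distance approx, soft 1px transition
  cov <- pmin(1, pmax(0, (1 - q) * min(a, b) + 0.5))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + value * cov
  img
}

# Add an anti-aliased thick segment with round caps from p0 to p1.
render_segment <- function(img, p0, p1, thickness, value) {
  h <- nrow(img); w <- ncol(img)
  r <- thickness / 2
  ext <- r + 1.5
  xs <- max(0, floor(min(p0[1], p1[1]) - ext)):min(w - 1, ceiling(max(p0[1], p1[1]) + ext))
  ys <- max(0, floor(min(p0[2], p1[2]) - ext)):min(h - 1, ceiling(max(p0[2], p1[2]) + ext))
  if (!length(xs) || !length(ys)) return(img)
  dx <- outer(rep(1, length(ys)), xs - p0[1])
  dy <- outer(ys - p0[2], rep(1, length(xs)))
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- if (len2 > 0) pmin(1, pmax(0, (dx * v[1] + dy * v[2]) / len2)) else 0
  d <- sqrt((dx - t * v[1])^2 + (dy - t * v[2])^2)
  cov <- pmin(1, pmax(0, r + 0.5 - d))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + value * cov
  img
}

# Separable Gaussian blur by shifted weighted sums (small kernels only).
gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  rad <- max(1L, as.integer(ceiling(2 * sd)))
  k <- exp(-((-rad):rad)^2 / (2 * sd^2))
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {       # vertical pass with edge replication
    off <- i - rad - 1L
    rows <- pmin(pmax(seq_len(h) + off, 1L), h)
    out <- out + k[i] * img[rows, , drop = FALSE]
  }
  img <- out
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {       # horizontal pass
    off <- i - rad - 1L
    cols <- pmin(pmax(seq_len(w) + off, 1L), w)
    out <- out + k[i] * img[, cols, drop = FALSE]
  }
  out
}

# --- skeleton geometry -------------------------------------------------------

# Anatomical layout constants, in pixels at the reference 256px frame; scaled
# linearly with min(image dims) / 256.
mouse_geometry <- function(scale) {
  list(
    body_a = 44 * scale,   # semi-axis along the body axis
    body_b = 21 * scale,   # semi-axis across
    head_a = 12 * scale, head_b = 9 * scale, head_gap = 8 * scale,
    pelvis_root_ax = 0.35, # pelvis start sits this fraction of body_a below center
    pelvis_root_lat = 4 * scale,
    joint_jitter = 1.2 * scale,
    pelvis_angle = 35, femur_angle = 70, tibia_angle = 15,  # degrees
    angle_jitter = 6
  )
}

deg2rad <- function(d) d * pi / 180

# Sample one mouse skeleton around `center` with body axis angle `theta`
# (radians; 0 = head up). Returns keypoint matrix (12 x 2), per-bone sampled
# target lengths, and body part geometry for rendering.
sample_mouse <- function(center, theta, cfg, geom) {
  u_ax <- c(sin(theta), -cos(theta))    # toward the head
  u_pp <- c(cos(theta), sin(theta))     # toward the animal's right (+x at theta=0)
  xy <- matrix(NA_real_, 12, 2)
  lengths <- tibble::tibble(bone = character(), side = character(),
                            target_px = numeric())
  bone_idx <- keypoint_bones()
  for (side in c("L", "R")) {
    s <- if (side == "L") -1 else 1
    root <- center - u_ax * (geom$pelvis_root_ax * geom$body_a) +
      u_pp * (s * geom$pelvis_root_lat)
    ap <- deg2rad(stats::rnorm(1, geom$pelvis_angle, geom$angle_jitter))
    af <- deg2rad(stats::rnorm(1, geom$femur_angle, geom$angle_jitter))
    at <- deg2rad(stats::rnorm(1, geom$tibia_angle, geom$angle_jitter))
    dirs <- list(
      pelvis = -u_ax * cos(ap) + u_pp * (s * sin(ap)),
      femur  = -u_ax * cos(af) + u_pp * (s * sin(af)),
      tibia  = -u_ax * cos(at) - u_pp * (s * sin(at))
    )
    snap <- function(p) if (cfg$integer_keypoints) round(p) else p
    prev_end <- root
    for (bone in c("pelvis", "femur", "tibia")) {
      target <- stats::rnorm(1, cfg$length_means[[bone]], cfg$length_sd)
      target <- max(target, 2 * cfg$bone_thickness + 1)
      start <- snap(prev_end + stats::runif(2, -geom$joint_jitter, geom$joint_jitter))
      end <- snap(start + target * dirs[[bone]])
      rows <- which(bone_idx$bone == bone & bone_idx$side == side)
      xy[rows[1], ] <- start
      xy[rows[2], ] <- end
      lengths <- dplyr::bind_rows(lengths, tibble::tibble(
        bone = bone, side = side, target_px = target))
      prev_end <- end
    }
  }
  head_center <- center + u_ax * (geom$body_a + geom$head_gap)
  list(xy = xy, lengths = lengths, u_ax = u_ax,
       head_center = head_center, center = center, theta = theta)
}

mouse_box <- function(mouse, geom, cfg, pad = 4) {
  # extremes over keypoints plus body and head ellipse extents
  ca <- abs(cos(mouse$theta)); sa <- abs(sin(mouse$theta))
  body_dx <- geom$body_a * sa + geom$body_b * ca
  body_dy <- geom$body_a * ca + geom$body_b * sa
  head_dx <- geom$head_a * sa + geom$head_b * ca
  head_dy <- geom$head_a * ca + geom$head_b * sa
  xs <- c(mouse$xy[, 1], mouse$center[1] + c(-1, 1) * body_dx,
          mouse$head_center[1] + c(-1, 1) * head_dx)
  ys <- c(mouse$xy[, 2], mouse$center[2] + c(-1, 1) * body_dy,
          mouse$head_center[2] + c(-1, 1) * head_dy)
  c(x0 = floor(min(xs)) - pad, y0 = floor(min(ys)) - pad,
    x1 = ceiling(max(xs)) + pad + 1, y1 = ceiling(max(ys)) + pad + 1)
}

boxes_overlap <- function(a, b) {
  (min(a["x1"], b["x1"]) > max(a["x0"], b["x0"])) &&
    (min(a["y1"], b["y1"]) > max(a["y0"], b["y0"]))
}

box_inside <- function(box, w, h, margin = 2) {
  box["x0"] >= margin && box["y0"] >= margin &&
    box["x1"] <= w - margin && box["y1"] <= h - margin
}

render_mouse <- function(img, mouse, geom, cfg) {
  img <- render_ellipse(img, mouse$center, geom$body_a, geom$body_b,
                        mouse$theta + pi / 2, 0.22)
  img <- render_ellipse(img, mouse$head_center, geom$head_a, geom$head_b,
                        mouse$theta + pi / 2, 0.20)
  spine0 <- mouse$center + mouse$u_ax * geom$body_a * 0.9
  spine1 <- mouse$center - mouse$u_ax * geom$body_a * 0.95
  img <- render_segment(img, spine0, spine1, 2 * (geom$body_b / 21), 0.12)
  info <- keypoint_skeleton()
  for (i in seq_len(nrow(info))) {
    img <- render_segment(img, mouse$xy[info[i, 1], ], mouse$xy[info[i, 2], ],
                          cfg$bone_thickness, cfg$bone_intensity)
  }
  img
}

render_decoy <- function(img, center, theta, geom) {
  # a curled, boneless, oblique body: no keypoints, different aspect
  img <- render_ellipse(img, center, geom$body_a * 0.55, geom$body_b * 1.25,
                        theta, 0.25)
  img <- render_ellipse(img, center + c(cos(theta), sin(theta)) * geom$body_a * 0.45,
                        geom$head_a * 0.9, geom$head_a * 0.9, 0, 0.22)
  img
}

# --- scene generation --------------------------------------------------------

#' Generate one synthetic radiograph scene
#'
#' Renders `config$n_mice` stylized mouse skeletons (body silhouette, head,
#' spine, and six bright bone segments whose endpoints are the stored
#' ground-truth keypoints) over Gaussian background noise. Bones satisfy
#' anatomical adjacency: each femur starts within a small jitter radius of the
#' ipsilateral pelvis end, each tibia within the same radius of the femur end.
#' Generation is deterministic for a fixed `config$seed`.
#'
#' @param config a [scene_config()].
#' @return an object of class `synthetic_scene`: a list with elements `image`
#'   (numeric `image_height x image_width` matrix on `[0, 1]`), `mice` (list of
#'   ground-truth records with `box`, `view`, `keypoints`, `lengths`),
#'   `decoys`, `pixel_spacing` (mm/pixel metadata, default 1) and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  w <- cfg$image_width; h <- cfg$image_height
  scale <- min(w, h) / 256
  geom <- mouse_geometry(scale)
  mice <- list()
  boxes <- list()
  if (cfg$n_mice > 0) {
    # nominal lattice of centers: side by side for two mice
    base_cx <- if (cfg$n_mice == 2) c(0.3, 0.7) * w else 0.5 * w
    placed <- FALSE
    for (attempt in seq_len(50)) {
      mice <- list(); boxes <- list(); ok <- TRUE
      for (i in seq_len(cfg$n_mice)) {
        center <- c(base_cx[i] + stats::runif(1, -10, 10) * scale,
                    0.52 * h + stats::runif(1, -10, 10) * scale)
        theta <- deg2rad(max(-7, min(7, stats::rnorm(1, 0, 3))))
        m <- sample_mouse(center, theta, cfg, geom)
        b <- mouse_box(m, geom, cfg)
        if (!box_inside(b, w, h) ||
            (length(boxes) && any(vapply(boxes, boxes_overlap, logical(1), b)))) {
          ok <- FALSE; break
        }
        mice[[i]] <- m; boxes[[i]] <- b
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) {
      stop("could not place ", cfg$n_mice,
           " non-overlapping mice after 50 attempts; enlarge the image",
           call. = FALSE)
    }
  }
  img <- matrix(0, h, w)
  for (m in mice) img <- render_mouse(img, m, geom, cfg)
  decoys <- list()
  if (cfg$decoy_prob > 0 && stats::runif(1) < cfg$decoy_prob) {
    for (attempt in seq_len(20)) {
      dc <- c(stats::runif(1, 0.15 * w, 0.85 * w), stats::runif(1, 0.12 * h, 0.25 * h))
      db <- c(x0 = dc[1] - geom$body_a * 0.7, y0 = dc[2] - geom$body_a * 0.7,
              x1 = dc[1] + geom$body_a * 0.7, y1 = dc[2] + geom$body_a * 0.7)
      if (box_inside(db, w, h) &&
          !(length(boxes) && any(vapply(boxes, boxes_overlap, logical(1), db)))) {
        th <- stats::runif(1, 0, 2 * pi)
        img <- render_decoy(img, dc, th, geom)
        decoys <- list(list(box = db, view = "side"))
        break
      }
    }
  }
  img <- gaussian_blur(img, cfg$blur_sd)
  if (cfg$background_noise_sd > 0 || TRUE) {
    img <- img + matrix(stats::rnorm(h * w, mean = 0.10, sd = cfg$background_noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)
  records <- lapply(seq_along(mice), function(i) {
    m <- mice[[i]]
    realized <- kp_bone_lengths(keypoint_set(m$xy))
    lengths <- dplyr::left_join(m$lengths, realized, by = c("bone", "side"))
    list(box = as.numeric(boxes[[i]]), view = "top",
         keypoints = keypoint_set(m$xy),
         lengths = lengths, center = m$center, angle = m$theta)
  })
  structure(list(image = img, mice = records, decoys = decoys,
                 pixel_spacing = 1.0, config = cfg),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene: %dx%d px, %d mice, %d decoys>\n",
              x$config$image_width, x$config$image_height,
              length(x$mice), length(x$decoys)))
  invisible(x)
}

#' Ground-truth bone lengths of a scene as a tibble
#'
#' @param scene a `synthetic_scene`.
#' @return tibble with one row per (mouse, bone, side): sampled target length
#'   and realized endpoint distance in pixels.
#' @export
scene_lengths <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  purrr::imap_dfr(scene$mice, function(m, i) {
    dplyr::mutate(m$lengths, mouse = i, .before = 1)
  })
}

#' Generate a dataset of synthetic radiographs on disk
#'
#' Renders `n_images` scenes (1-2 mice each, mouse count sampled uniformly),
#' splits them into train/val/test partitions and writes, per split, the PNG
#' images plus a COCO-keypoints JSON annotation file. Split sizes use
#' largest-remainder rounding so exact fractions are honoured.
#'
#' @param n_images total number of images (>= 3).
#' @param split_fractions numeric vector of three fractions (train, val, test)
#'   summing to 1.
#' @param config a [scene_config()]; its `seed` drives the whole dataset and
#'   its `n_mice` is ignored in favour of per-image sampling from
#'   `n_mice_range`.
#' @param out_dir output directory (created if missing).
#' @param n_mice_range integer range the per-image mouse count is drawn from.
#' @return the dataset manifest: a tibble with one row per image (`split`,
#'   `image`, `n_mice`), invisibly written to `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(n_images, split_fractions, config, out_dir,
                             n_mice_range = c(1L, 2L)) {
  stopifnot(inherits(config, "scene_config"))
  if (n_images < 3) stop("`n_images` must be at least 3", call. = FALSE)
  if (length(split_fractions) != 3 || abs(sum(split_fractions) - 1) > 1e-8) {
    stop("`split_fractions` must be three fractions summing to 1", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop("`out_dir` is not writable: ", out_dir, call. = FALSE)
  }
  sizes <- largest_remainder(n_images, split_fractions)
  splits <- rep(c("train", "val", "test"), sizes)
  counts <- with_seed(config$seed, {
    sample(seq.int(n_mice_range[1], n_mice_range[2]), n_images, replace = TRUE)
  })
  manifest <- vector("list", n_images)
  scenes <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$n_mice <- counts[i]
    # per-image seed derived from the root seed; kept within 32-bit range
    cfg_i$seed <- (config$seed * 7919L + i * 104729L) %% 2147483587L
    scenes[[i]] <- generate_scene(cfg_i)
  }
  for (split in c("train", "val", "test")) {
    idx <- which(splits == split)
    dir.create(file.path(out_dir, split), showWarnings = FALSE)
    entries <- lapply(idx, function(i) {
      fn <- file.path(split, sprintf("scene_%04d.png", i))
      write_image(scenes[[i]]$image, file.path(out_dir, fn))
      list(file_name = fn, scene = scenes[[i]])
    })
    write_coco_keypoints(entries, file.path(out_dir, paste0(split, "_annotations.json")))
    for (e in seq_along(idx)) {
      i <- idx[e]
      manifest[[i]] <- tibble::tibble(split = split,
                                      image = entries[[e]]$file_name,
                                      n_mice = length(scenes[[i]]$mice))
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_idx <- order(raw - sizes, decreasing = TRUE)
    sizes[order_idx[seq_len(rem)]] <- sizes[order_idx[seq_len(rem)]] + 1
  }
  as.integer(sizes)
}

#' Simulate a cohort of aged, sexed bone-length records
#'
#' Draws per-mouse ages and sexes and generates per-bone lengths from a
#' saturating (monoexponential) growth curve with a multiplicative sex effect
#' plus Gaussian measurement noise. Used to exercise the residualization and
#' variance-comparison statistics at desk scale.
#'
#' @param n number of mice.
#' @param seed integer seed.
#' @param age_range range of ages in days (uniformly sampled).
#' @param noise_sd measurement noise standard deviation (length units).
#' @param sex_effect multiplicative length advantage of males.
#' @return tibble with columns `mouse_id`, `age`, `sex`, `bone`, `side`,
#'   `length`, `source`.
#' @export
simulate_cohort <- function(n = 500, seed = 1L, age_range = c(30, 120),
                            noise_sd = 0.35, sex_effect = 1.04) {
  adult <- c(tibia = 18, femur = 15.5, pelvis = 11)  # asymptotic lengths
  with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- sample(c("M", "F"), n, replace = TRUE)
    grid <- tidyr::expand_grid(
      i = seq_len(n),
      bone = c("tibia", "femur", "pelvis"),
      side = c("L", "R")
    )
    grid$age <- age[grid$i]
    grid$sex <- sex[grid$i]
    l_inf <- adult[grid$bone] * ifelse(grid$sex == "M", sex_effect, 1)
    mu <- l_inf * (1 - 0.55 * exp(-0.035 * grid$age))
    grid$length <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    tibble::tibble(
      mouse_id = sprintf("m%05d", grid$i), age = grid$age, sex = grid$sex,
      bone = grid$bone, side = grid$side, length = grid$length,
      source = "manual"
    )
  })
}
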