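# On-disk formats: grayscale images, COCO-keypoints JSON, measurement and
# cohort CSV tables. Readers validate and reject rather than silently coerce.

coco_category <- function() {
  list(
    id = 1L, name = "mouse_top", supercategory = "mouse",
    keypoints = keypoint_names(),
    skeleton = lapply(seq_len(nrow(keypoint_skeleton())),
                      function(i) as.integer(keypoint_skeleton()[i, ]))
  )
}

#' Write a grayscale image
#'
#' Writes a `[0, 1]` intensity matrix as an 8-bit grayscale PNG.
#'
#' @param image numeric matrix with values in `[0, 1]` (rows = y, cols = x).
#' @param path output path ending in `.png`.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Read a grayscale radiograph
#'
#' Reads an 8- or 16-bit PNG or TIFF and returns a `[0, 1]` intensity matrix.
#' Multi-channel images are collapsed by channel averaging. TIFF inputs are
#' linearly rescaled to `[0, 1]` by the image's own min and max.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix (rows = y, cols = x) on `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  img
}

#' Write COCO-keypoints annotations
#'
#' Serializes image entries and their per-mouse keypoint annotations to a
#' COCO-keypoints JSON file (category `mouse_top` with the 12 canonical
#' landmark names and per-bone skeleton edges). Boxes are converted from the
#' package's half-open `[x0, x1) x [y0, y1)` convention to COCO
#' `[x, y, width, height]`.
#'
#' @param entries list of entries; each entry is either
#'   `list(file_name =, scene =)` with a `synthetic_scene`, or
#'   `list(file_name =, width =, height =, annotations =)` where each
#'   annotation is `list(keypoints = keypoint_set, box = c(x0, y0, x1, y1))`.
#' @param path output JSON path.
#' @export
write_coco_keypoints <- function(entries, path) {
  images <- list(); annotations <- list(); ann_id <- 0L
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (!is.null(e$scene)) {
      sc <- e$scene
      e$width <- sc$config$image_width
      e$height <- sc$config$image_height
      e$annotations <- lapply(sc$mice, function(m) {
        list(keypoints = m$keypoints, box = m$box)
      })
    }
    images[[i]] <- list(id = i, file_name = e$file_name,
                        width = e$width, height = e$height)
    for (a in e$annotations) {
      ann_id <- ann_id + 1L
      kp <- a$keypoints
      trip <- as.vector(t(cbind(kp$xy, kp$visibility)))
      box <- a$box
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = i, category_id = 1L,
        keypoints = trip, num_keypoints = sum(kp$visibility > 0),
        bbox = c(box[1], box[2], box[3] - box[1], box[4] - box[2]),
        area = (box[3] - box[1]) * (box[4] - box[2]), iscrowd = 0L
      )
    }
  }
  jsonlite::write_json(
    list(images = images, annotations = annotations,
         categories = list(coco_category())),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read COCO-keypoints annotations
#'
#' Parses a COCO-keypoints JSON file written by [write_coco_keypoints()] (or
#' any schema-compatible file with 12 keypoints per annotation and the
#' `mouse_top` category). The mapping of COCO `(x, y, v)` triplets to
#' [keypoint_set()] objects is lossless.
#'
#' @param path path to the JSON file.
#' @return list of image records, each
#'   `list(file_name, width, height, annotations)`, where each annotation is
#'   `list(keypoints = keypoint_set, box = c(x0, y0, x1, y1), label)`.
#' @export
read_coco_keypoints <- function(path) {
  if (!file.exists(path)) stop("annotation file does not exist: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  for (field in c("images", "annotations", "categories")) {
    if (is.null(doc[[field]])) {
      stop("schema error in ", path, ": missing '", field, "'", call. = FALSE)
    }
  }
  cat_ids <- vapply(doc$categories, function(ct) as.integer(ct$id), integer(1))
  cat_names <- vapply(doc$categories, function(ct) as.character(ct$name), character(1))
  known <- cat_names %in% "mouse_top"
  if (!any(known)) {
    stop("schema error in ", path, ": no 'mouse_top' category", call. = FALSE)
  }
  ok_ids <- cat_ids[known]
  records <- lapply(doc$images, function(im) {
    list(id = as.integer(im$id), file_name = im$file_name,
         width = as.integer(im$width), height = as.integer(im$height),
         annotations = list())
  })
  id_map <- match(vapply(records, `[[`, integer(1), "id"),
                  vapply(records, `[[`, integer(1), "id"))
  ids <- vapply(records, `[[`, integer(1), "id")
  for (a in doc$annotations) {
    if (!as.integer(a$category_id) %in% ok_ids) {
      stop("schema error: annotation id ", a$id, " has unknown category ",
           a$category_id, call. = FALSE)
    }
    trip <- as.numeric(unlist(a$keypoints))
    if (length(trip) != 36) {
      stop("schema error: annotation id ", a$id, " has ",
           length(trip) / 3, " keypoints, expected 12", call. = FALSE)
    }
    m <- matrix(trip, ncol = 3, byrow = TRUE)
    kp <- keypoint_set(m[, 1:2], visibility = as.integer(m[, 3]))
    bb <- as.numeric(unlist(a$bbox))
    box <- c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4])
    j <- which(ids == as.integer(a$image_id))
    if (!length(j)) {
      stop("schema error: annotation id ", a$id, " references unknown image ",
           a$image_id, call. = FALSE)
    }
    records[[j]]$annotations <- c(records[[j]]$annotations,
                                  list(list(keypoints = kp, box = box,
                                            label = "mouse_top")))
  }
  records
}

#' Write bone measurements to CSV
#'
#' One row per (image, mouse, bone, side) with coordinates and lengths printed
#' at fixed 4-decimal precision; quality flags are semicolon-joined.
#'
#' @param measurements tibble as returned by [measure_bones()] /
#'   [refine_measurements()].
#' @param path output CSV path.
#' @export
write_measurements <- function(measurements, path) {
  need <- c("image", "mouse", "bone", "side", "x_start", "y_start",
            "x_end", "y_end", "length_px", "top_view_prob", "flags")
  missing <- setdiff(need, names(measurements))
  if (length(missing)) {
    stop("measurements table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))
  out <- tibble::tibble(
    image = as.character(measurements$image),
    mouse = as.integer(measurements$mouse),
    bone = measurements$bone, side = measurements$side,
    x_start = fmt(measurements$x_start), y_start = fmt(measurements$y_start),
    x_end = fmt(measurements$x_end), y_end = fmt(measurements$y_end),
    length_px = fmt(measurements$length_px),
    top_view_prob = fmt(measurements$top_view_prob),
    flags = vapply(measurements$flags, function(f) paste(f, collapse = ";"),
                   character(1))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read bone measurements from CSV
#'
#' Inverse of [write_measurements()] up to the documented 4-decimal print
#' precision.
#'
#' @param path CSV path.
#' @return tibble with numeric coordinates/lengths and list-column `flags`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    image = readr::col_character(), mouse = readr::col_integer(),
    bone = readr::col_character(), side = readr::col_character(),
    x_start = readr::col_double(), y_start = readr::col_double(),
    x_end = readr::col_double(), y_end = readr::col_double(),
    length_px = readr::col_double(), top_view_prob = readr::col_double(),
    flags = readr::col_character()
  ))
  bad_bone <- setdiff(unique(raw$bone), c("tibia", "femur", "pelvis"))
  if (length(bad_bone)) {
    stop("unknown bone class in measurements: ", paste(bad_bone, collapse = ", "),
         call. = FALSE)
  }
  raw$flags <- lapply(raw$flags, function(f) {
    if (is.na(f) || !nzchar(f)) character(0) else strsplit(f, ";", fixed = TRUE)[[1]]
  })
  raw
}

#' Read a cohort metadata table
#'
#' @param path CSV with columns `mouse_id`, `age`, `sex` and optionally
#'   `bone`, `side`, `length`, `source`.
#' @return validated tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("mouse_id", "age", "sex")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$age <= 0)) stop("cohort ages must be positive", call. = FALSE)
  if (any(!tab$sex %in% c("M", "F"))) {
    stop("cohort sex must be 'M' or 'F'", call. = FALSE)
  }
  if ("length" %in% names(tab) && any(tab$length <= 0, na.rm = TRUE)) {
    stop("cohort lengths must be positive where present", call. = FALSE)
  }
  tab
}
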