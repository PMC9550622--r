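#' Tabular I/O for ground truth, predictions and image-level labels
#'
#' The on-disk interchange format is plain CSV with masks stored as
#' run-length strings ([rle_to_string()]) and label sets as
#' `'|'`-separated grouped class ids:
#'
#' * Ground truth: `image_id,width,height,cell_id,rle,labels` plus optional
#'   `cell_line`, `is_border`, `is_defective`, `nucleus_bbox`
#'   (`row0|col0|row1|col1`, 0-based half-open).
#' * Predictions: `image_id,width,height,cell_id,rle,class_id,confidence`,
#'   one row per (cell, class) detection. A missing `confidence` column
#'   defaults to 1 (label-only submissions).
#' * Image-level labels: `image_id,labels`.
#'
#' Ground-truth masks within one image must be pairwise disjoint and are
#' validated on load; predicted masks may overlap each other, but all rows of
#' one predicted cell must carry the identical mask.
#'
#' @param path File path.
#' @param image_labels_path Optional path to an image-level label CSV; when
#'   absent, each image's weak labels default to the union of its cells'
#'   labels.
#' @param scheme A `class_scheme` used to validate class ids.
#' @return `read_ground_truth()` returns a list with `images` (tibble:
#'   `image_id`, `width`, `height`, `cell_line`, `labels` list-column) and
#'   `cells` (tibble: `image_id`, `cell_id`, `width`, `height`, `rle`,
#'   `labels`, `is_border`, `is_defective`, `nucleus_bbox`).
#'   `read_predictions()` returns a tibble with one detection per row.
#' @name benchmark_io
NULL

label_set_to_string <- function(labels) {
  vapply(labels, function(l) paste(sort(unique(as.integer(l))), collapse = "|"), "")
}

label_set_from_string <- function(s, scheme = default_class_scheme()) {
  lapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) {
      return(integer(0))
    }
    ids <- suppressWarnings(as.integer(strsplit(x, "|", fixed = TRUE)[[1L]]))
    if (anyNA(ids) || any(ids < 0L | ids >= n_classes(scheme))) {
      stop("invalid class id in label set '", x, "' (valid ids: 0..",
           n_classes(scheme) - 1L, ")", call. = FALSE)
    }
    sort(unique(ids))
  })
}

bbox_to_string <- function(bbox) {
  vapply(bbox, function(b) {
    if (is.null(b) || all(is.na(b))) "" else paste(as.integer(b), collapse = "|")
  }, "")
}

bbox_from_string <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) {
      return(NULL)
    }
    b <- as.integer(strsplit(x, "|", fixed = TRUE)[[1L]])
    if (length(b) != 4L || anyNA(b)) {
      stop("invalid nucleus_bbox '", x, "'", call. = FALSE)
    }
    b
  })
}

#' @rdname benchmark_io
#' @export
read_ground_truth <- function(path, image_labels_path = NULL,
                              scheme = default_class_scheme()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    width = readr::col_integer(),
    height = readr::col_integer(),
    cell_id = readr::col_integer(),
    rle = readr::col_character(),
    labels = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  cells <- tibble::tibble(
    image_id = df$image_id,
    cell_id = df$cell_id,
    width = df$width,
    height = df$height,
    rle = df$rle,
    labels = label_set_from_string(df$labels, scheme),
    is_border = if ("is_border" %in% names(df)) {
      as.logical(df$is_border)
    } else {
      rep(FALSE, nrow(df))
    },
    is_defective = if ("is_defective" %in% names(df)) {
      as.logical(df$is_defective)
    } else {
      rep(FALSE, nrow(df))
    },
    nucleus_bbox = if ("nucleus_bbox" %in% names(df)) {
      bbox_from_string(df$nucleus_bbox)
    } else {
      vector("list", nrow(df))
    }
  )
  validate_gt_cells(cells)
  img <- dplyr::distinct(
    tibble::tibble(
      image_id = df$image_id,
      width = df$width,
      height = df$height,
      cell_line = if ("cell_line" %in% names(df)) df$cell_line else NA_character_
    )
  )
  if (anyDuplicated(img$image_id)) {
    stop("inconsistent image dimensions or cell line within one image_id",
         call. = FALSE)
  }
  if (!is.null(image_labels_path)) {
    il <- read_image_labels(image_labels_path, scheme)
    img$labels <- il$labels[match(img$image_id, il$image_id)]
    if (any(vapply(img$labels, is.null, TRUE))) {
      stop("image-level label file is missing images present in ground truth",
           call. = FALSE)
    }
  } else {
    img$labels <- lapply(img$image_id, function(id) {
      sort(unique(unlist(cells$labels[cells$image_id == id])))
    })
  }
  list(images = img, cells = cells)
}

validate_gt_cells <- function(cells) {
  if (nrow(cells) == 0L) {
    return(invisible(cells))
  }
  if (any(cells$cell_id < 1L)) {
    stop("cell_id must be >= 1", call. = FALSE)
  }
  key <- paste(cells$image_id, cells$cell_id)
  if (anyDuplicated(key)) {
    stop("duplicate (image_id, cell_id) in ground truth", call. = FALSE)
  }
  if (any(lengths(cells$labels) == 0L)) {
    stop("ground-truth cells must carry at least one label", call. = FALSE)
  }
  # per-image instance disjointness and mask non-emptiness
  for (id in unique(cells$image_id)) {
    sub <- cells[cells$image_id == id, ]
    idx <- lapply(seq_len(nrow(sub)), function(i) {
      r <- rle_from_string(sub$rle[i], sub$width[i], sub$height[i])
      fg <- rle_foreground_indices(r)
      if (length(fg) == 0L) {
        stop("empty mask for cell ", sub$cell_id[i], " in image ", id,
             call. = FALSE)
      }
      fg
    })
    all_px <- unlist(idx)
    if (anyDuplicated(all_px)) {
      stop("ground-truth masks overlap in image ", id, call. = FALSE)
    }
  }
  invisible(cells)
}

#' @rdname benchmark_io
#' @param gt A list with `images` and `cells` as returned by
#'   [read_ground_truth()] or [generate_dataset()].
#' @export
write_ground_truth <- function(gt, path) {
  cells <- gt$cells
  img <- gt$images
  df <- tibble::tibble(
    image_id = cells$image_id,
    width = cells$width,
    height = cells$height,
    cell_id = cells$cell_id,
    rle = cells$rle,
    labels = label_set_to_string(cells$labels),
    cell_line = img$cell_line[match(cells$image_id, img$image_id)],
    is_border = cells$is_border,
    is_defective = cells$is_defective,
    nucleus_bbox = bbox_to_string(cells$nucleus_bbox)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname benchmark_io
#' @export
read_predictions <- function(path, scheme = default_class_scheme()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    width = readr::col_integer(),
    height = readr::col_integer(),
    cell_id = readr::col_integer(),
    rle = readr::col_character(),
    class_id = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!"confidence" %in% names(df)) {
    df$confidence <- 1
  }
  pred <- tibble::tibble(
    image_id = df$image_id, width = df$width, height = df$height,
    cell_id = df$cell_id, rle = df$rle, class_id = df$class_id,
    confidence = df$confidence
  )
  validate_predictions(pred, scheme)
  pred
}

validate_predictions <- function(pred, scheme = default_class_scheme()) {
  if (nrow(pred) == 0L) {
    return(invisible(pred))
  }
  if (any(pred$class_id < 0L | pred$class_id >= n_classes(scheme))) {
    stop("prediction class_id out of range 0..", n_classes(scheme) - 1L,
         call. = FALSE)
  }
  if (anyNA(pred$confidence) || any(pred$confidence < 0 | pred$confidence > 1)) {
    stop("confidences must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(pred$image_id, pred$cell_id, pred$class_id)
  if (anyDuplicated(key)) {
    stop("duplicate (image_id, cell_id, class_id) in predictions",
         call. = FALSE)
  }
  # all detections of one predicted cell must carry the identical mask
  cell_key <- paste(pred$image_id, pred$cell_id)
  n_masks <- tapply(pred$rle, cell_key, function(x) length(unique(x)))
  if (any(n_masks > 1L)) {
    stop("a predicted cell carries different masks across its detections",
         call. = FALSE)
  }
  invisible(pred)
}

#' @rdname benchmark_io
#' @param pred A prediction tibble.
#' @export
write_predictions <- function(pred, path) {
  readr::write_csv(
    pred[, c("image_id", "width", "height", "cell_id", "rle",
             "class_id", "confidence")],
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname benchmark_io
#' @export
read_image_labels <- function(path, scheme = default_class_scheme()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    labels = readr::col_character()
  ), progress = FALSE)
  tibble::tibble(image_id = df$image_id,
                 labels = label_set_from_string(df$labels, scheme))
}

#' @rdname benchmark_io
#' @param images An image tibble with `image_id` and a `labels` list-column.
#' @export
write_image_labels <- function(images, path) {
  readr::write_csv(
    tibble::tibble(image_id = images$image_id,
                   labels = label_set_to_string(images$labels)),
    path, progress = FALSE
  )
  invisible(path)
}

#' Extract cell instances from an instance label image
#'
#' Turns a labelmap (integer raster, 0 = background, one positive id per
#' cell) into per-cell mask records. Instances are disjoint by construction.
#' The border flag is set from the nucleus bounding box when a nucleus
#' labelmap is supplied (a cell is a border cell when its nucleus touches
#' the image boundary); otherwise from the cell mask itself.
#'
#' @param labelmap Integer matrix; values 0 (background) or instance ids.
#' @param image_id Image identifier for the emitted records.
#' @param nucleus_labelmap Optional integer matrix of the same shape with
#'   matching instance ids marking each cell's nucleus.
#' @param expected_dim Optional `c(height, width)`; a mismatch with
#'   `dim(labelmap)` raises an error.
#' @return A cell tibble in the [read_ground_truth()] layout (without
#'   labels).
#' @export
labelmap_to_instances <- function(labelmap, image_id,
                                  nucleus_labelmap = NULL,
                                  expected_dim = NULL) {
  if (!is.null(expected_dim) && !identical(dim(labelmap), as.integer(expected_dim))) {
    stop("labelmap dimensions ", paste(dim(labelmap), collapse = "x"),
         " do not match expected ", paste(expected_dim, collapse = "x"),
         call. = FALSE)
  }
  h <- nrow(labelmap)
  w <- ncol(labelmap)
  ids <- sort(unique(labelmap[labelmap > 0L]))
  rows <- lapply(ids, function(id) {
    mask <- matrix(as.integer(labelmap == id), nrow = h)
    nuc_bbox <- NULL
    if (!is.null(nucleus_labelmap)) {
      hit <- which(nucleus_labelmap == id, arr.ind = TRUE)
      if (nrow(hit)) {
        # 0-based half-open [row0,row1) x [col0,col1)
        nuc_bbox <- c(min(hit[, 1L]) - 1L, min(hit[, 2L]) - 1L,
                      max(hit[, 1L]), max(hit[, 2L]))
      }
    }
    if (!is.null(nuc_bbox)) {
      border <- nuc_bbox[1L] == 0L || nuc_bbox[2L] == 0L ||
        nuc_bbox[3L] == h || nuc_bbox[4L] == w
    } else {
      border <- any(mask[1L, ] > 0L) || any(mask[h, ] > 0L) ||
        any(mask[, 1L] > 0L) || any(mask[, w] > 0L)
    }
    tibble::tibble(
      image_id = image_id, cell_id = as.integer(id),
      width = w, height = h,
      rle = rle_to_string(encode_rle(mask)),
      labels = list(integer(0)),
      is_border = border, is_defective = FALSE,
      nucleus_bbox = list(nuc_bbox)
    )
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(
      image_id = character(0), cell_id = integer(0),
      width = integer(0), height = integer(0), rle = character(0),
      labels = list(), is_border = logical(0), is_defective = logical(0),
      nucleus_bbox = list()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Read an instance label image (PNG or TIFF)
#'
#' @param path Path to a single-channel 8- or 16-bit PNG or TIFF labelmap
#'   (0 = background, positive integers = instance ids).
#' @return Integer matrix of instance ids.
#' @export
read_instance_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth %||% 16L
    if (length(dim(img)) == 3L) {
      img <- img[, , 1L]
    }
    storage.mode(img) <- "double"
    return(matrix(as.integer(round(img * (2^depth - 1))), nrow = nrow(img)))
  }
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
      img <- img[, , 1L]
    }
    return(matrix(as.integer(img), nrow = nrow(img)))
  }
  stop("unsupported instance image format: ", ext, call. = FALSE)
}
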