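# In-code fixture builders shared across test files.

mask_rect <- function(h, w, rows, cols) {
  m <- matrix(0L, h, w)
  m[rows, cols] <- 1L
  m
}

random_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# Build a ground-truth dataset from explicit masks and label sets.
# masks: named list image_id -> list of binary matrices (one per cell);
# labels: same shape, integer vectors of grouped class ids.
gt_fixture <- function(masks, labels, is_border = NULL, is_defective = NULL,
                       image_labels = NULL, cell_line = NULL) {
  cell_rows <- list()
  img_rows <- list()
  for (img in names(masks)) {
    ms <- masks[[img]]
    lb <- labels[[img]]
    h <- nrow(ms[[1L]])
    w <- ncol(ms[[1L]])
    for (i in seq_along(ms)) {
      cell_rows[[length(cell_rows) + 1L]] <- tibble::tibble(
        image_id = img, cell_id = i, width = w, height = h,
        rle = rle_to_string(encode_rle(ms[[i]])),
        labels = list(sort(as.integer(lb[[i]]))),
        is_border = if (is.null(is_border)) FALSE else is_border[[img]][i],
        is_defective = if (is.null(is_defective)) FALSE else is_defective[[img]][i],
        nucleus_bbox = list(NULL)
      )
    }
    il <- if (is.null(image_labels)) {
      sort(unique(unlist(lb)))
    } else {
      sort(as.integer(image_labels[[img]]))
    }
    img_rows[[length(img_rows) + 1L]] <- tibble::tibble(
      image_id = img, width = w, height = h,
      cell_line = if (is.null(cell_line)) "SYN-A" else cell_line[[img]],
      labels = list(il)
    )
  }
  list(images = dplyr::bind_rows(img_rows), cells = dplyr::bind_rows(cell_rows))
}

# Build a prediction table from masks plus a detection data frame with
# columns cell_id, class_id, confidence.
pred_fixture <- function(image_id, masks, detections) {
  h <- nrow(masks[[1L]])
  w <- ncol(masks[[1L]])
  tibble::tibble(
    image_id = image_id, width = w, height = h,
    cell_id = as.integer(detections$cell_id),
    rle = vapply(detections$cell_id,
                 function(i) rle_to_string(encode_rle(masks[[i]])), ""),
    class_id = as.integer(detections$class_id),
    confidence = detections$confidence
  )
}

# A small corrupted benchmark instance for oracle-equivalence testing.
random_instance <- function(seed) {
  n_cells <- 2L + seed %% 6L  # 2..7 cells
  sim <- generate_dataset(sim_config(
    n_images = 1L, image_size = 64L, cells_per_image = n_cells,
    multilabel_rate = 0.3, heterogeneity_rate = 0.5, border_rate = 0.2,
    negative_rate = 0.1, seed = seed
  ))
  corr <- corruption_config(
    mask_erosion_px = seed %% 3L,
    label_drop_rate = 0.2, label_swap_rate = 0.2,
    confidence_noise_sd = 0.3, seed = seed + 1L
  )
  pred <- make_predictions_from_gt(sim, corr)
  list(gt = sim, pred = pred)
}
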