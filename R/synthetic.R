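#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the label structure of a weakly supervised
#' single-cell localization benchmark: multi-cell fields of view with
#' non-overlapping cell instances, each containing a nucleus; per-cell label
#' sets of 1-4 grouped classes drawn from configurable class frequencies;
#' image-level weak labels formed as the union of the cell labels; planted
#' single-cell heterogeneity; and border cells whose nucleus touches the
#' image edge. Geometry is deliberately simple (axis-aligned ellipses on a
#' jittered grid): the contract is geometric validity, not photorealism.
#'
#' @param n_images Number of images.
#' @param image_size Image side length in pixels (square images).
#' @param cells_per_image Mean cells per image (Poisson-distributed,
#'   at least 1), default 20.
#' @param class_frequencies 19 positive reals (normalized internally). The
#'   default spans `imbalance_orders` orders of magnitude on a log scale
#'   across the classes, emulating a class-imbalanced benchmark.
#' @param imbalance_orders Dynamic range of the default frequencies in
#'   orders of magnitude (default 2).
#' @param multilabel_rate Per-slot probability of extra labels: each cell
#'   set has `1 + Binomial(3, multilabel_rate)` classes (default 0.25,
#'   giving roughly half of the label sets more than one class).
#' @param heterogeneity_rate Probability that an image with at least two
#'   non-border cells carries two distinct label sets (default 0.2).
#' @param border_rate Probability that a cell in an edge position is pushed
#'   so that its nucleus touches the image boundary (default 0.1).
#' @param negative_rate Probability that an image is a negative control
#'   (all cells Negative; default 0.05).
#' @param n_cell_lines Number of synthetic cell-line identifiers cycled
#'   through the images (default 5).
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_images = 50L, image_size = 256L,
                       cells_per_image = 20L, class_frequencies = NULL,
                       imbalance_orders = 2, multilabel_rate = 0.25,
                       heterogeneity_rate = 0.2, border_rate = 0.1,
                       negative_rate = 0.05, n_cell_lines = 5L, seed = 1L) {
  k <- 19L
  if (is.null(class_frequencies)) {
    class_frequencies <- 10^seq(0, -imbalance_orders, length.out = k)
  }
  stopifnot(length(class_frequencies) == k, all(class_frequencies > 0),
            multilabel_rate >= 0, multilabel_rate <= 1,
            heterogeneity_rate >= 0, heterogeneity_rate <= 1,
            border_rate >= 0, border_rate <= 1,
            negative_rate >= 0, negative_rate <= 1,
            n_images >= 1, image_size >= 16, cells_per_image >= 1)
  # feasibility: the packing grid needs slots of at least 8 px even for a
  # high draw from the Poisson cell count
  worst_n <- stats::qpois(0.999, cells_per_image)
  if (floor(image_size / ceiling(sqrt(max(1, worst_n)))) < 8) {
    stop("infeasible packing: too many cells for image_size", call. = FALSE)
  }
  structure(list(
    n_images = as.integer(n_images), image_size = as.integer(image_size),
    cells_per_image = cells_per_image,
    class_frequencies = class_frequencies / sum(class_frequencies),
    multilabel_rate = multilabel_rate,
    heterogeneity_rate = heterogeneity_rate,
    border_rate = border_rate, negative_rate = negative_rate,
    n_cell_lines = as.integer(n_cell_lines), seed = as.integer(seed)
  ), class = "sim_config")
}

# sample() treats a scalar first argument as 1:x; guard against that
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Rasterize one axis-aligned ellipse into `map`, clipped at the image
# boundary. Returns the updated map.
rasterize_ellipse <- function(map, id, cy, cx, ry, rx) {
  h <- nrow(map)
  w <- ncol(map)
  rows <- max(1L, cy - ry):min(h, cy + ry)
  cols <- max(1L, cx - rx):min(w, cx + rx)
  inside <- outer(((rows - cy) / ry)^2, ((cols - cx) / rx)^2, `+`) <= 1
  sub <- map[rows, cols, drop = FALSE]
  sub[inside] <- id
  map[rows, cols] <- sub
  map
}

draw_label_set <- function(cfg) {
  primary <- sample.int(19L, 1L, prob = cfg$class_frequencies) - 1L
  if (primary == 18L) {
    return(18L)
  }
  n_extra <- stats::rbinom(1L, 3L, cfg$multilabel_rate)
  if (n_extra > 0L) {
    pool <- setdiff(0:17, primary)
    extras <- sample(pool, min(n_extra, length(pool)),
                     prob = cfg$class_frequencies[pool + 1L])
    sort(unique(c(primary, extras)))
  } else {
    primary
  }
}

#' Generate a seeded synthetic benchmark dataset
#'
#' @param config A [sim_config()].
#' @return A list with `images` (tibble `image_id`, `width`, `height`,
#'   `cell_line`, `labels`) and `cells` (ground-truth cell tibble in the
#'   [read_ground_truth()] layout). Ground-truth instances are pairwise
#'   disjoint by construction; every image label is carried by at least one
#'   cell and vice versa.
#' @examples
#' sim <- generate_dataset(sim_config(n_images = 3, cells_per_image = 6,
#'                                    seed = 42))
#' nrow(sim$cells)
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sz <- config$image_size
  lines <- sprintf("SYN-%s", LETTERS[seq_len(config$n_cell_lines)])
  withr::with_seed(config$seed, {
    img_rows <- vector("list", config$n_images)
    cell_rows <- vector("list", config$n_images)
    for (ii in seq_len(config$n_images)) {
      image_id <- sprintf("synimg_%04d", ii)
      n_c <- max(1L, stats::rpois(1L, config$cells_per_image))
      g <- ceiling(sqrt(n_c))
      s <- floor(sz / g)
      slots <- sample.int(g * g, n_c)
      labelmap <- matrix(0L, sz, sz)
      nucmap <- matrix(0L, sz, sz)
      for (cc in seq_len(n_c)) {
        slot <- slots[cc] - 1L
        gr <- slot %/% g
        gc <- slot %% g
        r0 <- gr * s
        c0 <- gc * s
        rlo <- max(3L, floor(s * 0.30))
        rhi <- max(rlo, min(floor(s * 0.47), (s - 1L) %/% 2L))
        rx <- sample1(rlo:rhi)
        ry <- sample1(rlo:rhi)
        rnx <- max(1L, rx %/% 2L)
        rny <- max(1L, ry %/% 2L)
        cx <- sample1((c0 + rx + 1L):(c0 + s - rx))
        cy <- sample1((r0 + ry + 1L):(r0 + s - ry))
        # nucleus jitter small enough that the nucleus stays inside the cell
        jx <- max(0L, floor(0.15 * rx))
        jy <- max(0L, floor(0.15 * ry))
        dx <- sample1(-jx:jx)
        dy <- sample1(-jy:jy)
        # border planting: push edge cells so the nucleus touches the image
        # boundary (truncating the cell mask there)
        edges <- c(if (gr == 0L) "top", if (gr == g - 1L) "bottom",
                   if (gc == 0L) "left", if (gc == g - 1L) "right")
        if (length(edges) && stats::runif(1) < config$border_rate) {
          edge <- sample1(edges)
          if (edge == "top") {
            cy <- rny
            dy <- 0L
          } else if (edge == "bottom") {
            cy <- sz - rny + 1L
            dy <- 0L
          } else if (edge == "left") {
            cx <- rnx
            dx <- 0L
          } else {
            cx <- sz - rnx + 1L
            dx <- 0L
          }
        }
        labelmap <- rasterize_ellipse(labelmap, cc, cy, cx, ry, rx)
        nucmap <- rasterize_ellipse(nucmap, cc, cy + dy, cx + dx, rny, rnx)
      }
      # nuclei are defined as the intersection with their cell mask
      nucmap[nucmap != labelmap] <- 0L
      cells <- labelmap_to_instances(labelmap, image_id,
                                     nucleus_labelmap = nucmap)
      n_c <- nrow(cells)
      # labels
      if (stats::runif(1) < config$negative_rate) {
        base <- 18L
      } else {
        base <- draw_label_set(config)
      }
      lab <- rep(list(base), n_c)
      eligible <- which(!cells$is_border)
      if (!identical(base, 18L) && length(eligible) >= 2L &&
          stats::runif(1) < config$heterogeneity_rate) {
        variant <- if (length(base) >= 2L) {
          sort(setdiff(base, sample(base, 1L)))
        } else {
          pool <- setdiff(0:17, base)
          sort(c(base, sample(pool, 1L,
                              prob = config$class_frequencies[pool + 1L])))
        }
        n_var <- sample.int(length(eligible) - 1L, 1L)
        for (j in sample(eligible, n_var)) {
          lab[[j]] <- variant
        }
      }
      cells$labels <- lab
      line <- sample(lines, 1L)
      img_rows[[ii]] <- tibble::tibble(
        image_id = image_id, width = sz, height = sz, cell_line = line,
        labels = list(sort(unique(unlist(lab))))
      )
      cell_rows[[ii]] <- cells
    }
  })
  list(images = dplyr::bind_rows(img_rows),
       cells = dplyr::bind_rows(cell_rows))
}

#' Configuration for the prediction corruptor
#'
#' @param mask_erosion_px,mask_dilation_px Morphological erosion/dilation
#'   radius in pixels applied to every predicted mask (Chebyshev metric).
#' @param label_drop_rate Probability of dropping each ground-truth label
#'   from a cell's detections.
#' @param label_swap_rate Probability of replacing each surviving label with
#'   a uniformly drawn different class.
#' @param confidence_noise_sd Detection confidences are `1 - |N(0, sd)|`,
#'   clipped to `[0.01, 1]`; 0 gives exact confidence 1.
#' @param seed Integer seed.
#' @return A `corruption_config` list.
#' @export
corruption_config <- function(mask_erosion_px = 0L, mask_dilation_px = 0L,
                              label_drop_rate = 0, label_swap_rate = 0,
                              confidence_noise_sd = 0, seed = 1L) {
  stopifnot(mask_erosion_px >= 0, mask_dilation_px >= 0,
            label_drop_rate >= 0, label_drop_rate <= 1,
            label_swap_rate >= 0, label_swap_rate <= 1,
            confidence_noise_sd >= 0)
  structure(list(
    mask_erosion_px = as.integer(mask_erosion_px),
    mask_dilation_px = as.integer(mask_dilation_px),
    label_drop_rate = label_drop_rate, label_swap_rate = label_swap_rate,
    confidence_noise_sd = confidence_noise_sd, seed = as.integer(seed)
  ), class = "corruption_config")
}

#' Derive a (corrupted) prediction table from ground truth
#'
#' Copies the ground-truth cells into a detection table and degrades them
#' according to the corruption configuration: masks are eroded/dilated,
#' labels dropped or swapped, confidences jittered. With the all-zero
#' default configuration the result is a perfect submission (identical
#' masks, identical labels, confidence 1), which must score mAP = 1.
#' Cells whose mask erodes away entirely are dropped and recorded in the
#' `"dropped_cells"` attribute.
#'
#' @param gt Dataset list with `cells` (and `images`), e.g. from
#'   [generate_dataset()].
#' @param corruption A [corruption_config()].
#' @return Prediction tibble (`image_id`, `width`, `height`, `cell_id`,
#'   `rle`, `class_id`, `confidence`).
#' @export
make_predictions_from_gt <- function(gt, corruption = corruption_config()) {
  stopifnot(inherits(corruption, "corruption_config"))
  cells <- gt$cells
  morph <- corruption$mask_erosion_px > 0L || corruption$mask_dilation_px > 0L
  withr::with_seed(corruption$seed, {
    rles <- cells$rle
    if (morph) {
      rles <- vapply(seq_len(nrow(cells)), function(i) {
        m <- decode_rle(rle_from_string(cells$rle[i], cells$width[i],
                                        cells$height[i]))
        if (corruption$mask_erosion_px > 0L) {
          m <- EBImage::erode(
            m, EBImage::makeBrush(2L * corruption$mask_erosion_px + 1L,
                                  shape = "box"))
        }
        if (corruption$mask_dilation_px > 0L) {
          m <- EBImage::dilate(
            m, EBImage::makeBrush(2L * corruption$mask_dilation_px + 1L,
                                  shape = "box"))
        }
        m <- matrix(as.integer(m > 0), nrow = cells$height[i])
        if (sum(m) == 0L) {
          return(NA_character_)
        }
        rle_to_string(encode_rle(m))
      }, "")
    }
    dropped <- cells[is.na(rles), c("image_id", "cell_id")]
    rows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      if (is.na(rles[i])) next
      labels <- cells$labels[[i]]
      if (corruption$label_drop_rate > 0) {
        labels <- labels[stats::runif(length(labels)) >= corruption$label_drop_rate]
      }
      if (corruption$label_swap_rate > 0 && length(labels)) {
        swap <- stats::runif(length(labels)) < corruption$label_swap_rate
        labels[swap] <- vapply(labels[swap], function(l) {
          sample(setdiff(0:18, l), 1L)
        }, 0L)
        labels <- sort(unique(labels))
      }
      if (length(labels) == 0L) next
      conf <- if (corruption$confidence_noise_sd > 0) {
        pmin(1, pmax(0.01, 1 - abs(stats::rnorm(length(labels), 0,
                                                corruption$confidence_noise_sd))))
      } else {
        rep(1, length(labels))
      }
      rows[[i]] <- tibble::tibble(
        image_id = cells$image_id[i], width = cells$width[i],
        height = cells$height[i], cell_id = cells$cell_id[i],
        rle = rles[i], class_id = as.integer(labels), confidence = conf
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(image_id = character(0), width = integer(0),
                          height = integer(0), cell_id = integer(0),
                          rle = character(0), class_id = integer(0),
                          confidence = numeric(0))
  }
  attr(out, "dropped_cells") <- dropped
  out
}
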