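#' Refinement configuration
#'
#' Controls how the product of image-level labels and single-cell class
#' probabilities is rounded. The weak-label refinement multiplies the binary
#' image-level label vector (`il_labels`) with the per-cell probability
#' vector (`sc_labels`) and rounds the product, so a class survives only
#' when the image carries it *and* the cell-level model supports it.
#' Rounding any nonzero product up to 1 (`"ceil"`) keeps every image label
#' with nonzero probability; half-up rounding at a threshold (`"halfup"`,
#' default 0.5) removes low-certainty labels and is the default.
#'
#' @param rounding `"halfup"` (default) or `"ceil"`.
#' @param threshold Retention threshold in (0, 1) for half-up rounding; a
#'   class is kept when its probability is `>= threshold`.
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(rounding = c("halfup", "ceil"), threshold = 0.5) {
  rounding <- match.arg(rounding)
  stopifnot(threshold > 0, threshold < 1)
  structure(list(rounding = rounding, threshold = threshold),
            class = "refinement_config")
}

#' Refine one cell's labels from image-level labels and class probabilities
#'
#' Implements the weak-label refinement: every cell starts from the full
#' image-level label set, and each label is retained only when the cell's
#' class probability supports it (`>= threshold` under half-up rounding;
#' `> 0` under ceiling rounding). Because the image labels gate the product,
#' refinement can never add a class the image does not carry. A cell whose
#' set empties becomes Negative.
#'
#' @param il_labels Integer vector of grouped class ids: the image-level
#'   (weak) labels.
#' @param probs Numeric vector of per-class probabilities in `[0, 1]`,
#'   length [n_classes()], position `i` holding class id `i - 1`.
#' @param config A [refinement_config()].
#' @param scheme A `class_scheme`.
#' @return Sorted integer vector of retained grouped class ids (never
#'   empty; `{Negative}` as fallback).
#' @export
refine_cell_labels <- function(il_labels, probs,
                               config = refinement_config(),
                               scheme = default_class_scheme()) {
  k <- n_classes(scheme)
  if (length(probs) != k) {
    stop("probs must have length ", k, call. = FALSE)
  }
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  il_labels <- sort(unique(as.integer(il_labels)))
  if (length(il_labels) && (min(il_labels) < 0L || max(il_labels) >= k)) {
    stop("image-level class id out of range", call. = FALSE)
  }
  keep <- switch(config$rounding,
    halfup = il_labels[probs[il_labels + 1L] >= config$threshold],
    ceil = il_labels[probs[il_labels + 1L] > 0]
  )
  if (length(keep) == 0L) {
    keep <- negative_class(scheme)
  }
  as.integer(keep)
}

#' Refine a whole dataset of cells
#'
#' Applies [refine_cell_labels()] to every cell and summarizes how many
#' labels each class lost.
#'
#' @param image_labels Tibble `image_id`, `labels` (list-column of grouped
#'   ids).
#' @param probs Tibble `image_id`, `cell_id`, `p0`..`p18` (per-class
#'   probabilities).
#' @param config A [refinement_config()].
#' @param scheme A `class_scheme`.
#' @return Tibble `image_id`, `cell_id`, `labels` (refined sets). The
#'   attribute `"removed_per_class"` counts, per class, image labels that
#'   refinement removed from a cell.
#' @export
refine_dataset <- function(image_labels, probs,
                           config = refinement_config(),
                           scheme = default_class_scheme()) {
  k <- n_classes(scheme)
  pcols <- paste0("p", seq_len(k) - 1L)
  if (!all(pcols %in% names(probs))) {
    stop("probability table must have columns ", pcols[1L], "..",
         pcols[k], call. = FALSE)
  }
  il_row <- match(probs$image_id, image_labels$image_id)
  if (anyNA(il_row)) {
    stop("cells reference images with no image-level labels: ",
         paste(utils::head(unique(probs$image_id[is.na(il_row)]), 3L),
               collapse = ", "), call. = FALSE)
  }
  pm <- as.matrix(probs[, pcols])
  removed <- integer(k)
  refined <- vector("list", nrow(probs))
  for (i in seq_len(nrow(probs))) {
    il <- image_labels$labels[[il_row[i]]]
    refined[[i]] <- refine_cell_labels(il, pm[i, ], config, scheme)
    lost <- setdiff(il, refined[[i]])
    removed[lost + 1L] <- removed[lost + 1L] + 1L
  }
  out <- tibble::tibble(image_id = probs$image_id, cell_id = probs$cell_id,
                        labels = refined)
  attr(out, "removed_per_class") <- stats::setNames(removed,
                                                    scheme$grouped_classes)
  out
}

#' Proteins that multi-localize on images but single-localize per cell
#'
#' A protein qualifies when the union of its image-level label sets contains
#' at least two classes (it multi-localizes at the population level) while
#' every one of its refined single-cell label sets contains exactly one
#' class — the signature of precisely coordinated translocation rather than
#' simultaneous residence in several compartments.
#'
#' @param image_labels Tibble `protein`, `labels` (list-column; one row per
#'   image or one aggregated row per protein).
#' @param cell_labels Tibble `protein`, `labels` (list-column; one row per
#'   refined cell).
#' @return Character vector of qualifying protein identifiers.
#' @export
single_location_multilocalizers <- function(image_labels, cell_labels) {
  proteins <- intersect(unique(image_labels$protein),
                        unique(cell_labels$protein))
  keep <- vapply(proteins, function(p) {
    il_union <- unique(unlist(image_labels$labels[image_labels$protein == p]))
    if (length(il_union) < 2L) {
      return(FALSE)
    }
    sizes <- lengths(cell_labels$labels[cell_labels$protein == p])
    length(sizes) > 0L && all(sizes == 1L)
  }, TRUE)
  proteins[keep]
}
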