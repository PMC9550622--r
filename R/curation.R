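#' Curation configuration
#'
#' Thresholds for the dataset-cleaning filters. An image is removed when
#' strictly more than `negative_fraction_threshold` of its cells are
#' Negative, when strictly more than `defective_fraction_threshold` are
#' flagged defective, or when every cell's label set equals the image-level
#' label set (such homogeneous images carry no single-cell information
#' beyond their weak labels).
#'
#' @param negative_fraction_threshold,defective_fraction_threshold Reals in
#'   `[0, 1]`; both default to 0.5 with a strict `>` comparison.
#' @param exclude_border_cells Exclude border cells from heterogeneity
#'   accounting (default `TRUE`).
#' @return A `curation_config` list.
#' @export
curation_config <- function(negative_fraction_threshold = 0.5,
                            defective_fraction_threshold = 0.5,
                            exclude_border_cells = TRUE) {
  stopifnot(negative_fraction_threshold >= 0, negative_fraction_threshold <= 1,
            defective_fraction_threshold >= 0, defective_fraction_threshold <= 1)
  structure(list(
    negative_fraction_threshold = negative_fraction_threshold,
    defective_fraction_threshold = defective_fraction_threshold,
    exclude_border_cells = exclude_border_cells
  ), class = "curation_config")
}

#' Filter images by negative fraction, defective fraction and homogeneity
#'
#' @param images Image tibble with `image_id` and `labels` list-column.
#' @param cells Cell tibble with `image_id`, `labels`, `is_defective`.
#' @param config A [curation_config()].
#' @param scheme A `class_scheme`.
#' @return List with `kept` (image tibble) and `removed` (tibble `image_id`,
#'   `reason` in `negative_fraction` / `defective_fraction` /
#'   `matches_image_labels`). Reasons are assigned in that priority order,
#'   one per removed image. Re-filtering the kept set is a no-op.
#' @export
filter_images <- function(images, cells, config = curation_config(),
                          scheme = default_class_scheme()) {
  neg <- negative_class(scheme)
  removed <- tibble::tibble(image_id = character(0), reason = character(0))
  keep <- rep(TRUE, nrow(images))
  for (i in seq_len(nrow(images))) {
    sub <- cells[cells$image_id == images$image_id[i], ]
    if (nrow(sub) == 0L) next
    frac_neg <- mean(vapply(sub$labels, function(l) neg %in% l, TRUE))
    frac_def <- mean(sub$is_defective)
    il <- sort(unique(images$labels[[i]]))
    all_match <- all(vapply(sub$labels, function(l) {
      identical(sort(unique(as.integer(l))), as.integer(il))
    }, TRUE))
    reason <- NULL
    if (frac_neg > config$negative_fraction_threshold) {
      reason <- "negative_fraction"
    } else if (frac_def > config$defective_fraction_threshold) {
      reason <- "defective_fraction"
    } else if (all_match) {
      reason <- "matches_image_labels"
    }
    if (!is.null(reason)) {
      keep[i] <- FALSE
      removed <- dplyr::bind_rows(
        removed,
        tibble::tibble(image_id = images$image_id[i], reason = reason)
      )
    }
  }
  list(kept = images[keep, ], removed = removed)
}

label_set_key <- function(labels) {
  vapply(labels, function(l) paste(sort(unique(as.integer(l))), collapse = "|"), "")
}

#' Is an image heterogeneous?
#'
#' An image is heterogeneous when its eligible cells do not all carry the
#' same label set. Cells whose nucleus lies on the image border are excluded
#' from the comparison when `exclude_border` is set, since their patterns
#' are only partially observed.
#'
#' @param cells Cell tibble for one image (`labels`, `is_border`).
#' @param exclude_border Exclude border cells (default `TRUE`).
#' @return `TRUE`/`FALSE`, or `NA` when no eligible cell remains.
#' @export
is_heterogeneous <- function(cells, exclude_border = TRUE) {
  eligible <- if (exclude_border) cells[!cells$is_border, ] else cells
  if (nrow(eligible) == 0L) {
    return(NA)
  }
  length(unique(label_set_key(eligible$labels))) >= 2L
}

#' Heterogeneity census across a dataset
#'
#' Counts heterogeneous and homogeneous images per group (by default per
#' cell line).
#'
#' @param images Image tibble (`image_id`, grouping column).
#' @param cells Cell tibble (`image_id`, `labels`, `is_border`).
#' @param group_by Name of the grouping column in `images`; default
#'   `"cell_line"`.
#' @param exclude_border Passed to [is_heterogeneous()].
#' @return Tibble with the group, `n_heterogeneous`, `n_homogeneous`,
#'   `n_undefined` (images with no eligible cells) and `n_images`.
#' @export
heterogeneity_census <- function(images, cells, group_by = "cell_line",
                                 exclude_border = TRUE) {
  if (!group_by %in% names(images)) {
    stop("grouping column '", group_by, "' not present", call. = FALSE)
  }
  het <- vapply(images$image_id, function(id) {
    is_heterogeneous(cells[cells$image_id == id, ], exclude_border)
  }, NA)
  grp <- images[[group_by]]
  out <- tibble::tibble(
    group = sort(unique(grp)),
    n_heterogeneous = vapply(sort(unique(grp)), function(g) {
      sum(het[grp == g], na.rm = TRUE)
    }, 0L),
    n_homogeneous = vapply(sort(unique(grp)), function(g) {
      sum(!het[grp == g], na.rm = TRUE)
    }, 0L),
    n_undefined = vapply(sort(unique(grp)), function(g) {
      sum(is.na(het[grp == g]))
    }, 0L),
    n_images = vapply(sort(unique(grp)), function(g) sum(grp == g), 0L)
  )
  names(out)[1L] <- group_by
  out
}

#' Fraction of multiply-annotated cells with fully consistent labels
#'
#' A cell counts as consistent when all of its annotators assigned the
#' identical label set (order-invariant set comparison).
#'
#' @param annotations Named list: one element per cell, each a list of the
#'   annotators' label sets (integer vectors). Every cell needs at least two
#'   annotations.
#' @return Fraction of cells with all-identical annotations.
#' @export
annotator_agreement <- function(annotations) {
  if (length(annotations) == 0L) {
    stop("empty overlap set", call. = FALSE)
  }
  if (any(lengths(annotations) < 2L)) {
    stop("every cell needs at least two annotations", call. = FALSE)
  }
  consistent <- vapply(annotations, function(sets) {
    keys <- vapply(sets, function(s) paste(sort(unique(as.integer(s))), collapse = "|"), "")
    length(unique(keys)) == 1L
  }, TRUE)
  mean(consistent)
}

#' Chance probability of two annotators agreeing on a pre-specified label set
#'
#' Null model for annotator agreement: two annotators independently draw
#' `k_labels_each` specified labels uniformly from `n_labels` candidates;
#' the probability that both reproduce the same pre-specified selection is
#' `(1/n)^(2k)`. With 30 organelle labels this gives 0.1% for one label and
#' 0.0001% for two, so observed agreement far above these levels cannot be
#' chance.
#'
#' @param n_labels Number of candidate labels (>= 1).
#' @param k_labels_each Number of labels each annotator assigns (>= 1).
#' @return Probability in `(0, 1]`.
#' @export
chance_agreement <- function(n_labels, k_labels_each = 1L) {
  if (n_labels < 1L || k_labels_each < 1L) {
    stop("n_labels and k_labels_each must be >= 1", call. = FALSE)
  }
  (1 / n_labels)^(2 * k_labels_each)
}

#' Class-balance-preserving public/private split
#'
#' Randomized split of images into a public and a private side that
#' preserves the per-class cell-count proportions on both sides: from a
#' seeded random split of the requested size, greedy pairwise swaps are
#' applied whenever they reduce the maximum per-class absolute proportion
#' gap between the two sides.
#'
#' @param cells Cell tibble (`image_id`, `labels`).
#' @param public_fraction Fraction of images on the public side, in (0, 1).
#' @param seed Integer seed; identical seeds give identical splits.
#' @param n_iter Number of candidate swaps (default 1000).
#' @param scheme A `class_scheme`.
#' @return A `split_result`: `public_ids`, `private_ids`, `proportions`
#'   (per-class cell-count share on each side) and `max_gap`.
#' @export
stratified_split <- function(cells, public_fraction = 0.31, seed = 1L,
                             n_iter = 1000L, scheme = default_class_scheme()) {
  stopifnot(public_fraction > 0, public_fraction < 1)
  image_ids <- sort(unique(cells$image_id))
  n <- length(image_ids)
  if (n < 2L) {
    stop("need at least two images to split", call. = FALSE)
  }
  k <- n_classes(scheme)
  counts <- matrix(0L, nrow = n, ncol = k,
                   dimnames = list(image_ids, scheme$grouped_classes))
  row_of <- match(cells$image_id, image_ids)
  for (i in seq_len(nrow(cells))) {
    lab <- cells$labels[[i]]
    counts[row_of[i], lab + 1L] <- counts[row_of[i], lab + 1L] + 1L
  }
  present <- colSums(counts) > 0L
  rare <- colSums(counts > 0L) < 2L & present
  if (any(rare)) {
    warning("classes present in fewer than two images: ",
            paste(scheme$grouped_classes[rare], collapse = ", "),
            "; best-effort split", call. = FALSE)
  }
  n_pub <- max(1L, min(n - 1L, round(public_fraction * n)))
  gap_of <- function(pub) {
    cp <- colSums(counts[pub, , drop = FALSE])
    cq <- colSums(counts[!pub, , drop = FALSE])
    pp <- cp / max(1L, sum(cp))
    pq <- cq / max(1L, sum(cq))
    max(abs(pp - pq)[present])
  }
  withr::with_seed(seed, {
    pub <- rep(FALSE, n)
    pub[sample.int(n, n_pub)] <- TRUE
    gap <- gap_of(pub)
    for (it in seq_len(n_iter)) {
      i <- sample(which(pub), 1L)
      j <- sample(which(!pub), 1L)
      cand <- pub
      cand[i] <- FALSE
      cand[j] <- TRUE
      g2 <- gap_of(cand)
      if (g2 < gap) {
        pub <- cand
        gap <- g2
      }
    }
  })
  cp <- colSums(counts[pub, , drop = FALSE])
  cq <- colSums(counts[!pub, , drop = FALSE])
  structure(
    list(
      public_ids = image_ids[pub],
      private_ids = image_ids[!pub],
      proportions = tibble::tibble(
        class_id = seq_len(k) - 1L,
        class = scheme$grouped_classes,
        public = cp / max(1L, sum(cp)),
        private = cq / max(1L, sum(cq))
      ),
      max_gap = gap
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result: %d public / %d private images, max class gap %.4f>\n",
              length(x$public_ids), length(x$private_ids), x$max_gap))
  invisible(x)
}
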