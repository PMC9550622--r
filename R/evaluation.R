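#' Intersection over union of two binary masks
#'
#' `IOU(p, g) = |p intersect g| / |p union g|` by pixel counting, the
#' mask-similarity criterion used to match predicted cells to ground-truth
#' cells.
#'
#' @param p,g Binary matrices (or `rle_mask` objects) of equal dimensions.
#' @return A real in `[0, 1]`; 1 exactly when the masks are identical.
#' @export
compute_iou <- function(p, g) {
  if (inherits(p, "rle_mask")) p <- decode_rle(p)
  if (inherits(g, "rle_mask")) g <- decode_rle(g)
  if (!identical(dim(p), dim(g))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  pi <- which(p != 0)
  gi <- which(g != 0)
  iou_from_indices(pi, gi)
}

iou_from_indices <- function(pi, gi) {
  ni <- length(intersect(pi, gi))
  nu <- length(pi) + length(gi) - ni
  if (nu == 0L) {
    stop("IOU undefined for two empty masks", call. = FALSE)
  }
  ni / nu
}

#' Pairwise IOU matrix between predicted and ground-truth cells of one image
#'
#' @param pred_cells,gt_cells Cell tibbles (columns `cell_id`, `rle`,
#'   `width`, `height`) restricted to a single image.
#' @return Numeric matrix with one row per predicted cell and one column per
#'   ground-truth cell; dimnames carry the cell ids.
#' @export
iou_matrix <- function(pred_cells, gt_cells) {
  p_idx <- lapply(seq_len(nrow(pred_cells)), function(i) {
    rle_foreground_indices(
      rle_from_string(pred_cells$rle[i], pred_cells$width[i], pred_cells$height[i])
    )
  })
  g_idx <- lapply(seq_len(nrow(gt_cells)), function(i) {
    rle_foreground_indices(
      rle_from_string(gt_cells$rle[i], gt_cells$width[i], gt_cells$height[i])
    )
  })
  m <- matrix(0, nrow = length(p_idx), ncol = length(g_idx),
              dimnames = list(as.character(pred_cells$cell_id),
                              as.character(gt_cells$cell_id)))
  for (i in seq_along(p_idx)) {
    pr <- range(p_idx[[i]])
    for (j in seq_along(g_idx)) {
      gr <- range(g_idx[[j]])
      if (pr[1L] > gr[2L] || gr[1L] > pr[2L]) next  # index ranges disjoint
      ni <- length(intersect(p_idx[[i]], g_idx[[j]]))
      if (ni > 0L) {
        m[i, j] <- ni / (length(p_idx[[i]]) + length(g_idx[[j]]) - ni)
      }
    }
  }
  m
}

#' One-to-one matching of predicted to ground-truth masks
#'
#' Greedy matching by descending IOU among pairs at or above the threshold,
#' with a deterministic tie-break (descending IOU, then ascending
#' ground-truth id, then ascending predicted id). Each cell joins at most
#' one pair; the remainder is reported as unmatched.
#'
#' @param iou IOU matrix from [iou_matrix()] (rows = predicted cells,
#'   columns = ground-truth cells).
#' @param threshold Matching threshold in `(0, 1]`; default 0.6. The
#'   comparison is inclusive (`IOU >= threshold`) unless `strict = TRUE`.
#' @param strict Use a strict `>` comparison instead.
#' @return A `match_set`: list with `pairs` (tibble `pred_id`, `gt_id`,
#'   `iou`), `unmatched_pred` and `unmatched_gt` (character ids).
#' @export
match_instances <- function(iou, threshold = 0.6, strict = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  pred_ids <- rownames(iou) %||% as.character(seq_len(nrow(iou)))
  gt_ids <- colnames(iou) %||% as.character(seq_len(ncol(iou)))
  ok <- if (strict) which(iou > threshold) else which(iou >= threshold)
  pairs <- tibble::tibble(pred_id = character(0), gt_id = character(0),
                          iou = numeric(0))
  if (length(ok)) {
    pi <- (ok - 1L) %% nrow(iou) + 1L
    gi <- (ok - 1L) %/% nrow(iou) + 1L
    # tie-break: descending IOU, then ascending gt id, then ascending pred id
    ord <- order(-iou[ok], id_rank(gt_ids)[gi], id_rank(pred_ids)[pi])
    used_p <- logical(nrow(iou))
    used_g <- logical(ncol(iou))
    sel <- integer(0)
    for (k in ord) {
      if (!used_p[pi[k]] && !used_g[gi[k]]) {
        used_p[pi[k]] <- TRUE
        used_g[gi[k]] <- TRUE
        sel <- c(sel, k)
      }
    }
    pairs <- tibble::tibble(
      pred_id = pred_ids[pi[sel]],
      gt_id = gt_ids[gi[sel]],
      iou = iou[cbind(pi[sel], gi[sel])]
    )
  }
  structure(
    list(pairs = pairs,
         unmatched_pred = setdiff(pred_ids, pairs$pred_id),
         unmatched_gt = setdiff(gt_ids, pairs$gt_id)),
    class = "match_set"
  )
}

# rank ids numerically when they all parse as numbers, else lexicographically
id_rank <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (anyNA(num)) rank(ids, ties.method = "first") else rank(num, ties.method = "first")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set: %d pairs, %d unmatched pred, %d unmatched gt>\n",
              nrow(x$pairs), length(x$unmatched_pred), length(x$unmatched_gt)))
  invisible(x)
}

#' Classify detections into true/false positives per class
#'
#' Given the mask matching and the per-cell class detections, a detection of
#' class `c` on a matched predicted cell is a true positive exactly when `c`
#' belongs to its matched ground-truth cell's label set; every other
#' detection — wrong class on a matched cell, or any detection on an
#' unmatched cell — is a false positive. False negatives per class are
#' ground-truth instances carrying the class that no true-positive detection
#' accounts for.
#'
#' @param matches Named list of `match_set` objects, one per image.
#' @param detections Prediction tibble (`image_id`, `cell_id`, `class_id`,
#'   `confidence`).
#' @param gt_cells Ground-truth cell tibble with `labels` list-column.
#' @param scheme A `class_scheme`.
#' @return List with `scored` (tibble `class_id`, `confidence`, `is_tp`,
#'   `image_id`, `cell_id`) and `n_positives` (integer vector indexed by
#'   class id 0-based: ground-truth instances carrying each class).
#' @export
classify_detections <- function(matches, detections, gt_cells,
                                scheme = default_class_scheme()) {
  k <- n_classes(scheme)
  n_pos <- integer(k)
  for (lab in gt_cells$labels) {
    n_pos[lab + 1L] <- n_pos[lab + 1L] + 1L
  }
  # matched gt cell (key image|gt_id) for each matched pred cell
  match_of <- character(0)
  for (img in names(matches)) {
    p <- matches[[img]]$pairs
    if (nrow(p)) {
      match_of[paste0(img, "|", p$pred_id)] <- paste0(img, "|", p$gt_id)
    }
  }
  gt_key <- paste0(gt_cells$image_id, "|", gt_cells$cell_id)
  if (nrow(detections)) {
    det_cell <- paste0(detections$image_id, "|", detections$cell_id)
    unknown <- !det_cell %in% unlist(lapply(names(matches), function(img) {
      ms <- matches[[img]]
      c(paste0(img, "|", ms$pairs$pred_id), paste0(img, "|", ms$unmatched_pred))
    }))
    if (any(unknown)) {
      stop("detections reference cells absent from the match computation: ",
           paste(utils::head(unique(det_cell[unknown]), 3L), collapse = ", "),
           call. = FALSE)
    }
    matched_gt <- match_of[det_cell]
    gt_row <- match(matched_gt, gt_key)
    is_tp <- !is.na(gt_row) & mapply(function(r, cls) {
      !is.na(r) && cls %in% gt_cells$labels[[r]]
    }, gt_row, detections$class_id)
    scored <- tibble::tibble(
      class_id = detections$class_id,
      confidence = detections$confidence,
      is_tp = as.logical(is_tp),
      image_id = detections$image_id,
      cell_id = detections$cell_id
    )
  } else {
    scored <- tibble::tibble(
      class_id = integer(0), confidence = numeric(0), is_tp = logical(0),
      image_id = character(0), cell_id = integer(0)
    )
  }
  list(scored = scored, n_positives = n_pos)
}

#' Average precision over a confidence-ranked detection list
#'
#' Detections are ranked by descending confidence (ties broken by
#' `image_id`, `cell_id`, `class_id` so the result is invariant to input row
#' order); precision `p = TP/(TP+FP)` and recall `r = TP/(TP+FN)` are
#' evaluated at every cut of the ranking, and AP is the integral of the
#' interpolated precision envelope over recall from 0 to 1 (the all-point
#' interpolation, with precision at each recall taken as the maximum
#' precision at any equal-or-higher recall).
#'
#' @param scored Tibble with columns `confidence`, `is_tp` and (for the
#'   tie-break) optionally `image_id`, `cell_id`, `class_id`.
#' @param n_positives Number of ground-truth positives for the class
#'   (`TP + FN`); when 0 the class has no defined AP and `NA` is returned.
#' @return AP in `[0, 1]`, or `NA` when `n_positives == 0`.
#' @export
average_precision <- function(scored, n_positives) {
  if (n_positives < 0) {
    stop("n_positives must be non-negative", call. = FALSE)
  }
  if (n_positives == 0L) {
    return(NA_real_)
  }
  n <- nrow(scored)
  if (n == 0L) {
    return(0)
  }
  ord <- order(
    -scored$confidence,
    if ("image_id" %in% names(scored)) scored$image_id else rep("", n),
    if ("cell_id" %in% names(scored)) scored$cell_id else rep(0L, n),
    if ("class_id" %in% names(scored)) scored$class_id else rep(0L, n)
  )
  tp <- cumsum(as.integer(scored$is_tp[ord]))
  fp <- seq_len(n) - tp
  precision <- tp / (tp + fp)
  recall <- tp / n_positives
  envelope <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * envelope)
}

#' Precision-recall curve for one class
#'
#' @inheritParams average_precision
#' @return Tibble with `confidence`, `tp`, `fp`, `fn`, `precision`, `recall`
#'   at every cut of the ranking.
#' @export
pr_curve <- function(scored, n_positives) {
  n <- nrow(scored)
  if (n == 0L) {
    return(tibble::tibble(confidence = numeric(0), tp = integer(0),
                          fp = integer(0), fn = integer(0),
                          precision = numeric(0), recall = numeric(0)))
  }
  ord <- order(-scored$confidence,
               if ("image_id" %in% names(scored)) scored$image_id else rep("", n),
               if ("cell_id" %in% names(scored)) scored$cell_id else rep(0L, n),
               if ("class_id" %in% names(scored)) scored$class_id else rep(0L, n))
  tp <- cumsum(as.integer(scored$is_tp[ord]))
  fp <- seq_len(n) - tp
  tibble::tibble(
    confidence = scored$confidence[ord],
    tp = tp, fp = fp, fn = n_positives - tp,
    precision = tp / (tp + fp),
    recall = if (n_positives > 0) tp / n_positives else rep(NA_real_, n)
  )
}

#' Score a submission: mAP at an IOU threshold across grouped classes
#'
#' The complete scoring pipeline: per image, predicted masks are matched
#' one-to-one to ground-truth masks at the IOU threshold (class-agnostic,
#' mask-first); detections are pooled globally across images within each
#' class, ranked by confidence, and summarized as average precision; the
#' final score is the mean AP over classes present in the ground truth
#' (classes with no ground-truth positives are reported as `NA` and excluded
#' from the mean unless `absent_as_zero = TRUE`).
#'
#' @param gt Ground truth as a list with `images` and `cells`
#'   ([read_ground_truth()] / [generate_dataset()]).
#' @param predictions Prediction tibble ([read_predictions()] /
#'   [make_predictions_from_gt()]).
#' @param threshold IOU matching threshold (default 0.6).
#' @param scheme A `class_scheme`.
#' @param strict Use strict `IOU > threshold` matching.
#' @param absent_as_zero Score classes absent from the ground truth as
#'   AP = 0 instead of excluding them from the mean.
#' @return An `eval_report`: list with `per_class_ap` (named by class),
#'   `map` (mean AP), `mean_matched_iou`, `tallies` (per-class TP/FP/FN),
#'   `n_matched`, `threshold`.
#' @examples
#' sim <- generate_dataset(sim_config(n_images = 2, cells_per_image = 4,
#'                                    seed = 7))
#' pred <- make_predictions_from_gt(sim)
#' rep <- evaluate_submission(sim, pred)
#' rep$map
#' @export
evaluate_submission <- function(gt, predictions, threshold = 0.6,
                                scheme = default_class_scheme(),
                                strict = FALSE, absent_as_zero = FALSE) {
  validate_predictions(predictions, scheme)
  gt_cells <- gt$cells
  image_ids <- unique(c(gt_cells$image_id, predictions$image_id))
  pred_cells <- dplyr::distinct(
    predictions[, c("image_id", "cell_id", "width", "height", "rle")]
  )
  matches <- list()
  for (img in image_ids) {
    pc <- pred_cells[pred_cells$image_id == img, ]
    gc <- gt_cells[gt_cells$image_id == img, ]
    m <- iou_matrix(pc, gc)
    matches[[img]] <- match_instances(m, threshold = threshold, strict = strict)
  }
  cls <- classify_detections(matches, predictions, gt_cells, scheme)
  k <- n_classes(scheme)
  per_class_ap <- stats::setNames(rep(NA_real_, k), scheme$grouped_classes)
  tp_c <- fp_c <- integer(k)
  for (c_id in seq_len(k) - 1L) {
    sc <- cls$scored[cls$scored$class_id == c_id, ]
    n_pos <- cls$n_positives[c_id + 1L]
    per_class_ap[c_id + 1L] <- average_precision(sc, n_pos)
    tp_c[c_id + 1L] <- sum(sc$is_tp)
    fp_c[c_id + 1L] <- sum(!sc$is_tp)
  }
  fn_c <- cls$n_positives - tp_c
  defined <- !is.na(per_class_ap)
  ap_for_mean <- per_class_ap
  if (absent_as_zero) {
    ap_for_mean[!defined] <- 0
    defined <- rep(TRUE, k)
  }
  all_pairs <- dplyr::bind_rows(lapply(matches, function(m) m$pairs))
  structure(
    list(
      per_class_ap = per_class_ap,
      map = mean(ap_for_mean[defined]),
      mean_matched_iou = if (nrow(all_pairs)) mean(all_pairs$iou) else NA_real_,
      tallies = tibble::tibble(
        class_id = seq_len(k) - 1L,
        class = scheme$grouped_classes,
        tp = tp_c, fp = fp_c, fn = fn_c,
        n_positives = cls$n_positives
      ),
      n_matched = nrow(all_pairs),
      threshold = threshold
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Submission score at IOU >= %.2f\n", x$threshold))
  cat(sprintf("  mAP:              %.4f\n", x$map))
  cat(sprintf("  mean matched IOU: %.4f (%d matched pairs)\n",
              x$mean_matched_iou, x$n_matched))
  defined <- !is.na(x$per_class_ap)
  cat(sprintf("  classes scored:   %d of %d\n", sum(defined),
              length(x$per_class_ap)))
  invisible(x)
}

#' Mean IOU over matched pairs
#'
#' Arithmetic mean of the pair IOUs across one or more match sets: the
#' segmentation-quality summary of a submission.
#'
#' @param matches A `match_set` or a list of them.
#' @return Mean IOU, or `NA` when there are no matched pairs.
#' @export
mean_matched_iou <- function(matches) {
  if (inherits(matches, "match_set")) {
    matches <- list(matches)
  }
  ious <- unlist(lapply(matches, function(m) m$pairs$iou))
  if (length(ious) == 0L) {
    return(NA_real_)
  }
  mean(ious)
}
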