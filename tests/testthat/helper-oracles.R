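# Independent reference implementations used to validate the package's fast
# paths. These deliberately use naive per-pixel / per-cut / exhaustive
# algorithms and share no code with the implementations they check.

# --- naive RLE codec: explicit pixel walk in the declared scan order
# (top-to-bottom within a column, columns left-to-right) ---------------------

naive_rle_counts <- function(mask) {
  counts <- integer(0)
  cur_val <- 0L
  cur_len <- 0L
  for (col in seq_len(ncol(mask))) {
    for (row in seq_len(nrow(mask))) {
      px <- as.integer(mask[row, col])
      if (px == cur_val) {
        cur_len <- cur_len + 1L
      } else {
        counts <- c(counts, cur_len)
        cur_val <- px
        cur_len <- 1L
      }
    }
  }
  c(counts, cur_len)
}

naive_rle_decode <- function(counts, height, width) {
  m <- matrix(0L, height, width)
  pos <- 0L
  val <- 0L
  for (len in counts) {
    if (len > 0L && val == 1L) {
      for (p in (pos + 1L):(pos + len)) {
        row <- (p - 1L) %% height + 1L
        col <- (p - 1L) %/% height + 1L
        m[row, col] <- 1L
      }
    }
    pos <- pos + len
    val <- 1L - val
  }
  m
}

# --- exhaustive one-to-one matching maximizing total IOU --------------------

oracle_match_pairs <- function(iou, threshold = 0.6) {
  elig <- which(iou >= threshold, arr.ind = TRUE)
  if (nrow(elig) == 0L) {
    return(elig)
  }
  best <- list(score = -1, rows = integer(0))
  n <- nrow(elig)
  rec <- function(k, used_p, used_g, chosen, score) {
    if (score > best$score) {
      best <<- list(score = score, rows = chosen)
    }
    if (k > n) {
      return()
    }
    for (j in k:n) {
      p <- elig[j, 1L]
      g <- elig[j, 2L]
      if (!used_p[p] && !used_g[g]) {
        up <- used_p
        up[p] <- TRUE
        ug <- used_g
        ug[g] <- TRUE
        rec(j + 1L, up, ug, c(chosen, j), score + iou[p, g])
      }
    }
  }
  rec(1L, logical(nrow(iou)), logical(ncol(iou)), integer(0), 0)
  elig[best$rows, , drop = FALSE]
}

# --- all-cuts AP: recompute precision/recall from scratch at every cut of
# the ranking, then integrate the precision envelope over unique recalls ----

oracle_ap <- function(confidence, is_tp, n_pos,
                      image_id = rep("", length(confidence)),
                      cell_id = rep(0L, length(confidence)),
                      class_id = rep(0L, length(confidence))) {
  if (n_pos == 0L) {
    return(NA_real_)
  }
  n <- length(confidence)
  if (n == 0L) {
    return(0)
  }
  ord <- order(-confidence, image_id, cell_id, class_id)
  prec <- rec <- numeric(n)
  for (k in seq_len(n)) {
    kept <- ord[seq_len(k)]
    tp <- sum(is_tp[kept])
    prec[k] <- tp / k
    rec[k] <- tp / n_pos
  }
  ap <- 0
  prev <- 0
  for (r in sort(unique(rec))) {
    if (r == 0) next
    ap <- ap + (r - prev) * max(prec[rec >= r])
    prev <- r
  }
  ap
}

# --- end-to-end brute-force scorer ------------------------------------------

oracle_evaluate <- function(gt, predictions, threshold = 0.6, n_class = 19L) {
  gt_cells <- gt$cells
  image_ids <- unique(c(gt_cells$image_id, predictions$image_id))
  matched_gt_of <- character(0)  # pred key -> gt key
  all_ious <- numeric(0)
  for (img in image_ids) {
    pc <- unique(predictions[predictions$image_id == img,
                             c("cell_id", "rle", "width", "height")])
    gc <- gt_cells[gt_cells$image_id == img, ]
    if (nrow(pc) == 0L || nrow(gc) == 0L) next
    iou <- matrix(0, nrow(pc), nrow(gc))
    for (i in seq_len(nrow(pc))) {
      pm <- decode_rle(rle_from_string(pc$rle[i], pc$width[i], pc$height[i]))
      for (j in seq_len(nrow(gc))) {
        gm <- decode_rle(rle_from_string(gc$rle[j], gc$width[j], gc$height[j]))
        iou[i, j] <- compute_iou(pm, gm)
      }
    }
    pairs <- oracle_match_pairs(iou, threshold)
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        matched_gt_of[paste0(img, "|", pc$cell_id[pairs[r, 1L]])] <-
          paste0(img, "|", gc$cell_id[pairs[r, 2L]])
        all_ious <- c(all_ious, iou[pairs[r, 1L], pairs[r, 2L]])
      }
    }
  }
  gt_key <- paste0(gt_cells$image_id, "|", gt_cells$cell_id)
  n_pos <- integer(n_class)
  for (lab in gt_cells$labels) {
    n_pos[lab + 1L] <- n_pos[lab + 1L] + 1L
  }
  aps <- rep(NA_real_, n_class)
  for (c_id in seq_len(n_class) - 1L) {
    det <- predictions[predictions$class_id == c_id, ]
    is_tp <- logical(nrow(det))
    if (nrow(det)) {
      for (i in seq_len(nrow(det))) {
        gk <- matched_gt_of[paste0(det$image_id[i], "|", det$cell_id[i])]
        is_tp[i] <- !is.na(gk) &&
          c_id %in% gt_cells$labels[[match(gk, gt_key)]]
      }
    }
    aps[c_id + 1L] <- oracle_ap(det$confidence, is_tp, n_pos[c_id + 1L],
                                det$image_id, det$cell_id, det$class_id)
  }
  list(per_class_ap = aps,
       map = mean(aps[!is.na(aps)]),
       mean_matched_iou = if (length(all_ious)) mean(all_ious) else NA_real_,
       n_matched = length(all_ious))
}
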