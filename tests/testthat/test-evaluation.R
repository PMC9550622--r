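test_that("IOU is exact pixel counting", {
  a <- mask_rect(4, 4, 1:2, 1:2)
  expect_equal(compute_iou(a, a), 1)
  expect_equal(compute_iou(a, mask_rect(4, 4, 3:4, 3:4)), 0)
  # two 2x2 squares overlapping in 2 pixels: 2 / 6
  b <- mask_rect(4, 4, 1:2, 2:3)
  expect_equal(compute_iou(a, b), 2 / 6)
  expect_error(compute_iou(a, mask_rect(5, 5, 1:2, 1:2)), "dimensions")
})

test_that("matching is one-to-one at the threshold with greedy resolution", {
  g <- mask_rect(10, 10, 2:7, 2:7)          # 36 px
  p_exact <- g
  p_half <- mask_rect(10, 10, 2:7, 2:4)     # 18 px subset: IOU 0.5
  p_hi <- mask_rect(10, 10, 2:7, 2:6)       # 30 px subset: IOU 30/36 ~ 0.83
  p_lo <- mask_rect(10, 10, 2:6, 2:7)       # 30 px subset, different shape

  m <- iou_matrix(tibble::tibble(cell_id = 1L,
                                 rle = rle_to_string(encode_rle(p_exact)),
                                 width = 10L, height = 10L),
                  tibble::tibble(cell_id = 1L,
                                 rle = rle_to_string(encode_rle(g)),
                                 width = 10L, height = 10L))
  ms <- match_instances(m, 0.6)
  expect_equal(nrow(ms$pairs), 1L)
  expect_equal(ms$pairs$iou, 1)

  # IOU 0.5 leaves both sides unmatched at threshold 0.6
  m2 <- matrix(0.5, 1, 1, dimnames = list("1", "1"))
  ms2 <- match_instances(m2, 0.6)
  expect_equal(nrow(ms2$pairs), 0L)
  expect_equal(ms2$unmatched_pred, "1")
  expect_equal(ms2$unmatched_gt, "1")
  # the comparison is inclusive by default, strict on request
  m3 <- matrix(0.6, 1, 1, dimnames = list("1", "1"))
  expect_equal(nrow(match_instances(m3, 0.6)$pairs), 1L)
  expect_equal(nrow(match_instances(m3, 0.6, strict = TRUE)$pairs), 0L)

  # two preds over one gt: only the higher-IOU pred is matched, and the
  # exhaustive assignment oracle agrees
  m4 <- matrix(c(0.9, 0.7), 2, 1, dimnames = list(c("1", "2"), "1"))
  ms4 <- match_instances(m4, 0.6)
  expect_equal(ms4$pairs$pred_id, "1")
  expect_equal(ms4$unmatched_pred, "2")
  expect_equal(unname(oracle_match_pairs(m4, 0.6)[, 1L]), 1L)
})

test_that("raising the threshold never increases the matched-pair count", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      n_p <- sample(1:6, 1)
      n_g <- sample(1:6, 1)
      iou <- matrix(stats::runif(n_p * n_g), n_p, n_g)
      prev <- Inf
      for (thr in c(0.3, 0.5, 0.7, 0.9)) {
        n_pairs <- nrow(match_instances(iou, thr)$pairs)
        expect_lte(n_pairs, prev)
        prev <- n_pairs
      }
    }
  })
})

test_that("detection accounting follows the matched-pair label sets", {
  g1 <- mask_rect(12, 12, 2:5, 2:5)
  g2 <- mask_rect(12, 12, 8:11, 8:11)
  gt <- gt_fixture(masks = list(img = list(g1, g2)),
                   labels = list(img = list(c(16L, 14L), 2L)))
  # pred 1 matches gt 1 but detects only Cytosol (16); pred 2 is a stray
  # blob matching nothing, carrying 3 detections
  stray <- mask_rect(12, 12, 2:5, 8:11)
  pred <- pred_fixture("img", list(g1, stray),
                       data.frame(cell_id = c(1, 2, 2, 2),
                                  class_id = c(16, 0, 1, 2),
                                  confidence = c(0.9, 0.8, 0.7, 0.6)))
  rep <- evaluate_submission(gt, pred)
  t <- rep$tallies
  expect_equal(t$tp[t$class_id == 16], 1L)           # Cytosol detected
  expect_equal(t$fn[t$class_id == 14], 1L)           # Mitochondria missed
  expect_equal(sum(t$fp), 3L)                        # stray cell: 3 FPs
  expect_equal(t$fn[t$class_id == 2], 1L)            # unmatched gt class
  # conservation: TP + FN equals the gt instance count per class
  expect_equal(t$tp + t$fn, t$n_positives)
})

test_that("average precision reproduces hand-computed rankings", {
  # single TP with one positive
  expect_equal(average_precision(
    tibble::tibble(confidence = 1, is_tp = TRUE), 1), 1)
  # ranking [TP, FP, TP] with 2 positives: 0.5*1 + 0.5*(2/3)
  sc <- tibble::tibble(confidence = c(0.9, 0.8, 0.7),
                       is_tp = c(TRUE, FALSE, TRUE))
  expect_equal(average_precision(sc, 2), 5 / 6)
  # no detections but positives exist
  expect_equal(average_precision(sc[0, ], 3), 0)
  # no positives: AP undefined
  expect_true(is.na(average_precision(sc, 0)))
  expect_error(average_precision(sc, -1), "non-negative")
})

test_that("streaming AP equals the all-cuts oracle on random rankings", {
  withr::with_seed(99, {
    for (rep in 1:300) {
      n <- sample(0:25, 1)
      conf <- round(stats::runif(n), 2)  # coarse grid forces ties
      is_tp <- stats::runif(n) < 0.5
      n_pos <- sum(is_tp) + sample(0:5, 1)
      sc <- tibble::tibble(confidence = conf, is_tp = is_tp,
                           image_id = sample(letters[1:3], n, replace = TRUE),
                           cell_id = sample.int(50, n),
                           class_id = rep(1L, n))
      expect_equal(average_precision(sc, n_pos),
                   oracle_ap(conf, is_tp, n_pos, sc$image_id, sc$cell_id,
                             sc$class_id))
    }
  })
})

test_that("the report is invariant under prediction row permutation", {
  inst <- random_instance(7)
  rep1 <- evaluate_submission(inst$gt, inst$pred)
  withr::with_seed(1, {
    shuffled <- inst$pred[sample.int(nrow(inst$pred)), ]
  })
  rep2 <- evaluate_submission(inst$gt, shuffled)
  expect_equal(rep1$per_class_ap, rep2$per_class_ap)
  expect_equal(rep1$map, rep2$map)
  expect_equal(rep1$mean_matched_iou, rep2$mean_matched_iou)
})

test_that("a perfect submission scores mAP 1 and empty predictions score 0", {
  sim <- generate_dataset(sim_config(n_images = 3, image_size = 96,
                                     cells_per_image = 5, seed = 13))
  perfect <- make_predictions_from_gt(sim)
  rep <- evaluate_submission(sim, perfect)
  expect_equal(rep$map, 1)
  expect_equal(rep$mean_matched_iou, 1)
  empty <- perfect[0, ]
  rep0 <- evaluate_submission(sim, empty)
  expect_equal(rep0$map, 0)
  expect_true(is.na(rep0$mean_matched_iou))
})

test_that("classes absent from the ground truth are excluded from the mean", {
  g1 <- mask_rect(8, 8, 2:5, 2:5)
  gt <- gt_fixture(masks = list(img = list(g1)),
                   labels = list(img = list(0L)))
  pred <- pred_fixture("img", list(g1),
                       data.frame(cell_id = 1, class_id = 0, confidence = 1))
  rep <- evaluate_submission(gt, pred)
  expect_equal(sum(!is.na(rep$per_class_ap)), 1L)
  expect_equal(rep$map, 1)
  # absent-as-zero semantics on request
  rep0 <- evaluate_submission(gt, pred, absent_as_zero = TRUE)
  expect_equal(rep0$map, 1 / 19)
})

test_that("mean matched IOU is the arithmetic mean of pair IOUs", {
  ms <- structure(list(pairs = tibble::tibble(pred_id = c("1", "2"),
                                              gt_id = c("1", "2"),
                                              iou = c(0.6, 0.8)),
                       unmatched_pred = character(0),
                       unmatched_gt = character(0)),
                  class = "match_set")
  expect_equal(mean_matched_iou(ms), 0.7)
  empty <- structure(list(pairs = tibble::tibble(iou = numeric(0)),
                          unmatched_pred = "1", unmatched_gt = character(0)),
                     class = "match_set")
  expect_true(is.na(mean_matched_iou(empty)))
  # recompute from the pair list on a random fixture
  inst <- random_instance(3)
  rep <- evaluate_submission(inst$gt, inst$pred)
  ora <- oracle_evaluate(inst$gt, inst$pred)
  expect_equal(rep$mean_matched_iou, ora$mean_matched_iou)
})
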