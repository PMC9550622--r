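blank_mask <- function(i) mask_rect(8, 8, (2 * i - 1):(2 * i), 1:2)

four_cell_image <- function(labels, image_labels = NULL,
                            is_defective = rep(FALSE, 4)) {
  gt_fixture(
    masks = list(img = lapply(1:4, blank_mask)),
    labels = list(img = labels),
    is_defective = list(img = is_defective),
    image_labels = if (is.null(image_labels)) NULL else list(img = image_labels)
  )
}

test_that("the negative-fraction filter applies a strict > 50% rule", {
  # 3 of 4 cells Negative: 75% > 50%, removed
  gt <- four_cell_image(list(18L, 18L, 18L, 0L), image_labels = 0L)
  res <- filter_images(gt$images, gt$cells)
  expect_equal(res$removed$reason, "negative_fraction")
  # 2 of 4 Negative: exactly 50%, not above, kept
  gt2 <- four_cell_image(list(18L, 18L, 0L, 1L), image_labels = c(0L, 1L))
  res2 <- filter_images(gt2$images, gt2$cells)
  expect_equal(nrow(res2$removed), 0L)
  expect_equal(res2$kept$image_id, "img")
})

test_that("defective-majority images and weak-label copies are removed", {
  gt <- four_cell_image(list(0L, 0L, 1L, 1L), image_labels = c(0L, 1L),
                        is_defective = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(filter_images(gt$images, gt$cells)$removed$reason,
               "defective_fraction")
  # every cell's label set equals the image-level set
  gt2 <- four_cell_image(rep(list(c(0L, 5L)), 4), image_labels = c(0L, 5L))
  expect_equal(filter_images(gt2$images, gt2$cells)$removed$reason,
               "matches_image_labels")
  # a single deviating cell keeps the image
  gt3 <- four_cell_image(c(rep(list(c(0L, 5L)), 3), list(0L)),
                         image_labels = c(0L, 5L))
  expect_equal(nrow(filter_images(gt3$images, gt3$cells)$removed), 0L)
})

test_that("filtering kept images again is a no-op", {
  sim <- generate_dataset(sim_config(n_images = 20, image_size = 64,
                                     cells_per_image = 4,
                                     negative_rate = 0.4, seed = 5))
  first <- filter_images(sim$images, sim$cells)
  again <- filter_images(first$kept, sim$cells)
  expect_equal(nrow(again$removed), 0L)
  expect_equal(again$kept$image_id, first$kept$image_id)
  # reasons partition the removed set
  expect_equal(sort(c(first$kept$image_id, first$removed$image_id)),
               sort(sim$images$image_id))
})

test_that("heterogeneity compares label sets of non-border cells", {
  same <- gt_fixture(masks = list(img = lapply(1:3, blank_mask)),
                     labels = list(img = rep(list(16L), 3)))
  expect_false(is_heterogeneous(same$cells))
  mixed <- gt_fixture(masks = list(img = lapply(1:3, blank_mask)),
                      labels = list(img = list(16L, c(16L, 2L), 16L)))
  expect_true(is_heterogeneous(mixed$cells))
  # the deviating cell sits on the border: excluded, image homogeneous
  border <- gt_fixture(masks = list(img = lapply(1:3, blank_mask)),
                       labels = list(img = list(16L, 16L, c(16L, 2L))),
                       is_border = list(img = c(FALSE, FALSE, TRUE)))
  expect_false(is_heterogeneous(border$cells))
  expect_true(is_heterogeneous(border$cells, exclude_border = FALSE))
  only_border <- gt_fixture(masks = list(img = list(blank_mask(1))),
                            labels = list(img = list(16L)),
                            is_border = list(img = TRUE))
  expect_true(is.na(is_heterogeneous(only_border$cells)))
})

test_that("the census counts heterogeneous images per cell line", {
  sim <- generate_dataset(sim_config(n_images = 30, image_size = 64,
                                     cells_per_image = 5,
                                     heterogeneity_rate = 0.5,
                                     negative_rate = 0, seed = 8))
  cen <- heterogeneity_census(sim$images, sim$cells)
  expect_equal(sum(cen$n_images), 30L)
  # census totals agree with direct per-image evaluation
  het <- vapply(sim$images$image_id, function(id) {
    isTRUE(is_heterogeneous(sim$cells[sim$cells$image_id == id, ]))
  }, TRUE)
  expect_equal(sum(cen$n_heterogeneous), sum(het))
  # all-homogeneous dataset gives zero counts
  sim0 <- generate_dataset(sim_config(n_images = 10, image_size = 64,
                                      cells_per_image = 4,
                                      heterogeneity_rate = 0, seed = 9))
  expect_equal(sum(heterogeneity_census(sim0$images, sim0$cells)$n_heterogeneous),
               0L)
})

test_that("annotator agreement is the fraction of identically labeled cells", {
  expect_equal(annotator_agreement(list(
    a = list(c(0L, 2L), c(2L, 0L)),  # order-invariant
    b = list(1L, 1L, 1L)
  )), 1)
  expect_equal(annotator_agreement(list(
    a = list(0L, 0L),
    b = list(1L, 2L)
  )), 0.5)
  expect_error(annotator_agreement(list()), "empty")
  expect_error(annotator_agreement(list(a = list(1L))), "two annotations")
})

test_that("chance agreement reproduces the printed probabilities", {
  # one label from 30: (1/30)^2, prints as 0.1% at one significant figure
  expect_equal(signif(100 * chance_agreement(30, 1), 1), 0.1)
  # two labels from 30: (1/30)^4, prints as 0.0001%
  expect_equal(signif(100 * chance_agreement(30, 2), 1), 0.0001)
  expect_equal(chance_agreement(1, 1), 1)
  # monotone decreasing in both arguments
  expect_true(all(diff(vapply(2:10, chance_agreement, 0, k_labels_each = 1)) < 0))
  expect_true(all(diff(vapply(1:5, function(k) chance_agreement(30, k), 0)) < 0))
  expect_error(chance_agreement(0, 1), ">= 1")
})

test_that("the stratified split preserves size, determinism and balance", {
  sim <- generate_dataset(sim_config(n_images = 100, image_size = 64,
                                     cells_per_image = 5, seed = 15))
  sp <- suppressWarnings(stratified_split(sim$cells, 0.31, seed = 2))
  expect_equal(abs(length(sp$public_ids) - 31L) <= 2L, TRUE)
  expect_equal(sort(c(sp$public_ids, sp$private_ids)),
               sort(sim$images$image_id))
  expect_length(intersect(sp$public_ids, sp$private_ids), 0L)
  sp2 <- suppressWarnings(stratified_split(sim$cells, 0.31, seed = 2))
  expect_identical(sp$public_ids, sp2$public_ids)
  # a homogeneous class distribution splits with negligible gap
  uni <- gt_fixture(
    masks = stats::setNames(lapply(1:10, function(i) list(blank_mask(1))),
                            sprintf("im%02d", 1:10)),
    labels = stats::setNames(rep(list(list(0L)), 10), sprintf("im%02d", 1:10))
  )
  spu <- stratified_split(uni$cells, 0.5, seed = 3)
  expect_equal(spu$max_gap, 0)
})

test_that("split proportions converge with dataset size", {
  sim <- generate_dataset(sim_config(n_images = 300, image_size = 64,
                                     cells_per_image = 4, seed = 16))
  sp <- suppressWarnings(stratified_split(sim$cells, 0.31, seed = 4,
                                          n_iter = 500))
  expect_lt(sp$max_gap, 0.05)
  expect_lt(abs(length(sp$public_ids) / 300 - 0.31), 0.02)
})
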