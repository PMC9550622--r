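#' Pearson correlation with two-tailed significance
#'
#' Product-moment correlation between two numeric vectors with the p-value
#' from the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom, as used to relate segmentation quality (mean
#' matched IOU) to classification performance (mAP) across submissions.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, finite, with
#'   nonzero variance.
#' @return List with `r`, `p` (two-tailed), `n` and `df`. When either input
#'   has zero variance, `r` and `p` are `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 pairs", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, df = n - 2L))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, df = n - 2L)
}

#' Critical value of the Pearson correlation coefficient
#'
#' The smallest |r| significant at level `alpha` with `df = n - 2` degrees
#' of freedom: `r* = t* / sqrt(t*^2 + df)` where `t*` is the Student-t
#' quantile at the corresponding tail probability. Exact inverse of the
#' p-value computation in [pearson_r()].
#'
#' @param df Degrees of freedom (`n - 2`), >= 1.
#' @param alpha Significance level in (0, 1).
#' @param two_tailed Two-tailed test (default `TRUE`).
#' @return The critical correlation in (0, 1).
#' @examples
#' pearson_critical_value(48, 0.02)  # ~0.33
#' @export
pearson_critical_value <- function(df, alpha = 0.05, two_tailed = TRUE) {
  if (df < 1L) {
    stop("df must be >= 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  tail <- if (two_tailed) alpha / 2 else alpha
  tstar <- stats::qt(1 - tail, df)
  tstar / sqrt(tstar^2 + df)
}

#' Render an evaluation report or cohort table as JSON
#'
#' Stable key ordering; `NA` per-class APs (classes absent from the ground
#' truth) render as `null`. [parse_report()] restores the numeric content.
#'
#' @param report An `eval_report` or a cohort tibble from [score_cohort()].
#' @return A JSON string.
#' @export
render_report <- function(report) {
  if (inherits(report, "eval_report")) {
    x <- list(
      map = report$map,
      mean_matched_iou = report$mean_matched_iou,
      n_matched = report$n_matched,
      threshold = report$threshold,
      per_class_ap = as.list(report$per_class_ap),
      tallies = as.data.frame(report$tallies)
    )
  } else {
    x <- lapply(seq_len(nrow(report)), function(i) as.list(report[i, ]))
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = TRUE)
}

#' @rdname render_report
#' @param json A JSON string from [render_report()].
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (!is.null(x$per_class_ap)) {
    x$per_class_ap <- vapply(x$per_class_ap,
                             function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                             0)
    x$tallies <- tibble::as_tibble(x$tallies)
  }
  x
}

#' Score a cohort of submissions against one ground truth
#'
#' Evaluates each prediction table with [evaluate_submission()] and collects
#' one row per submission: mAP, mean matched IOU and the per-class APs. The
#' mAP column is always the mean of the defined per-class entries.
#'
#' @param gt Ground-truth dataset list.
#' @param predictions Named list of prediction tibbles (one per
#'   submission/team).
#' @param threshold IOU matching threshold.
#' @param scheme A `class_scheme`.
#' @return Tibble with `submission`, `map`, `mean_matched_iou` and one
#'   `ap_<class id>` column per grouped class.
#' @export
score_cohort <- function(gt, predictions, threshold = 0.6,
                         scheme = default_class_scheme()) {
  if (is.null(names(predictions))) {
    names(predictions) <- sprintf("submission_%02d", seq_along(predictions))
  }
  rows <- lapply(names(predictions), function(nm) {
    rep <- evaluate_submission(gt, predictions[[nm]], threshold = threshold,
                               scheme = scheme)
    ap <- as.list(rep$per_class_ap)
    names(ap) <- sprintf("ap_%d", seq_along(ap) - 1L)
    dplyr::bind_cols(
      tibble::tibble(submission = nm, map = rep$map,
                     mean_matched_iou = rep$mean_matched_iou),
      tibble::as_tibble(ap)
    )
  })
  dplyr::bind_rows(rows)
}

#' Long-format per-class AP table for distribution plots
#'
#' One row per (submission, class) with the AP score, the shape violin or
#' box plots of per-class score distributions consume.
#'
#' @param cohort A cohort tibble from [score_cohort()].
#' @param scheme A `class_scheme`.
#' @return Tibble `submission`, `class_id`, `class`, `ap`.
#' @export
cohort_class_table <- function(cohort, scheme = default_class_scheme()) {
  k <- n_classes(scheme)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    tibble::tibble(
      submission = cohort$submission[i],
      class_id = seq_len(k) - 1L,
      class = scheme$grouped_classes,
      ap = as.numeric(cohort[i, sprintf("ap_%d", seq_len(k) - 1L)])
    )
  })
  dplyr::bind_rows(rows)
}
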