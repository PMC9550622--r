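#' Run-length encoding for binary instance masks
#'
#' Binary cell masks are serialized as alternating background/foreground run
#' lengths in a fixed column-major scan order: pixels are visited
#' top-to-bottom within a column, columns left-to-right (the native layout of
#' an R matrix). The first run is always background and may have length zero,
#' so every mask has exactly one canonical encoding.
#'
#' @param mask Integer or logical matrix with values 0/1 (`FALSE`/`TRUE`);
#'   rows are image rows, columns are image columns.
#' @return An object of class `rle_mask`: a list with `counts` (integer run
#'   lengths), `width`, `height` and `order` (`"col"`).
#' @examples
#' m <- matrix(0L, 3, 3); m[2, 2] <- 1L
#' r <- encode_rle(m)
#' r$counts
#' identical(decode_rle(r), m)
#' @seealso [decode_rle()], [rle_to_string()]
#' @export
encode_rle <- function(mask) {
  if (!is.matrix(mask)) {
    stop("`mask` must be a matrix", call. = FALSE)
  }
  v <- as.integer(mask)
  if (anyNA(v) || !all(v == 0L | v == 1L)) {
    stop("mask values must be binary (0/1)", call. = FALSE)
  }
  if (length(v) == 0L) {
    stop("mask must have at least one pixel", call. = FALSE)
  }
  runs <- rle(v)
  counts <- runs$lengths
  if (runs$values[1L] == 1L) {
    counts <- c(0L, counts)
  }
  new_rle_mask(counts, ncol(mask), nrow(mask))
}

#' Decode a run-length encoded mask back to a binary matrix
#'
#' Exact inverse of [encode_rle()].
#'
#' @param rle An `rle_mask` object.
#' @return Integer matrix of 0/1 with `rle$height` rows and `rle$width`
#'   columns.
#' @export
decode_rle <- function(rle) {
  stopifnot(inherits(rle, "rle_mask"))
  counts <- rle$counts
  if (sum(counts) != rle$width * rle$height) {
    stop("corrupt RLE: run lengths sum to ", sum(counts),
         " but mask has ", rle$width * rle$height, " pixels", call. = FALSE)
  }
  vals <- rep_len(c(0L, 1L), length(counts))
  v <- rep.int(vals, counts)
  matrix(v, nrow = rle$height, ncol = rle$width)
}

new_rle_mask <- function(counts, width, height, order = "col") {
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0L)) {
    stop("RLE counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(counts = counts, width = as.integer(width),
         height = as.integer(height), order = order),
    class = "rle_mask"
  )
}

#' @export
print.rle_mask <- function(x, ...) {
  cat(sprintf("<rle_mask %dx%d (%s-major), %d runs, %d fg px>\n",
              x$height, x$width, x$order, length(x$counts),
              sum(x$counts[seq_along(x$counts) %% 2L == 0L])))
  invisible(x)
}

#' Serialize run lengths as a whitespace-separated string
#'
#' The string form is what the tabular readers and writers use in the `rle`
#' column of ground-truth and prediction CSV files.
#'
#' @param rle An `rle_mask`.
#' @return A single string of space-separated run lengths.
#' @export
rle_to_string <- function(rle) {
  stopifnot(inherits(rle, "rle_mask"))
  paste(rle$counts, collapse = " ")
}

#' Parse a run-length string into an `rle_mask`
#'
#' @param s String of space-separated run lengths.
#' @param width,height Mask dimensions in pixels.
#' @return An `rle_mask`; errors if the runs do not cover `width * height`
#'   pixels.
#' @export
rle_from_string <- function(s, width, height) {
  counts <- suppressWarnings(as.integer(strsplit(trimws(s), "\\s+")[[1L]]))
  if (anyNA(counts)) {
    stop("corrupt RLE string: ", s, call. = FALSE)
  }
  r <- new_rle_mask(counts, width, height)
  if (sum(r$counts) != r$width * r$height) {
    stop("corrupt RLE: run lengths do not cover the mask", call. = FALSE)
  }
  r
}

# Foreground pixel indices (1-based, column-major) straight from the runs,
# without materializing the full raster. The hot path of IOU computation.
rle_foreground_indices <- function(rle) {
  counts <- rle$counts
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  fg <- seq_along(counts) %% 2L == 0L
  fg <- fg & counts > 0L
  if (!any(fg)) {
    return(integer(0))
  }
  sequence(counts[fg], from = starts[fg])
}

indices_to_mask <- function(idx, width, height) {
  m <- matrix(0L, nrow = height, ncol = width)
  m[idx] <- 1L
  m
}
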