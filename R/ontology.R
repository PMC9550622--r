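#' The subcellular localization class scheme
#'
#' Annotation happens on 31 fine labels (30 organelle patterns plus
#' Negative/Unspecific); scoring happens on 19 grouped classes obtained by
#' merging patterns that are functionally and spatially similar: Actin
#' filaments absorbs Focal adhesion sites, Centrosome absorbs Centriolar
#' satellite, Plasma membrane absorbs Cell Junctions, and the Vesicles and
#' punctate cytosolic pattern class absorbs Vesicles, Peroxisomes, Endosomes,
#' Lysosomes, Lipid droplets and Cytoplasmic bodies. Four fine labels
#' (Microtubule ends, Rods and Rings, Cleavage furrow, Mitotic chromosome)
#' have no grouped destination and are discarded during grouping. Grouped
#' class ids are 0-based with Negative last (id 18).
#'
#' The scheme ships as a versioned YAML resource; alternate schemes in the
#' same format can be loaded with [load_class_scheme()].
#'
#' @return A `class_scheme` object: grouped class names (length 19), fine
#'   label names (length 31) and the fine-to-group mapping (`NA` for
#'   discarded labels).
#' @examples
#' sch <- default_class_scheme()
#' class_name(18, sch)
#' group_label_set(c("Peroxisomes", "Endosomes"), sch)
#' @export
default_class_scheme <- function() {
  if (is.null(.scmeval_env$scheme)) {
    path <- system.file("extdata", "class_scheme.yaml", package = "scmeval",
                        mustWork = TRUE)
    .scmeval_env$scheme <- load_class_scheme(path)
  }
  .scmeval_env$scheme
}

.scmeval_env <- new.env(parent = emptyenv())

#' Load a class scheme from a YAML file
#'
#' @param path Path to a YAML file with fields `version`, `grouped_classes`
#'   (ordered names) and `fine_labels` (list of `{name, group}` entries where
#'   `group` is a grouped class name or `DISCARDED`).
#' @return A `class_scheme` object.
#' @export
load_class_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  grouped <- as.character(raw$grouped_classes)
  fine <- vapply(raw$fine_labels, function(x) as.character(x$name), "")
  target <- vapply(raw$fine_labels, function(x) as.character(x$group), "")
  if (anyDuplicated(grouped) || anyDuplicated(fine)) {
    stop("class scheme contains duplicate names", call. = FALSE)
  }
  unknown <- setdiff(setdiff(target, "DISCARDED"), grouped)
  if (length(unknown)) {
    stop("fine labels map to unknown grouped classes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  map <- match(target, grouped) - 1L  # NA for DISCARDED
  names(map) <- fine
  structure(
    list(version = raw$version %||% 1L,
         grouped_classes = grouped,
         fine_labels = fine,
         fine_to_group = map),
    class = "class_scheme"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat(sprintf("<class_scheme v%s: %d fine labels -> %d grouped classes (%d discarded)>\n",
              x$version, length(x$fine_labels), length(x$grouped_classes),
              sum(is.na(x$fine_to_group))))
  invisible(x)
}

#' Number of grouped classes and the Negative class id
#'
#' @param scheme A `class_scheme`.
#' @return `n_classes()`: the number of grouped classes (19 by default);
#'   `negative_class()`: the grouped id of the Negative class.
#' @export
n_classes <- function(scheme = default_class_scheme()) {
  length(scheme$grouped_classes)
}

#' @rdname n_classes
#' @export
negative_class <- function(scheme = default_class_scheme()) {
  id <- match("Negative", scheme$grouped_classes) - 1L
  if (is.na(id)) {
    stop("scheme has no Negative class", call. = FALSE)
  }
  id
}

#' Map between grouped class names and 0-based ids
#'
#' `class_index()` and `class_name()` are mutual inverses over the grouped
#' classes of a scheme.
#'
#' @param name Grouped class name.
#' @param id 0-based grouped class id.
#' @param scheme A `class_scheme`.
#' @export
class_index <- function(name, scheme = default_class_scheme()) {
  idx <- match(name, scheme$grouped_classes)
  if (anyNA(idx)) {
    stop("unknown grouped class: ",
         paste(name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

#' @rdname class_index
#' @export
class_name <- function(id, scheme = default_class_scheme()) {
  id <- as.integer(id)
  if (anyNA(id) || any(id < 0L | id >= length(scheme$grouped_classes))) {
    stop("grouped class id out of range 0..",
         length(scheme$grouped_classes) - 1L, call. = FALSE)
  }
  scheme$grouped_classes[id + 1L]
}

#' Group a set of fine annotation labels into grouped class ids
#'
#' Each fine label is replaced by its grouped class; discarded labels are
#' dropped. A set left empty after discarding becomes `{Negative}`, the same
#' fallback used when label refinement empties a cell's set. Names that are
#' grouped-class names but not fine labels (the merged classes' own names)
#' map to themselves, so grouping an already-grouped set is a no-op.
#'
#' @param fine Character vector of fine label names (duplicates allowed,
#'   treated as a set).
#' @param scheme A `class_scheme`.
#' @return Sorted integer vector of grouped class ids.
#' @export
group_label_set <- function(fine, scheme = default_class_scheme()) {
  if (length(fine) == 0L) {
    return(negative_class(scheme))
  }
  ids <- scheme$fine_to_group[match(fine, names(scheme$fine_to_group))]
  miss <- is.na(match(fine, names(scheme$fine_to_group)))
  if (any(miss)) {
    grp <- match(fine[miss], scheme$grouped_classes) - 1L
    if (anyNA(grp)) {
      stop("unknown fine label: ",
           paste(fine[miss][is.na(grp)], collapse = ", "), call. = FALSE)
    }
    ids[miss] <- grp
  }
  out <- sort(unique(ids[!is.na(ids)]))
  if (length(out) == 0L) {
    out <- negative_class(scheme)
  }
  as.integer(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
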