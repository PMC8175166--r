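#' Labeled set of same-shape trial tensors
#'
#' The universal input container: `n` dense arrays of identical shape
#' `(m_1, ..., m_h)` (order `h >= 2`; for raw EEG, channels x time; after CWT
#' tensorization, channels x time x scales) with one integer class label per
#' trial. Class ids are the sorted unique labels.
#'
#' @param trials List of dense numeric/complex arrays, all with identical
#'   `dim()`. Plain matrices are accepted (order 2).
#' @param labels Integer-like vector, one label per trial. Every class must be
#'   non-empty by construction.
#' @param groups Optional grouping vector (same length as `labels`) marking
#'   trials that must stay in the same cross-validation fold, e.g. all sliding
#'   windows cut from one recording epoch.
#' @return An object of class `trial_set`: list with elements `trials`,
#'   `labels` (integer), `groups` (or `NULL`), `dims`, `n`, `classes`.
#' @examples
#' ts <- trial_set(list(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), c(1, 2))
#' ts$n
#' @export
trial_set <- function(trials, labels, groups = NULL) {
  if (!is.list(trials) || length(trials) == 0) {
    stop("`trials` must be a non-empty list of arrays", call. = FALSE)
  }
  trials <- lapply(trials, function(x) {
    if (is.null(dim(x))) stop("every trial must be a matrix or array", call. = FALSE)
    x
  })
  dims <- dim(trials[[1]])
  ok <- vapply(trials, function(x) identical(dim(x), dims), logical(1))
  if (!all(ok)) {
    stop(sprintf("all trials must share shape (%s); trial %d differs",
                 paste(dims, collapse = ", "), which(!ok)[1]), call. = FALSE)
  }
  finite <- vapply(trials, function(x) all(is.finite(Mod(x))), logical(1))
  if (!all(finite)) {
    stop(sprintf("trial %d contains non-finite values", which(!finite)[1]),
         call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != length(trials) || anyNA(labels)) {
    stop("`labels` must be one integer per trial", call. = FALSE)
  }
  if (!is.null(groups)) {
    if (length(groups) != length(trials)) {
      stop("`groups` must have one entry per trial", call. = FALSE)
    }
    groups <- as.character(groups)
  }
  structure(
    list(
      trials = trials, labels = labels, groups = groups,
      dims = as.integer(dims), n = length(trials),
      classes = sort(unique(labels))
    ),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d trials of shape (%s), %d classes (%s)\n",
    x$n, paste(x$dims, collapse = " x "), length(x$classes),
    paste(sprintf("%d: n=%d", x$classes, tabulate_classes(x)), collapse = ", ")
  ))
  invisible(x)
}

tabulate_classes <- function(data) {
  vapply(data$classes, function(j) sum(data$labels == j), integer(1))
}

#' Subset a trial set by trial index
#'
#' @param data A [trial_set()].
#' @param idx Integer indices of the trials to keep.
#' @return A `trial_set` with the selected trials (groups carried along).
#' @export
trial_subset <- function(data, idx) {
  stopifnot(inherits(data, "trial_set"))
  trial_set(data$trials[idx], data$labels[idx],
            groups = if (is.null(data$groups)) NULL else data$groups[idx])
}

#' Class mean tensors and the grand mean
#'
#' Arithmetic mean of the trials of each class and of all trials:
#' `M_j = (1/n_j) sum_{i: y_i = j} X_i`, `M = (1/n) sum_i X_i`.
#'
#' @param data A [trial_set()].
#' @return List with `class_means` (named by class id), `grand_mean`, and
#'   per-class `counts`.
#' @export
class_means <- function(data) {
  stopifnot(inherits(data, "trial_set"))
  counts <- tabulate_classes(data)
  if (any(counts == 0)) {
    stop(sprintf("class %d has no trials", data$classes[which(counts == 0)[1]]),
         call. = FALSE)
  }
  acc <- function(idx) Reduce(`+`, data$trials[idx]) / length(idx)
  cm <- lapply(data$classes, function(j) acc(which(data$labels == j)))
  names(cm) <- as.character(data$classes)
  grand <- Reduce(`+`, mapply(function(m, n) m * n, cm, counts,
                              SIMPLIFY = FALSE)) / data$n
  list(class_means = cm, grand_mean = grand,
       counts = stats::setNames(counts, as.character(data$classes)))
}
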