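#' Projected class-mean prototypes
#'
#' Maps every class mean tensor through the learned projections:
#' `P_j = M_j x_1 U_1 ... x_h U_h`. These are the reference points of the
#' nearest-class-mean rule.
#'
#' @param model A fitted [fit_mdsp()] model.
#' @return An object of class `mdsp_prototypes`: list with `prototypes`
#'   (one array per class) and `class_ids`.
#' @export
fit_prototypes <- function(model) {
  stopifnot(inherits(model, "mdsp_model"))
  protos <- lapply(model$class_means,
                   function(Mj) multi_mode_product(Mj, model$projections))
  structure(list(prototypes = protos, class_ids = model$classes),
            class = "mdsp_prototypes")
}

#' Nearest projected class-mean prediction
#'
#' A trial `X` is projected to `F = X x_1 U_1 ... x_h U_h` and assigned to
#' `argmin_j ||F - M_j x_1 U_1 ... x_h U_h||_F` (modulus-based Frobenius norm
#' for complex features). No grand-mean centering is applied at test time.
#' Distance ties are broken deterministically by the lowest class id.
#'
#' @param object A fitted [fit_mdsp()] model.
#' @param newdata A [trial_set()], a list of trial arrays, or a single trial
#'   array conforming to the model's input shape.
#' @param prototypes Optional precomputed [fit_prototypes()] result.
#' @param ... Unused.
#' @return Integer vector of predicted class ids, one per trial.
#' @export
predict.mdsp_model <- function(object, newdata, prototypes = NULL, ...) {
  if (is.null(prototypes)) prototypes <- fit_prototypes(object)
  trials <- if (inherits(newdata, "trial_set")) {
    newdata$trials
  } else if (is.list(newdata)) {
    newdata
  } else {
    list(newdata)
  }
  vapply(trials, function(X) {
    F_ <- project_trial(object, X)
    d <- vapply(prototypes$prototypes, function(P) fnorm(F_ - P), numeric(1))
    prototypes$class_ids[which.min(d)]
  }, integer(1))
}

#' Classification metrics from predicted and true labels
#'
#' Confusion-matrix-derived accuracy, precision, recall and F1. Per-class
#' values are one-vs-rest; the summary row reports, for binary problems, the
#' positive class taken as the higher class id (class 2 under 1/2 labels),
#' and macro averages otherwise.
#'
#' @param truth Integer vector of true class ids.
#' @param predicted Integer vector of predictions, same length.
#' @return A list of class `mdsp_score`: `metrics` (one-row tibble: `n`,
#'   `accuracy`, `precision`, `recall`, `f1`, `averaging`), `per_class`
#'   tibble, and the `confusion` table (rows = truth, cols = predicted).
#' @export
score_predictions <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  classes <- sort(unique(c(truth, predicted)))
  conf <- table(factor(truth, levels = classes),
                factor(predicted, levels = classes), dnn = c("truth", "predicted"))
  per_class <- purrr::map_dfr(seq_along(classes), function(j) {
    tp <- conf[j, j]
    fp <- sum(conf[-j, j])
    fn <- sum(conf[j, -j])
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
      2 * prec * rec / (prec + rec)
    tibble::tibble(class = classes[j], n = sum(conf[j, ]),
                   precision = prec, recall = rec, f1 = f1)
  })
  acc <- sum(diag(conf)) / length(truth)
  if (length(classes) == 2) {
    pos <- which.max(classes)  # positive class = higher class id
    summary_row <- tibble::tibble(
      n = length(truth), accuracy = acc,
      precision = per_class$precision[pos], recall = per_class$recall[pos],
      f1 = per_class$f1[pos],
      averaging = sprintf("positive class %d", classes[pos])
    )
  } else {
    summary_row <- tibble::tibble(
      n = length(truth), accuracy = acc,
      precision = mean(per_class$precision, na.rm = TRUE),
      recall = mean(per_class$recall, na.rm = TRUE),
      f1 = mean(per_class$f1, na.rm = TRUE),
      averaging = "macro"
    )
  }
  structure(list(metrics = summary_row, per_class = per_class, confusion = conf),
            class = "mdsp_score")
}

#' @export
print.mdsp_score <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}
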