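#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the iteration trace of an MDSP fit
#'
#' @param x A fitted [fit_mdsp()] model.
#' @param ... Unused.
#' @return The per-sweep trace tibble: `sweep`, per-mode `err_mode<k>`,
#'   total `err`, `objective`, `seconds`.
#' @export
tidy.mdsp_model <- function(x, ...) x$trace

#' One-row summary of an MDSP fit
#'
#' @param x A fitted [fit_mdsp()] model.
#' @param ... Unused.
#' @return Tibble with convergence flag, sweeps run, final total error,
#'   final Fisher objective, and the filter-count configuration.
#' @export
glance.mdsp_model <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, iterations = x$iterations,
    final_err = utils::tail(x$trace$err, 1),
    objective = utils::tail(x$trace$objective, 1),
    dims = paste(x$dims_out, collapse = "x"),
    n_classes = length(x$classes)
  )
}

#' Tidy the spectrum of a DSP fit
#'
#' @param x A fitted [fit_dsp()] model.
#' @param ... Unused.
#' @return Tibble with `filter` index and generalized `eigenvalue`
#'   (descending Fisher ratios).
#' @export
tidy.dsp_model <- function(x, ...) {
  tibble::tibble(filter = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues)
}

#' One-row summary of a DSP fit
#'
#' @param x A fitted [fit_dsp()] model.
#' @param ... Unused.
#' @return Tibble with filter count, channels, the ratio-trace objective
#'   (sum of kept eigenvalues) and the leading eigenvalue.
#' @export
glance.dsp_model <- function(x, ...) {
  tibble::tibble(
    d = x$d, channels = nrow(x$U),
    objective = sum(x$eigenvalues), leading_eigenvalue = x$eigenvalues[1]
  )
}

#' Summarize a cross-validation table
#'
#' @param x An [cross_validate()] result.
#' @param ... Unused.
#' @return One-row tibble: mean/sd accuracy and F1, fraction of convergent
#'   fits, and the configuration.
#' @export
glance.mdsp_cv <- function(x, ...) {
  tibble::tibble(
    mean_accuracy = mean(x$accuracy), sd_accuracy = stats::sd(x$accuracy),
    mean_f1 = mean(x$f1, na.rm = TRUE),
    prop_converged = mean(x$converged),
    folds = attr(x, "folds"), repeats = attr(x, "repeats"),
    dims = paste(attr(x, "dims"), collapse = "x")
  )
}

#' Convergence-trace plot of an MDSP fit
#'
#' Total relative change `err(t)` per sweep on a log scale, with the
#' convergence threshold as a dashed line.
#'
#' @param object A fitted [fit_mdsp()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdsp_model <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$sweep, y = .data$err)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$epsilon, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sweep", y = "total relative change err(t)",
                  title = sprintf("MDSP convergence (%s after %d sweeps)",
                                  if (object$converged) "converged" else "not converged",
                                  object$iterations)) +
    ggplot2::theme_minimal()
}

#' Fold-accuracy plot of a cross-validation run
#'
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot object: per-fold accuracies by repeat with the overall
#'   mean as a horizontal line.
#' @export
autoplot.mdsp_cv <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$repeat_), y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = mean(df$accuracy), linetype = "dashed") +
    ggplot2::labs(x = "repeat", y = "fold accuracy",
                  title = sprintf("%d x %d-fold cross-validation, dims %s",
                                  attr(object, "repeats"), attr(object, "folds"),
                                  paste(attr(object, "dims"), collapse = "x"))) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
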