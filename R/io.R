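# Plain-text interchange: a directory with one dense array per trial
# (trial_0001.txt: "# dims: ..." header + one value per line, column-major,
# full precision) and a labels.tsv table (trial, label[, group]).

write_array_txt <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims: %s", paste(dim(x), collapse = " ")), con)
  writeLines(format(as.vector(x), digits = 17, trim = TRUE, scientific = TRUE),
             con)
}

read_array_txt <- function(path) {
  header <- readLines(path, n = 1)
  dims <- as.integer(strsplit(sub("^# dims: *", "", header), " ")[[1]])
  vals <- utils::read.table(path, skip = 1)[[1]]
  array(as.numeric(vals), dim = dims)
}

#' Write a trial set as a plain-text archive
#'
#' @param data A [trial_set()] (real-valued trials).
#' @param dir Directory to create/fill.
#' @return `dir`, invisibly.
#' @export
write_trial_archive <- function(data, dir) {
  stopifnot(inherits(data, "trial_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(data$n)) {
    write_array_txt(data$trials[[i]], file.path(dir, sprintf("trial_%04d.txt", i)))
  }
  lab <- data.frame(trial = sprintf("trial_%04d", seq_len(data$n)),
                    label = data$labels)
  if (!is.null(data$groups)) lab$group <- data$groups
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a plain-text trial archive
#'
#' @param dir Directory written by [write_trial_archive()] (or following the
#'   same layout: `trial_*.txt` arrays + `labels.tsv`).
#' @return A [trial_set()].
#' @export
read_trial_archive <- function(dir) {
  lab <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  trials <- lapply(lab$trial, function(id) {
    read_array_txt(file.path(dir, paste0(id, ".txt")))
  })
  trial_set(trials, lab$label,
            groups = if ("group" %in% names(lab)) lab$group else NULL)
}

#' Serialize a fitted MDSP model to a plain-text directory
#'
#' Writes each projection matrix, class-mean tensor and the grand mean as
#' dense text arrays, the iteration trace as CSV, and the configuration and
#' convergence flag as JSON metadata.
#'
#' @param model A fitted [fit_mdsp()] model (real-valued).
#' @param dir Directory to create/fill.
#' @return `dir`, invisibly.
#' @export
write_mdsp_model <- function(model, dir) {
  stopifnot(inherits(model, "mdsp_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(model$projections)) {
    write_array_txt(model$projections[[k]], file.path(dir, sprintf("U_%d.txt", k)))
  }
  for (j in seq_along(model$class_means)) {
    write_array_txt(model$class_means[[j]],
                    file.path(dir, sprintf("class_mean_%s.txt",
                                           names(model$class_means)[j])))
  }
  write_array_txt(model$grand_mean, file.path(dir, "grand_mean.txt"))
  utils::write.csv(model$trace, file.path(dir, "trace.csv"), row.names = FALSE)
  meta <- list(
    order = length(model$dims_in), dims_in = model$dims_in,
    dims_out = model$dims_out, classes = model$classes,
    counts = as.integer(model$counts), epsilon = model$epsilon,
    t_max = model$t_max, reg = model$reg, init = model$init,
    converged = model$converged, iterations = model$iterations
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a serialized MDSP model
#'
#' @param dir Directory written by [write_mdsp_model()].
#' @return An `mdsp_model`.
#' @export
read_mdsp_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  h <- meta$order
  U <- lapply(seq_len(h), function(k) {
    read_array_txt(file.path(dir, sprintf("U_%d.txt", k)))
  })
  cm <- lapply(meta$classes, function(j) {
    read_array_txt(file.path(dir, sprintf("class_mean_%d.txt", j)))
  })
  names(cm) <- as.character(meta$classes)
  structure(
    list(
      projections = U, class_means = cm,
      grand_mean = read_array_txt(file.path(dir, "grand_mean.txt")),
      counts = stats::setNames(meta$counts, as.character(meta$classes)),
      classes = as.integer(meta$classes),
      dims_in = as.integer(meta$dims_in), dims_out = as.integer(meta$dims_out),
      epsilon = meta$epsilon, t_max = meta$t_max, reg = meta$reg,
      init = meta$init, converged = meta$converged,
      iterations = meta$iterations,
      trace = tibble::as_tibble(utils::read.csv(file.path(dir, "trace.csv")))
    ),
    class = "mdsp_model"
  )
}

#' Write predictions and metrics as delimited text / JSON
#'
#' @param truth,predicted Label vectors, equal length.
#' @param dir Output directory; writes `predictions.tsv` (trial, truth,
#'   predicted) and `metrics.json`.
#' @return The [score_predictions()] result, invisibly.
#' @export
write_evaluation <- function(truth, predicted, dir) {
  sc <- score_predictions(truth, predicted)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(trial = seq_along(truth), truth = truth, predicted = predicted),
    file.path(dir, "predictions.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  jsonlite::write_json(
    list(metrics = as.list(sc$metrics), per_class = sc$per_class),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(sc)
}
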