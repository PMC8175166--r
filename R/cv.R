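#' Repeated stratified (optionally grouped) cross-validation of MDSP
#'
#' Repeated k-fold cross-validation of the full MDSP pipeline on tensor (or
#' 2-D) trials: within each fold the projections, class means and scatters
#' are estimated on the training split only, and the held-out trials are
#' classified by the nearest projected class mean. Folds are stratified by
#' class; when the trial set carries `groups` (e.g. sliding windows cut from
#' one epoch) whole groups are assigned to folds so temporally correlated
#' windows never straddle the train/test boundary (disable with
#' `grouped = FALSE`). The defaults, 5 folds and 5 repeats, give the usual
#' 5 x 5-fold protocol.
#'
#' @param data A [trial_set()].
#' @param dims Per-mode filter counts passed to [fit_mdsp()].
#' @param folds Number of folds, >= 2.
#' @param repeats Number of repetitions with reshuffled fold assignments.
#' @param seed Seed controlling all fold assignments.
#' @param grouped Honor `data$groups` when present (default `TRUE`).
#' @param epsilon,t_max,reg Passed to [fit_mdsp()].
#' @return A tibble of class `mdsp_cv`, one row per (repeat, fold):
#'   `repeat_`, `fold`, `n_test`, `accuracy`, `precision`, `recall`, `f1`,
#'   `converged`, `iterations`. Attribute `dims` records the configuration.
#' @export
cross_validate <- function(data, dims, folds = 5, repeats = 5, seed = 1,
                           grouped = TRUE, epsilon = 0.01, t_max = 50,
                           reg = 1e-8) {
  stopifnot(inherits(data, "trial_set"))
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  assignments <- make_fold_assignments(data, folds, repeats, seed, grouped)
  rows <- list()
  for (r in seq_len(repeats)) {
    fold_id <- assignments[[r]]
    for (f in seq_len(folds)) {
      test_idx <- which(fold_id == f)
      train <- trial_subset(data, which(fold_id != f))
      fit <- fit_mdsp(train, dims, epsilon = epsilon, t_max = t_max, reg = reg)
      pred <- predict(fit, trial_subset(data, test_idx))
      sc <- score_predictions(data$labels[test_idx], pred)
      rows[[length(rows) + 1]] <- tibble::tibble(
        repeat_ = r, fold = f, n_test = length(test_idx),
        accuracy = sc$metrics$accuracy, precision = sc$metrics$precision,
        recall = sc$metrics$recall, f1 = sc$metrics$f1,
        converged = fit$converged, iterations = fit$iterations
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "dims") <- dims
  attr(out, "folds") <- folds
  attr(out, "repeats") <- repeats
  attr(out, "seed") <- seed
  class(out) <- c("mdsp_cv", class(out))
  out
}

# One fold-id vector per repeat; stratified by class, at group granularity
# when groups are honored. Deterministic in `seed`.
make_fold_assignments <- function(data, folds, repeats, seed, grouped) {
  use_groups <- grouped && !is.null(data$groups)
  if (use_groups) {
    grp <- data$groups
    ug <- unique(grp)
    # a group's class = class of its first trial (windows share the epoch label)
    gclass <- data$labels[match(ug, grp)]
    counts <- table(gclass)
  } else {
    counts <- table(data$labels)
  }
  if (any(counts < folds)) {
    small <- names(counts)[which(counts < folds)[1]]
    stop(sprintf("class %s has only %d %s but %d folds were requested",
                 small, min(counts), if (use_groups) "groups" else "trials",
                 folds), call. = FALSE)
  }
  with_local_seed(seed, lapply(seq_len(repeats), function(r) {
    if (use_groups) {
      gfold <- integer(length(ug))
      for (cl in unique(gclass)) {
        idx <- which(gclass == cl)
        gfold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      gfold[match(grp, ug)]
    } else {
      fold_id <- integer(data$n)
      for (cl in data$classes) {
        idx <- which(data$labels == cl)
        fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      fold_id
    }
  }))
}

#' Grid search over filter counts (and preprocessing variants)
#'
#' Evaluates every combination of per-mode filter counts by
#' [cross_validate()]. Following the discard rule of the alternating
#' optimizer, a combination in which any fold's fit fails to converge within
#' `t_max` sweeps is flagged and excluded from the ranking; the remaining
#' combinations are ranked by mean accuracy, ties broken by fewer total
#' filters, then by lower filter counts on the lowest mode index. If no
#' combination converges the table is returned fully flagged with attribute
#' `no_convergent_configuration = TRUE` rather than raising an error.
#'
#' @param data A [trial_set()], or a named list of trial sets representing
#'   preprocessing candidates (e.g. different analysis-window starts); the
#'   grid is then crossed with the datasets.
#' @param dims_grid List of candidate filter counts per mode, e.g.
#'   `list(1:4, 1:4)`; expanded to the full Cartesian grid.
#' @param folds,repeats,seed,grouped,epsilon,t_max,reg See [cross_validate()].
#' @return A tibble of class `mdsp_grid`: `dataset`, `dims` (list column),
#'   one `m<k>` column per mode, `mean_accuracy`, `sd_accuracy`,
#'   `convergent`, `rank` (`NA` for flagged rows), ordered by rank.
#' @export
grid_search <- function(data, dims_grid, folds = 5, repeats = 5, seed = 1,
                        grouped = TRUE, epsilon = 0.01, t_max = 50,
                        reg = 1e-8) {
  datasets <- if (inherits(data, "trial_set")) list(data = data) else data
  stopifnot(length(datasets) >= 1, all(vapply(datasets, inherits, logical(1),
                                              "trial_set")))
  if (is.null(names(datasets))) names(datasets) <- paste0("data", seq_along(datasets))
  if (!is.list(dims_grid) || length(dims_grid) == 0) {
    stop("`dims_grid` must be a non-empty list of per-mode candidate counts",
         call. = FALSE)
  }
  combos <- expand.grid(rev(dims_grid), KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, rev(seq_along(dims_grid)), drop = FALSE]
  names(combos) <- paste0("m", seq_along(dims_grid))
  rows <- list()
  for (ds in names(datasets)) {
    for (i in seq_len(nrow(combos))) {
      dims <- as.integer(combos[i, ])
      cv <- cross_validate(datasets[[ds]], dims, folds = folds,
                           repeats = repeats, seed = seed, grouped = grouped,
                           epsilon = epsilon, t_max = t_max, reg = reg)
      row <- tibble::tibble(
        dataset = ds, dims = list(dims),
        mean_accuracy = mean(cv$accuracy), sd_accuracy = stats::sd(cv$accuracy),
        convergent = all(cv$converged)
      )
      for (k in seq_along(dims)) row[[paste0("m", k)]] <- dims[k]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  out$rank <- NA_integer_
  ok <- which(out$convergent)
  if (length(ok) > 0) {
    key <- out[ok, ]
    total <- vapply(key$dims, sum, integer(1))
    tie_cols <- as.matrix(key[, paste0("m", seq_along(dims_grid)), drop = FALSE])
    ord <- do.call(order, c(list(-key$mean_accuracy, total),
                            lapply(seq_len(ncol(tie_cols)),
                                   function(k) tie_cols[, k])))
    out$rank[ok[ord]] <- seq_along(ok)
  }
  out <- out[order(out$rank, na.last = TRUE), ]
  attr(out, "no_convergent_configuration") <- length(ok) == 0
  class(out) <- c("mdsp_grid", class(out))
  out
}
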