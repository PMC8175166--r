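#' Within- and between-class scatter matrices of 2-D trials
#'
#' For trials `X_i` (channels x time) with class means `M_j` and grand mean
#' `M`:
#' `S_w = sum_j sum_{i: y_i = j} (X_i - M_j)(X_i - M_j)^T` and
#' `S_b = sum_j n_j (M_j - M)(M_j - M)^T`. Both are `c x c`, symmetric,
#' positive semidefinite.
#'
#' @param data A [trial_set()] of order-2 trials.
#' @param means Optional precomputed [class_means()] result.
#' @return List with matrices `Sw` and `Sb`.
#' @export
scatter_matrices <- function(data, means = NULL) {
  stopifnot(inherits(data, "trial_set"))
  if (length(data$dims) != 2) {
    stop("scatter_matrices() expects order-2 (channels x time) trials; use mode_scatter() for tensors",
         call. = FALSE)
  }
  if (is.null(means)) means <- class_means(data)
  c_ <- data$dims[1]
  Sw <- matrix(0, c_, c_)
  Sb <- matrix(0, c_, c_)
  for (j in seq_along(data$classes)) {
    Mj <- means$class_means[[j]]
    for (i in which(data$labels == data$classes[j])) {
      D <- data$trials[[i]] - Mj
      Sw <- Sw + herm_tcrossprod(D)
    }
    B <- Mj - means$grand_mean
    Sb <- Sb + means$counts[[j]] * herm_tcrossprod(B)
  }
  list(Sw = Sw, Sb = Sb)
}

# Sign canonicalization: scale each column so its largest-magnitude entry is
# positive; ties in magnitude broken by the lowest row index. Makes eigenvector
# output reproducible and the convergence error well defined.
canonicalize_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    a <- abs(U[, j])
    i <- which(a == max(a))[1]
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

# Symmetric-definite generalized eigenproblem Sb u = lambda (Sw) u via
# Cholesky reduction: with Sw = L L^T, solve the ordinary symmetric problem
# L^{-1} Sb L^{-T} y = lambda y and back-transform u = L^{-T} y. Eigenvalues
# descending; eigenvectors Sw-orthonormal, then sign-canonicalized.
geigen_sym <- function(Sb, Sw, d) {
  R <- tryCatch(chol(Sw), error = function(e) NULL)
  # chol can "succeed" on a numerically singular PSD matrix with rounding-level
  # pivots; treat those as singular too (an added ridge always clears this bar)
  if (!is.null(R) &&
      min(diag(R))^2 <= nrow(Sw) * .Machine$double.eps * max(diag(Sw))) {
    R <- NULL
  }
  if (is.null(R)) {
    stop("within-class scatter is singular; refit with a ridge coefficient reg > 0",
         call. = FALSE)
  }
  L <- t(R)
  tmp <- forwardsolve(L, Sb)
  C <- t(forwardsolve(L, t(tmp)))
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  U <- backsolve(R, e$vectors[, seq_len(d), drop = FALSE])
  # unit-norm columns (the usual eigenvector convention): the Fisher ratio is
  # scale-invariant, and a scale-free U is what makes the relative-change
  # convergence error purely directional
  U <- U / rep(sqrt(colSums(U^2)), each = nrow(U))
  list(vectors = canonicalize_signs(U), values = e$values[seq_len(d)])
}

# Relative ridge: Sw + (reg * mean diagonal mass + eps floor) * I. reg = 0
# reproduces the unregularized formulation verbatim on well-posed inputs.
# The machine-epsilon floor is tied to the between-scatter scale (`hint`) so
# that a rounding-level within-scatter (noiseless trials, where tr(Sw) is
# ~eps^2 garbage) is treated as isotropic instead of being whitened against.
regularize_scatter <- function(Sw, reg, hint = NULL) {
  if (reg < 0) stop("`reg` must be >= 0", call. = FALSE)
  if (reg == 0) return(Sw)
  m <- nrow(Sw)
  tw <- Re(sum(diag(Sw))) / m
  th <- if (is.null(hint)) 0 else Re(sum(diag(hint))) / m
  ridge <- reg * tw + .Machine$double.eps * (tw + th)
  if (ridge <= 0) ridge <- reg
  Sw + diag(ridge, m)
}

#' Fit discriminative spatial patterns (DSP)
#'
#' Classical Fisher-criterion spatial filtering of 2-D EEG trials: finds
#' `U in R^{c x d}` maximizing `tr(U^T S_b U) / tr(U^T S_w U)` through the
#' generalized eigenproblem `S_b u = lambda S_w u`; the returned columns are
#' the eigenvectors of the `d` largest eigenvalues. An optional relative ridge
#' `reg * tr(S_w)/c * I` keeps `S_w` invertible when `n < c + p`.
#'
#' @param data A [trial_set()] of order-2 trials with at least 2 classes.
#' @param d Number of spatial filters, `1 <= d <= c`.
#' @param reg Relative ridge coefficient, default `1e-8`; `0` disables it.
#' @return An object of class `dsp_model`: projection `U` (sign-canonicalized,
#'   eigenvalues descending), `eigenvalues`, `class_means`, `grand_mean`,
#'   `scatter` (`Sw`, `Sb`), `counts`, `classes`, `d`, `reg`.
#' @export
fit_dsp <- function(data, d, reg = 1e-8) {
  stopifnot(inherits(data, "trial_set"))
  c_ <- data$dims[1]
  if (d < 1 || d > c_) {
    stop(sprintf("`d` must be in 1..%d (number of channels), got %s", c_, d),
         call. = FALSE)
  }
  if (length(data$classes) < 2) {
    stop("DSP needs at least 2 classes", call. = FALSE)
  }
  means <- class_means(data)
  sc <- scatter_matrices(data, means)
  Sw <- Re(regularize_scatter(sc$Sw, reg, hint = sc$Sb))
  ge <- geigen_sym(Re(sc$Sb), Sw, d)
  structure(
    list(
      U = ge$vectors, eigenvalues = ge$values,
      class_means = means$class_means, grand_mean = means$grand_mean,
      scatter = sc, counts = means$counts, classes = data$classes,
      d = as.integer(d), reg = reg, dims = data$dims
    ),
    class = "dsp_model"
  )
}

#' @export
print.dsp_model <- function(x, ...) {
  cat(sprintf("<dsp_model> %d spatial filters on %d channels; leading eigenvalues: %s\n",
              x$d, nrow(x$U),
              paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Spatially filtered DSP features
#'
#' Projects one trial through the learned filters after centering by the
#' training grand mean: `F = U^T (X - M)`. Test trials reuse the grand mean
#' estimated on the training set.
#'
#' @param model A fitted [fit_dsp()] model.
#' @param X A `c x t` trial matrix.
#' @return A `d x t` feature matrix.
#' @export
dsp_features <- function(model, X) {
  stopifnot(inherits(model, "dsp_model"))
  if (is.null(dim(X)) || !identical(dim(X), dim(model$grand_mean))) {
    stop(sprintf("trial shape (%s) does not match the model's (%s)",
                 paste(dim(X), collapse = ", "),
                 paste(dim(model$grand_mean), collapse = ", ")), call. = FALSE)
  }
  crossprod(model$U, X - model$grand_mean)
}
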