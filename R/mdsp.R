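#' Partially projected mode-k scatter matrices
#'
#' Fixing all projection matrices except mode `k`, the multilinear Fisher
#' criterion reduces to a DSP-like trace ratio in `U_k` alone. With
#' `B_j = (M_j - M)` projected through every `U_d`, `d != k`, and `B_j^(k)`
#' its mode-k unfolding, the between scatter is
#' `S_b^(k) = sum_j n_j B_j^(k) B_j^(k)H`; with `W_i = (X_i - M_j)` projected
#' likewise, `S_w^(k) = sum_i W_i^(k) W_i^(k)H`. Then the criterion's
#' numerator equals `tr(U_k^T S_b^(k) U_k)` and its denominator
#' `tr(U_k^T S_w^(k) U_k)`. Within-class terms are accumulated class by class
#' so the order-2 case with an identity co-projection reproduces
#' [scatter_matrices()] bit for bit.
#'
#' @param data A [trial_set()].
#' @param projections List of per-mode projection matrices `U_d`
#'   (`m_d x m_d'`); entry `k` is ignored.
#' @param mode The mode whose scatter pair is required.
#' @param means Optional precomputed [class_means()] result.
#' @return List with `Sb` and `Sw`, both `m_k x m_k` (Hermitian for complex
#'   trials).
#' @export
mode_scatter <- function(data, projections, mode, means = NULL) {
  stopifnot(inherits(data, "trial_set"))
  h <- length(data$dims)
  check_mode(mode, h)
  check_projections(projections, data$dims, skip = mode)
  if (is.null(means)) means <- class_means(data)
  mk <- data$dims[mode]
  Sb <- matrix(0, mk, mk)
  Sw <- matrix(0, mk, mk)
  for (j in seq_along(data$classes)) {
    Mj <- means$class_means[[j]]
    for (i in which(data$labels == data$classes[j])) {
      W <- multi_mode_product(data$trials[[i]] - Mj, projections, skip = mode)
      Sw <- Sw + herm_tcrossprod(tensor_unfold(W, mode))
    }
    B <- multi_mode_product(Mj - means$grand_mean, projections, skip = mode)
    Sb <- Sb + means$counts[[j]] * herm_tcrossprod(tensor_unfold(B, mode))
  }
  list(Sb = Sb, Sw = Sw)
}

check_projections <- function(projections, dims, skip = NULL) {
  for (k in seq_along(projections)) {
    if (!is.null(skip) && k == skip) next
    u <- projections[[k]]
    if (is.null(u)) next
    if (nrow(u) != dims[k]) {
      stop(sprintf("projection for mode %d has %d rows but the mode has size %d",
                   k, nrow(u), dims[k]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Conditionally optimal update of one projection matrix
#'
#' Solves the mode-`k` subproblem of the alternating optimization: the new
#' `U_k` collects the top `ndim` generalized eigenvectors of
#' `(S_b^(k), S_w^(k) + reg-ridge)`, sorted by descending eigenvalue and
#' sign-canonicalized exactly as in [fit_dsp()]. Complex Hermitian scatters
#' are reduced to their real parts (symmetric PSD) so projections stay real.
#'
#' @inheritParams mode_scatter
#' @param ndim Number of filters `m_k'` to retain for this mode.
#' @param reg Relative ridge coefficient applied to `S_w^(k)`.
#' @return List with the new `U_k` (`m_k x ndim`) and its `values`.
#' @export
update_mode <- function(data, projections, mode, ndim, reg = 1e-8, means = NULL) {
  sc <- mode_scatter(data, projections, mode, means = means)
  Sb <- Re(sc$Sb)
  Sw <- Re(regularize_scatter(sc$Sw, reg, hint = sc$Sb))
  if (ndim < 1 || ndim > nrow(Sb)) {
    stop(sprintf("mode %d: `ndim` must be in 1..%d, got %s", mode, nrow(Sb), ndim),
         call. = FALSE)
  }
  if (all(abs(Sb) < .Machine$double.eps * max(1, abs(Sw)))) {
    warning(sprintf("mode %d: between-class scatter is zero; objective is degenerate",
                    mode))
  }
  geigen_sym(Sb, Sw, ndim)
}

#' Relative change between successive projection matrices
#'
#' The mode-k convergence error at sweep `t`:
#' `err_k(t) = ||U_k^t - U_k^{t-1}||_F / ||U_k^{t-1}||_F^2`, evaluated after
#' sign canonicalization of both arguments (eigenvector sign flips would
#' otherwise make the error oscillate spuriously).
#'
#' @param U_prev,U_curr Matrices of identical shape.
#' @return A non-negative scalar; `0` when the canonicalized matrices agree.
#' @export
convergence_error <- function(U_prev, U_curr) {
  if (!identical(dim(U_prev), dim(U_curr))) {
    stop("`U_prev` and `U_curr` must have identical shape", call. = FALSE)
  }
  U_prev <- canonicalize_signs(U_prev)
  U_curr <- canonicalize_signs(U_curr)
  np <- fnorm(U_prev)
  if (np == 0) stop("`U_prev` has zero norm", call. = FALSE)
  fnorm(U_curr - U_prev) / np^2
}

fisher_objective <- function(centered, B_list, counts, projections) {
  num <- 0
  for (j in seq_along(B_list)) {
    num <- num + counts[[j]] * fnorm(multi_mode_product(B_list[[j]], projections))^2
  }
  den <- 0
  for (W in centered) {
    den <- den + fnorm(multi_mode_product(W, projections))^2
  }
  if (den == 0) Inf else num / den
}

# mode_scatter over precomputed centered trials / class differences; avoids
# re-centering every sweep. Same accumulation order as mode_scatter().
mode_scatter_centered <- function(centered, class_idx, B_list, counts,
                                  projections, mode, mk) {
  Sb <- matrix(0, mk, mk)
  Sw <- matrix(0, mk, mk)
  for (j in seq_along(B_list)) {
    for (i in class_idx[[j]]) {
      W <- multi_mode_product(centered[[i]], projections, skip = mode)
      Sw <- Sw + herm_tcrossprod(tensor_unfold(W, mode))
    }
    B <- multi_mode_product(B_list[[j]], projections, skip = mode)
    Sb <- Sb + counts[[j]] * herm_tcrossprod(tensor_unfold(B, mode))
  }
  list(Sb = Sb, Sw = Sw)
}

# Under the declared unfolding convention (remaining modes ascending, lowest
# varying fastest), projecting every mode but k acts on the mode-k unfolding
# by right multiplication with the Kronecker product of the co-projections in
# DESCENDING mode order:
#   unfold_k(X prod_{d != k} x_d U_d) = unfold_k(X) %*% kron(U_h, ..., U_1)[d != k].
kron_coprojection <- function(projections, skip) {
  P <- matrix(1, 1, 1)
  for (d in sort(setdiff(seq_along(projections), skip), decreasing = TRUE)) {
    P <- P %x% projections[[d]]
  }
  P
}

# One-time stacked unfoldings for the fast (real-valued) sweep: for every
# mode k, all centered trials (and sqrt(n_j)-weighted class differences) are
# unfolded and stacked trial-major into a single matrix, so each sweep's
# scatter pair is two BLAS products instead of n small tensor contractions.
build_sweep_stacks <- function(centered, class_idx, B_list, counts, dims) {
  h <- length(dims)
  Gw <- vector("list", h)
  Gb <- vector("list", h)
  ord <- unlist(class_idx)  # trial order matching the per-class accumulation
  for (k in seq_len(h)) {
    Gw[[k]] <- do.call(rbind, lapply(centered[ord],
                                     function(x) tensor_unfold(x, k)))
    Gb[[k]] <- do.call(rbind, lapply(seq_along(B_list), function(j) {
      sqrt(counts[[j]]) * tensor_unfold(B_list[[j]], k)
    }))
  }
  list(Gw = Gw, Gb = Gb, n = length(centered), p = length(B_list))
}

# Sw^(k), Sb^(k) from the stacked unfoldings under the current projections.
mode_scatter_stacked <- function(stacks, projections, mode, mk) {
  P <- kron_coprojection(projections, mode)
  fold_rows <- function(Y, blocks) {
    matrix(array(Y, dim = c(mk, blocks, ncol(Y))), mk)
  }
  Mw <- fold_rows(stacks$Gw[[mode]] %*% P, stacks$n)
  Mb <- fold_rows(stacks$Gb[[mode]] %*% P, stacks$p)
  list(Sb = tcrossprod(Mb), Sw = tcrossprod(Mw), Mw = Mw, Mb = Mb)
}

#' Fit multilinear discriminative spatial patterns (MDSP)
#'
#' Learns one projection matrix per tensor mode, `U_k in R^{m_k x m_k'}`,
#' jointly maximizing the multilinear Fisher criterion
#' `sum_j n_j ||(M_j - M) x_1 U_1 ... x_h U_h||^2 /
#'  sum_j sum_{i:y_i=j} ||(X_i - M_j) x_1 U_1 ... x_h U_h||^2`
#' by Gauss-Seidel alternating optimization: every `U_k` starts at the first
#' `m_k'` columns of the identity (or a seeded random orthonormal matrix),
#' then sweeps update modes `1..h` in ascending order via [update_mode()],
#' each update using the latest values of the other modes. After each sweep
#' the per-mode relative changes `err_k(t)` ([convergence_error()]) are
#' summed to `err(t)`; the fit stops when `err(t) <= epsilon` or after
#' `t_max` sweeps. Non-convergence is not an error: the model is returned
#' flagged (`converged = FALSE`) so a surrounding parameter search can discard
#' the configuration.
#'
#' @param data A [trial_set()] with at least 2 classes.
#' @param dims Integer vector of per-mode filter counts `(m_1', ..., m_h')`,
#'   `1 <= m_k' <= m_k`.
#' @param epsilon Convergence threshold on the summed relative change,
#'   default `0.01`.
#' @param t_max Maximum number of sweeps, default `50`.
#' @param reg Relative ridge on every within-class scatter, default `1e-8`.
#' @param init `"identity"` (deterministic, default) or `"random"` (seeded
#'   random orthonormal matrices).
#' @param seed Seed for `init = "random"`; ignored otherwise.
#' @return An object of class `mdsp_model`: `projections` (list of `U_k`),
#'   `class_means`, `grand_mean`, `counts`, `classes`, `dims_in`, `dims_out`,
#'   `converged`, `iterations`, and `trace`, a tibble with one row per sweep
#'   (`sweep`, per-mode `err_mode<k>`, total `err`, Fisher `objective`,
#'   wall-clock `seconds`).
#' @examples
#' set.seed(1)
#' ts <- trial_set(replicate(8, array(rnorm(24), c(2, 3, 4)), simplify = FALSE),
#'                 rep(1:2, 4))
#' fit <- fit_mdsp(ts, dims = c(2, 2, 2))
#' fit$converged
#' @export
fit_mdsp <- function(data, dims, epsilon = 0.01, t_max = 50, reg = 1e-8,
                     init = c("identity", "random"), seed = NULL) {
  stopifnot(inherits(data, "trial_set"))
  init <- match.arg(init)
  m <- data$dims
  h <- length(m)
  dims <- as.integer(dims)
  if (length(dims) != h) {
    stop(sprintf("`dims` must give one filter count per mode (order %d)", h),
         call. = FALSE)
  }
  if (any(dims < 1) || any(dims > m)) {
    bad <- which(dims < 1 | dims > m)[1]
    stop(sprintf("mode %d: filter count %d outside 1..%d", bad, dims[bad], m[bad]),
         call. = FALSE)
  }
  if (length(data$classes) < 2) stop("MDSP needs at least 2 classes", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (t_max < 1) stop("`t_max` must be >= 1", call. = FALSE)

  means <- class_means(data)
  class_idx <- lapply(data$classes, function(j) which(data$labels == j))
  centered <- vector("list", data$n)
  for (j in seq_along(class_idx)) {
    for (i in class_idx[[j]]) {
      centered[[i]] <- data$trials[[i]] - means$class_means[[j]]
    }
  }
  B_list <- lapply(means$class_means, function(Mj) Mj - means$grand_mean)

  U <- vector("list", h)
  if (init == "identity") {
    for (k in seq_len(h)) U[[k]] <- diag(m[k])[, seq_len(dims[k]), drop = FALSE]
  } else {
    U <- with_local_seed(seed, lapply(seq_len(h), function(k) {
      canonicalize_signs(qr.Q(qr(matrix(stats::rnorm(m[k] * dims[k]), m[k])))[,
        seq_len(dims[k]), drop = FALSE])
    }))
  }

  # Small problems take the straightforward per-trial accumulation (the same
  # summation order as mode_scatter / scatter_matrices); large ones take the
  # stacked BLAS path, which is algebraically identical but reassociates the
  # floating-point sums. Complex trials always take the per-trial path.
  complex_path <- any(vapply(data$trials, is.complex, logical(1))) ||
    data$n * prod(m) <= 1e5
  stacks <- if (!complex_path) {
    build_sweep_stacks(centered, class_idx, B_list, means$counts, m)
  }

  trace <- vector("list", t_max)
  converged <- FALSE
  t_used <- 0
  for (t in seq_len(t_max)) {
    t0 <- Sys.time()
    U_prev <- U
    obj <- NA_real_
    for (k in seq_len(h)) {
      sc <- if (complex_path) {
        mode_scatter_centered(centered, class_idx, B_list, means$counts,
                              U, k, m[k])
      } else {
        mode_scatter_stacked(stacks, U, k, m[k])
      }
      Sb <- Re(sc$Sb)
      Sw <- Re(regularize_scatter(sc$Sw, reg, hint = Sb))
      U[[k]] <- geigen_sym(Sb, Sw, dims[k])$vectors
      if (!complex_path && k == h) {
        # after the last mode's update these stacks carry all-new co-projections,
        # so the Fisher objective of the full projection is two small products
        num <- sum(crossprod(U[[h]], sc$Mb)^2)
        den <- sum(crossprod(U[[h]], sc$Mw)^2)
        obj <- if (den == 0) Inf else num / den
      }
    }
    if (complex_path) {
      obj <- fisher_objective(centered, B_list, means$counts, U)
    }
    errs <- vapply(seq_len(h),
                   function(k) convergence_error(U_prev[[k]], U[[k]]),
                   numeric(1))
    row <- c(list(sweep = t),
             stats::setNames(as.list(errs), paste0("err_mode", seq_len(h))),
             list(err = sum(errs), objective = obj,
                  seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    trace[[t]] <- tibble::as_tibble(row)
    t_used <- t
    if (sum(errs) <= epsilon) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      projections = U, class_means = means$class_means,
      grand_mean = means$grand_mean, counts = means$counts,
      classes = data$classes, dims_in = m, dims_out = dims,
      epsilon = epsilon, t_max = as.integer(t_max), reg = reg, init = init,
      converged = converged, iterations = t_used,
      trace = dplyr::bind_rows(trace[seq_len(t_used)])
    ),
    class = "mdsp_model"
  )
}

#' @export
print.mdsp_model <- function(x, ...) {
  cat(sprintf(
    "<mdsp_model> order-%d trials (%s) -> (%s); %d sweep(s), %s (final err %.3g)\n",
    length(x$dims_in), paste(x$dims_in, collapse = " x "),
    paste(x$dims_out, collapse = " x "), x$iterations,
    if (x$converged) "converged" else "NOT converged",
    utils::tail(x$trace$err, 1)
  ))
  invisible(x)
}

#' Project a trial into the learned tensor subspace
#'
#' `F = X x_1 U_1 x_2 U_2 ... x_h U_h`. The raw trial is projected without
#' mean centering; centering enters only the scatter computations during
#' fitting and the prototype distances at classification.
#'
#' @param model A fitted [fit_mdsp()] model.
#' @param X One trial array conforming to the model's input shape.
#' @return An array of shape `(m_1', ..., m_h')`.
#' @export
project_trial <- function(model, X) {
  stopifnot(inherits(model, "mdsp_model"))
  if (is.null(dim(X)) || !identical(as.integer(dim(X)), model$dims_in)) {
    stop(sprintf("trial shape (%s) does not match the model's input shape (%s)",
                 paste(dim(X), collapse = ", "),
                 paste(model$dims_in, collapse = ", ")), call. = FALSE)
  }
  multi_mode_product(X, model$projections)
}

# Run `expr` under a temporary RNG state; restores the caller's state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(seed, expr)
}
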