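#' Mode-k unfolding of a tensor
#'
#' Rearranges an order-`h` dense array into a matrix whose rows index mode
#' `mode`. Columns enumerate the remaining modes in ascending mode order with
#' the lowest remaining mode varying fastest: element `(i_1, ..., i_h)` lands
#' in row `i_k` and column
#' `1 + sum_{d != k} (i_d - 1) * prod_{e < d, e != k} m_e`.
#' This convention is the exact inverse of [tensor_fold()].
#'
#' @param x Dense numeric (or complex) array of order >= 2.
#' @param mode Mode to unfold along, 1-based, in `1..h`.
#' @return A matrix with `dim(x)[mode]` rows and `prod(dim(x)[-mode])` columns.
#' @examples
#' x <- array(1:24, dim = c(2, 3, 4))
#' dim(tensor_unfold(x, 2)) # 3 x 8
#' @export
tensor_unfold <- function(x, mode) {
  dims <- dim(x)
  if (is.null(dims) || length(dims) < 2) {
    stop("`x` must be a dense array of order >= 2", call. = FALSE)
  }
  h <- length(dims)
  check_mode(mode, h)
  perm <- c(mode, setdiff(seq_len(h), mode))
  m <- aperm(x, perm)
  dim(m) <- c(dims[mode], prod(dims[-mode]))
  m
}

#' Fold a mode-k unfolding back into a tensor
#'
#' Inverse of [tensor_unfold()]: `tensor_fold(tensor_unfold(x, k), k, dim(x))`
#' recovers `x` elementwise for every mode `k`.
#'
#' @param m Matrix with `dims[mode]` rows and `prod(dims[-mode])` columns.
#' @param mode Mode the matrix was unfolded along, 1-based.
#' @param dims Target tensor shape (integer vector, length >= 2).
#' @return A dense array of shape `dims`.
#' @export
tensor_fold <- function(m, mode, dims) {
  h <- length(dims)
  if (h < 2) stop("`dims` must describe an array of order >= 2", call. = FALSE)
  check_mode(mode, h)
  if (nrow(m) != dims[mode] || ncol(m) != prod(dims[-mode])) {
    stop(sprintf(
      "cannot fold a %d x %d matrix into shape (%s) along mode %d: expected %d x %d",
      nrow(m), ncol(m), paste(dims, collapse = ", "), mode,
      dims[mode], prod(dims[-mode])
    ), call. = FALSE)
  }
  perm <- c(mode, setdiff(seq_len(h), mode))
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

#' Mode-k product of a tensor and a matrix
#'
#' Contracts mode `mode` of `x` (size `m_k`) with an `m_k x m_k'` matrix `u`:
#' the result element `(i_1, ..., j, ..., i_h)` is
#' `sum_i x[i_1, ..., i, ..., i_h] * u[i, j]`, so the mode-`k` size becomes
#' `ncol(u)`. Equivalently `tensor_fold(t(u) %*% tensor_unfold(x, k), k, .)`.
#' For complex inputs the transpose is plain (not conjugated); conjugation
#' enters only in the scatter computations of [mode_scatter()].
#'
#' @param x Dense array of order >= 2.
#' @param u Matrix with `dim(x)[mode]` rows.
#' @param mode Mode to contract, 1-based.
#' @return Array whose mode-`mode` size is `ncol(u)`.
#' @export
mode_product <- function(x, u, mode) {
  dims <- dim(x)
  if (is.null(dims) || length(dims) < 2) {
    stop("`x` must be a dense array of order >= 2", call. = FALSE)
  }
  check_mode(mode, length(dims))
  u <- as.matrix(u)
  if (nrow(u) != dims[mode]) {
    stop(sprintf(
      "mode-%d product needs a matrix with %d rows, got %d",
      mode, dims[mode], nrow(u)
    ), call. = FALSE)
  }
  unf <- tensor_unfold(x, mode)
  res <- if (is.complex(unf) || is.complex(u)) t(u) %*% unf else crossprod(u, unf)
  new_dims <- dims
  new_dims[mode] <- ncol(u)
  tensor_fold(res, mode, new_dims)
}

#' Sequential mode products over several modes
#'
#' Applies [mode_product()] along every mode that has a matrix in `mats`,
#' optionally skipping one mode. Because products along distinct modes
#' commute, the result is independent of application order.
#'
#' @param x Dense array of order >= 2.
#' @param mats List of per-mode matrices, `mats[[k]]` conforming to mode `k`;
#'   a `NULL` entry leaves that mode unprojected.
#' @param skip Optional mode index to leave unprojected even if a matrix is
#'   supplied.
#' @return The multiply-projected array.
#' @export
multi_mode_product <- function(x, mats, skip = NULL) {
  dims <- dim(x)
  if (is.null(dims) || length(dims) < 2) {
    stop("`x` must be a dense array of order >= 2", call. = FALSE)
  }
  h <- length(dims)
  if (length(mats) > h) {
    stop(sprintf("got %d projection matrices for an order-%d tensor",
                 length(mats), h), call. = FALSE)
  }
  if (!is.null(skip)) check_mode(skip, h)
  for (k in seq_along(mats)) {
    if (!is.null(skip) && k == skip) next
    if (is.null(mats[[k]])) next
    x <- mode_product(x, mats[[k]], k)
  }
  x
}

check_mode <- function(mode, h) {
  if (length(mode) != 1 || !is.finite(mode) || mode != as.integer(mode) ||
      mode < 1 || mode > h) {
    stop(sprintf("`mode` must be a single index in 1..%d (tensor order %d), got %s",
                 h, h, paste(format(mode), collapse = ",")), call. = FALSE)
  }
  invisible(as.integer(mode))
}

# Hermitian outer product a %*% Conj(t(a)); plain tcrossprod for real input.
herm_tcrossprod <- function(a) {
  if (is.complex(a)) a %*% Conj(t(a)) else tcrossprod(a)
}

# Frobenius norm, complex-safe.
fnorm <- function(x) sqrt(sum(Mod(x)^2))
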