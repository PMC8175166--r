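# Independent brute-force oracles used to pin down the tensor algebra and
# scatter definitions. All are deliberately naive (index loops over the
# written-out summation formulas) and share no code with the implementation.

rand_tensor <- function(dims) array(rnorm(prod(dims)), dim = dims)

# unfold by the documented index formula: element (i_1..i_h) -> row i_k,
# column 1 + sum_{d != k}(i_d - 1) * prod_{e < d, e != k} m_e
oracle_unfold <- function(x, k) {
  dims <- dim(x)
  h <- length(dims)
  out <- matrix(NA_real_, dims[k], prod(dims[-k]))
  idx_grid <- as.matrix(expand.grid(lapply(dims, seq_len)))
  for (r in seq_len(nrow(idx_grid))) {
    idx <- idx_grid[r, ]
    rest <- setdiff(seq_len(h), k)
    col <- 1
    mult <- 1
    for (d in rest) {
      col <- col + (idx[d] - 1) * mult
      mult <- mult * dims[d]
    }
    out[idx[k], col] <- x[matrix(idx, 1)]
  }
  out
}

# mode-k product by the definition's summation, looped over every output index
oracle_mode_product <- function(x, u, k) {
  dims <- dim(x)
  new_dims <- dims
  new_dims[k] <- ncol(u)
  out <- array(0, dim = new_dims)
  idx_grid <- as.matrix(expand.grid(lapply(new_dims, seq_len)))
  for (r in seq_len(nrow(idx_grid))) {
    idx <- idx_grid[r, ]
    acc <- 0
    for (i in seq_len(dims[k])) {
      src <- idx
      src[k] <- i
      acc <- acc + x[matrix(src, 1)] * u[i, idx[k]]
    }
    out[matrix(idx, 1)] <- acc
  }
  out
}

# per-element loop evaluation of the class means
oracle_class_means <- function(trials, labels) {
  classes <- sort(unique(labels))
  cm <- lapply(classes, function(j) {
    idx <- which(labels == j)
    acc <- array(0, dim = dim(trials[[1]]))
    for (i in idx) acc <- acc + trials[[i]]
    acc / length(idx)
  })
  grand <- array(0, dim = dim(trials[[1]]))
  for (i in seq_along(trials)) grand <- grand + trials[[i]]
  list(class_means = cm, grand_mean = grand / length(trials))
}

# double-loop evaluation of the scatter definitions for 2-D trials
oracle_scatters <- function(trials, labels) {
  om <- oracle_class_means(trials, labels)
  classes <- sort(unique(labels))
  c_ <- nrow(trials[[1]])
  Sw <- matrix(0, c_, c_)
  Sb <- matrix(0, c_, c_)
  for (jj in seq_along(classes)) {
    Mj <- om$class_means[[jj]]
    for (i in which(labels == classes[jj])) {
      D <- trials[[i]] - Mj
      Sw <- Sw + D %*% t(D)
    }
    B <- Mj - om$grand_mean
    Sb <- Sb + sum(labels == classes[jj]) * (B %*% t(B))
  }
  list(Sw = Sw, Sb = Sb)
}

# random labeled 2-D trial set
rand_matrix_set <- function(n_per_class, classes, c_, t_, sep = 0) {
  trials <- list()
  labels <- integer(0)
  for (j in seq_len(classes)) {
    shift <- matrix(0, c_, t_)
    if (sep > 0) shift[(j - 1) %% c_ + 1, ] <- sep
    for (i in seq_len(n_per_class)) {
      trials[[length(trials) + 1]] <- matrix(rnorm(c_ * t_), c_) + shift
      labels <- c(labels, j)
    }
  }
  trial_set(trials, labels)
}

max_principal_angle <- function(A, B) {
  max(subspace_recovery_score(list(A), list(B)))
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
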