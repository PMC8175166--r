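#' Specification of a planted-subspace tensor dataset
#'
#' Describes a dataset whose class mean tensors differ only inside a known
#' low-dimensional multilinear subspace: class-`j` mean
#' `= a * core_j x_1 Q_1 ... x_h Q_h` with shared random orthonormal bases
#' `Q_k (m_k x r_k)` and distinct random cores, plus iid Gaussian noise of
#' sd `sigma` on every trial. The defaults (`amplitude = 1`,
#' `noise_sd = 0.1`) put the noise at a tenth of the planted effect.
#'
#' @param shape Tensor shape `(m_1, ..., m_h)`, order >= 2.
#' @param ranks Per-mode planted ranks `(r_1, ..., r_h)`, `r_k <= m_k`.
#' @param classes Number of classes `p >= 2`.
#' @param trials_per_class Training trials drawn per class.
#' @param amplitude Effect amplitude `a >= 0`.
#' @param noise_sd Noise standard deviation `sigma >= 0`.
#' @param holdout_per_class Extra trials per class drawn from the same class
#'   means, returned separately for held-out evaluation (default 0).
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return Object of class `planted_spec`.
#' @export
planted_spec <- function(shape, ranks, classes = 2, trials_per_class = 40,
                         amplitude = 1, noise_sd = 0.1, holdout_per_class = 0,
                         seed = 1) {
  shape <- as.integer(shape)
  ranks <- as.integer(ranks)
  if (length(shape) < 2 || any(shape < 1)) {
    stop("`shape` must be an order >= 2 shape of positive sizes", call. = FALSE)
  }
  if (length(ranks) != length(shape) || any(ranks < 1) || any(ranks > shape)) {
    stop("`ranks` must satisfy 1 <= r_k <= m_k for every mode", call. = FALSE)
  }
  if (classes < 2) stop("`classes` must be >= 2", call. = FALSE)
  if (amplitude < 0 || noise_sd < 0) {
    stop("`amplitude` and `noise_sd` must be >= 0", call. = FALSE)
  }
  structure(list(shape = shape, ranks = ranks, classes = as.integer(classes),
                 trials_per_class = as.integer(trials_per_class),
                 amplitude = amplitude, noise_sd = noise_sd,
                 holdout_per_class = as.integer(holdout_per_class),
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a planted-subspace tensor dataset
#'
#' @param spec A [planted_spec()].
#' @return List with `data` (a [trial_set()]), `holdout` (a `trial_set` or
#'   `NULL`), `bases` (the ground-truth `Q_k`), and `class_means`.
#' @export
planted_dataset <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  with_local_seed(spec$seed, {
    h <- length(spec$shape)
    Q <- lapply(seq_len(h), function(k) {
      qr.Q(qr(matrix(stats::rnorm(spec$shape[k] * spec$ranks[k]),
                     spec$shape[k])))[, seq_len(spec$ranks[k]), drop = FALSE]
    })
    means <- lapply(seq_len(spec$classes), function(j) {
      core <- array(stats::rnorm(prod(spec$ranks)), dim = spec$ranks)
      M <- core
      for (k in seq_len(h)) M <- mode_product(M, t(Q[[k]]), k)
      spec$amplitude * M
    })
    draw <- function(per_class) {
      trials <- list()
      labels <- integer(0)
      for (j in seq_len(spec$classes)) {
        for (i in seq_len(per_class)) {
          noise <- array(stats::rnorm(prod(spec$shape), sd = spec$noise_sd),
                         dim = spec$shape)
          trials[[length(trials) + 1]] <- means[[j]] + noise
          labels <- c(labels, j)
        }
      }
      trial_set(trials, labels)
    }
    data <- draw(spec$trials_per_class)
    holdout <- if (spec$holdout_per_class > 0) draw(spec$holdout_per_class) else NULL
    list(data = data, holdout = holdout, bases = Q, class_means = means)
  })
}

#' Principal angles between estimated and planted subspaces
#'
#' For each mode, the canonical angles between the column spans of the
#' estimated `U_k` and the ground-truth `Q_k`, from the singular values of
#' the product of their orthonormalized bases. Returns the largest angle per
#' mode (radians): 0 means perfect recovery, `pi/2` an orthogonal estimate.
#' Angles are computed on the `min(r_k, m_k')` leading directions.
#'
#' @param estimated List of estimated per-mode matrices (e.g. an
#'   `mdsp_model$projections`).
#' @param truth List of planted bases `Q_k`.
#' @return Numeric vector of per-mode maximum principal angles in radians.
#' @export
subspace_recovery_score <- function(estimated, truth) {
  if (length(estimated) != length(truth)) {
    stop("`estimated` and `truth` must have one matrix per mode", call. = FALSE)
  }
  vapply(seq_along(estimated), function(k) {
    U <- qr_basis(estimated[[k]])
    Q <- qr_basis(truth[[k]])
    r <- min(ncol(U), ncol(Q))
    s <- svd(crossprod(Q, U))$d[seq_len(r)]
    smin <- min(pmin(pmax(s, 0), 1))
    if (smin^2 < 0.5) {
      acos(smin)
    } else {
      # near-aligned spans: acos() cannot resolve angles below ~sqrt(eps);
      # the sine of the largest angle is the spectral norm of the residual
      resid <- U - Q %*% crossprod(Q, U)
      asin(min(1, max(svd(resid)$d)))
    }
  }, numeric(1))
}

qr_basis <- function(M) {
  qrd <- qr(M)
  if (qrd$rank < ncol(M)) {
    stop("rank-deficient matrix: subspace angles are undefined", call. = FALSE)
  }
  qr.Q(qrd)[, seq_len(ncol(M)), drop = FALSE]
}

#' Specification of simulated MRCP trials
#'
#' Emulates the movement-related cortical potential: a slow negative drift
#' that builds up before a voluntary movement on a lateralized subset of
#' channels (contralateral to the moving finger), buried in 1/f (pink)
#' background noise on every channel. The default geometry mirrors a
#' 19-channel 10-20 montage at 100 Hz with 2 s pre-movement epochs, 40
#' trials per class, drift onset 0.4 s before the event (the late NS
#' component), peak drift amplitude 8 (negative, arbitrary microvolt-like
#' units) and pink-noise sd 2.
#'
#' @param channels Number of channels `c`.
#' @param rate Sampling rate in Hz.
#' @param duration Epoch length in seconds; epochs span `-duration..0` s.
#' @param active List of two integer vectors: channels carrying the drift for
#'   class 1 ("left tap", right-hemisphere sites) and class 2 ("right tap",
#'   left-hemisphere sites). Defaults to mirrored central sites.
#' @param amplitude Peak drift magnitude (applied as a negative shift).
#' @param onset Drift onset in seconds before the event.
#' @param noise_sd Pink-noise standard deviation per channel.
#' @param trials_per_class Trials per class.
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return Object of class `mrcp_spec`.
#' @export
mrcp_spec <- function(channels = 19, rate = 100, duration = 2,
                      active = NULL, amplitude = 8, onset = 0.4,
                      noise_sd = 2, trials_per_class = 40, seed = 1) {
  channels <- as.integer(channels)
  if (channels < 2) stop("`channels` must be >= 2", call. = FALSE)
  if (onset <= 0 || onset > duration) {
    stop("`onset` must lie within the epoch (0 < onset <= duration)",
         call. = FALSE)
  }
  if (is.null(active)) {
    mid <- (channels + 1) / 2
    off <- max(2, round(channels / 6))
    pick <- function(center) {
      sort(unique(pmin(pmax(round(center) + (-1:1), 1L), channels)))
    }
    active <- list(pick(mid + off), pick(mid - off))
  }
  if (length(active) != 2 ||
      !all(unlist(active) %in% seq_len(channels))) {
    stop("`active` must be two channel-index vectors within 1..channels",
         call. = FALSE)
  }
  structure(list(channels = channels, rate = rate, duration = duration,
                 active = active, amplitude = amplitude, onset = onset,
                 noise_sd = noise_sd,
                 trials_per_class = as.integer(trials_per_class),
                 seed = as.integer(seed)),
            class = "mrcp_spec")
}

# 1/f-amplitude noise, unit sd, via spectral shaping of white noise.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k0 <- 0:(n - 1)
  f <- pmin(k0, n - k0)  # symmetric frequency index
  f[1] <- 1              # keep DC finite; removed by centering below
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate simulated MRCP trials
#'
#' Each trial is a `channels x T` epoch spanning `-duration..0` s: the
#' class's active channels carry a linear negative ramp that starts `onset`
#' seconds before the event and reaches `-amplitude` at the event; every
#' channel additionally carries independent pink noise of sd `noise_sd`.
#'
#' @param spec An [mrcp_spec()].
#' @return List with `epochs` (list of [recording_epoch()]) and `labels`
#'   (1 = left tap, 2 = right tap).
#' @export
mrcp_trials <- function(spec) {
  stopifnot(inherits(spec, "mrcp_spec"))
  with_local_seed(spec$seed, {
    T_ <- round(spec$duration * spec$rate)
    t <- seq(-spec$duration, by = 1 / spec$rate, length.out = T_)
    ramp <- -spec$amplitude * pmax(0, (t + spec$onset) / spec$onset)
    epochs <- list()
    labels <- integer(0)
    for (j in 1:2) {
      for (i in seq_len(spec$trials_per_class)) {
        X <- matrix(0, spec$channels, T_)
        X[spec$active[[j]], ] <- matrix(ramp, length(spec$active[[j]]), T_,
                                        byrow = TRUE)
        if (spec$noise_sd > 0) {
          for (ch in seq_len(spec$channels)) {
            X[ch, ] <- X[ch, ] + spec$noise_sd * pink_noise(T_)
          }
        }
        epochs[[length(epochs) + 1]] <- recording_epoch(X, spec$rate,
                                                        t0 = -spec$duration)
        labels <- c(labels, j)
      }
    }
    list(epochs = epochs, labels = labels)
  })
}
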