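#' A multichannel EEG epoch
#'
#' @param samples `channels x time` numeric matrix.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample relative to the movement event, in
#'   seconds (e.g. `-2` for an epoch covering the 2 s before the event).
#' @return Object of class `recording_epoch`.
#' @export
recording_epoch <- function(samples, rate, t0 = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || ncol(samples) < 2) {
    stop("`samples` must be a numeric channels x time matrix with >= 2 samples",
         call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("`rate` must be a positive sampling rate in Hz", call. = FALSE)
  }
  structure(list(samples = samples, rate = rate, t0 = t0),
            class = "recording_epoch")
}

#' @export
print.recording_epoch <- function(x, ...) {
  cat(sprintf("<recording_epoch> %d channels x %d samples @ %g Hz, t0 = %g s\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$t0))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth low-pass filter to each
#' channel. The defaults — order 5, 7 Hz cutoff — isolate the low-frequency
#' MRCP band.
#'
#' @param epoch A [recording_epoch()].
#' @param cutoff_hz Cutoff frequency in Hz, must be below Nyquist.
#' @param order Filter order.
#' @return The filtered epoch (shape and timing preserved).
#' @export
eeg_lowpass <- function(epoch, cutoff_hz = 7, order = 5) {
  stopifnot(inherits(epoch, "recording_epoch"))
  if (cutoff_hz >= epoch$rate / 2) {
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 cutoff_hz, epoch$rate / 2), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (epoch$rate / 2), type = "low")
  # odd-reflection padding before the forward-backward pass keeps the filter
  # state consistent at the epoch boundaries (filtfilt alone starts from zero
  # state, which leaves large edge transients on signals with offsets)
  T_ <- ncol(epoch$samples)
  npad <- min(T_ - 1, ceiling(2 * epoch$rate / cutoff_hz) * order)
  out <- t(apply(epoch$samples, 1, function(x) {
    left <- 2 * x[1] - x[(npad + 1):2]
    right <- 2 * x[T_] - x[(T_ - 1):(T_ - npad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    y[(npad + 1):(npad + T_)]
  }))
  recording_epoch(out, epoch$rate, epoch$t0)
}

#' Spectral downsampling of an epoch
#'
#' Resamples each channel to `target_rate` by exact Fourier-domain
#' resampling (zero-delay band limitation to the new Nyquist frequency).
#' Output length is `round(T * p/q)` where `p/q` is the reduced rational
#' `target_rate / rate` (exactly `T * p/q` when that is an integer, e.g.
#' 6144 samples at 1024 Hz -> 600 samples at 100 Hz). `t0` is preserved.
#'
#' @param epoch A [recording_epoch()].
#' @param target_rate New sampling rate in Hz, `<=` the current rate.
#' @return The resampled epoch.
#' @export
eeg_resample <- function(epoch, target_rate) {
  stopifnot(inherits(epoch, "recording_epoch"))
  if (target_rate > epoch$rate) {
    stop("upsampling is not supported: `target_rate` must be <= the epoch rate",
         call. = FALSE)
  }
  if (target_rate == epoch$rate) return(epoch)
  scaled <- round(c(target_rate, epoch$rate) * 1000)
  g <- rational_gcd(scaled[1], scaled[2])
  T_ <- ncol(epoch$samples)
  n_out <- round(T_ * (scaled[1] / g) / (scaled[2] / g))
  out <- t(apply(epoch$samples, 1, fft_resample, n_out = n_out))
  recording_epoch(out, target_rate, epoch$t0)
}

# Fourier resampling to n_out samples: keep the spectrum below the new
# Nyquist, drop the rest, invert at the new length.
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  X <- stats::fft(x)
  K <- min(floor((n_out - 1) / 2), floor((n_in - 1) / 2))
  Y <- complex(n_out)
  Y[1] <- X[1]
  if (K > 0) {
    Y[1 + seq_len(K)] <- X[1 + seq_len(K)]
    Y[n_out + 1 - seq_len(K)] <- X[n_in + 1 - seq_len(K)]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

rational_gcd <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' Sliding windows over an epoch
#'
#' Cuts consecutive windows of `round(length_s * rate)` samples starting at
#' `t0, t0 + step_s, ...`; window `w`'s start index is exactly
#' `(w - 1) * round(step_s * rate)` and any final partial window is discarded,
#' giving `floor((T - L) / step) + 1` windows. The defaults (0.5 s windows
#' moved by a 0.1 s hop, i.e. 0.4 s overlap) match the MRCP analysis chain;
#' set `step_s = 0.4` for the literal 0.1 s-overlap reading.
#'
#' @param epoch A [recording_epoch()].
#' @param length_s Window length in seconds.
#' @param step_s Hop between window starts in seconds.
#' @return List of `recording_epoch` windows with correct `t0` values.
#' @export
sliding_windows <- function(epoch, length_s = 0.5, step_s = 0.1) {
  stopifnot(inherits(epoch, "recording_epoch"))
  T_ <- ncol(epoch$samples)
  L <- round(length_s * epoch$rate)
  step <- round(step_s * epoch$rate)
  if (step < 1) stop("`step_s` must be at least one sample", call. = FALSE)
  if (L > T_) {
    stop(sprintf("window of %d samples exceeds the %d-sample epoch", L, T_),
         call. = FALSE)
  }
  n_win <- floor((T_ - L) / step) + 1
  lapply(seq_len(n_win), function(w) {
    s <- (w - 1) * step
    recording_epoch(epoch$samples[, (s + 1):(s + L), drop = FALSE],
                    epoch$rate, epoch$t0 + s / epoch$rate)
  })
}

#' Complex Gaussian mother wavelet
#'
#' The order-`P` complex Gaussian wavelet is the `P`-th derivative of
#' `exp(-i x) exp(-x^2)`, L2-normalized. The derivative is carried as a
#' complex polynomial factor via the recursion
#' `p_{n+1}(x) = p_n'(x) + (-i - 2x) p_n(x)`.
#'
#' @param order Derivative order, 1..8.
#' @return List with `psi(x)` (vectorized complex evaluation) and
#'   `center_freq`, the spectral-peak frequency magnitude in cycles per unit
#'   of `x` (used to convert scales to pseudo-frequencies).
#' @export
cgau_wavelet <- function(order = 4) {
  if (!(order %in% 1:8)) {
    stop("unsupported wavelet order; supported complex Gaussian orders: cgau1..cgau8",
         call. = FALSE)
  }
  # polynomial coefficients, ascending powers, complex
  p <- as.complex(1)
  for (n in seq_len(order)) {
    dp <- if (length(p) > 1) p[-1] * seq_len(length(p) - 1) else as.complex(0)
    term1 <- c(dp, 0 + 0i, 0 + 0i)[seq_len(length(p) + 1)]
    termI <- c(-1i * p, 0 + 0i)[seq_len(length(p) + 1)]
    termX <- c(0 + 0i, -2 * p)
    p <- term1 + termI + termX
  }
  poly_eval <- function(x) {
    acc <- rep(p[length(p)], length(x))
    for (k in rev(seq_len(length(p) - 1))) acc <- acc * x + p[k]
    acc
  }
  raw <- function(x) poly_eval(x) * exp(-1i * x - x^2)
  # numeric L2 normalization and spectral peak on a fine grid
  dx <- 1 / 64
  grid <- seq(-8, 8, by = dx)
  v <- raw(grid)
  nrm <- sqrt(sum(Mod(v)^2) * dx)
  sp <- Mod(stats::fft(v))
  freqs <- (seq_along(grid) - 1) / (length(grid) * dx)
  freqs[freqs > 1 / (2 * dx)] <- freqs[freqs > 1 / (2 * dx)] - 1 / dx
  fc <- abs(freqs[which.max(sp)])
  list(psi = function(x) raw(x) / nrm, center_freq = fc, order = order)
}

#' Wavelet configuration for CWT tensorization
#'
#' @param family Mother wavelet name, `"cgau1"`..`"cgau8"` (complex Gaussian
#'   of that derivative order); default `"cgau4"`.
#' @param scales Optional explicit scale sequence (in samples, strictly
#'   positive and strictly increasing). When `NULL`, [cwt_tensorize()]
#'   derives `n_scales` log-spaced scales whose pseudo-frequencies cover
#'   `freq_range` at the epoch's sampling rate.
#' @param n_scales Number of scales when `scales` is `NULL`; default 10.
#' @param freq_range Pseudo-frequency band in Hz covered by the automatic
#'   scale sequence; default `c(0.5, 7)`, the MRCP band.
#' @param magnitude If `TRUE` (default) the tensor holds coefficient moduli;
#'   if `FALSE`, complex coefficients are kept.
#' @return Object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = "cgau4", scales = NULL, n_scales = 10,
                         freq_range = c(0.5, 7), magnitude = TRUE) {
  m <- regmatches(family, regexec("^cgau([1-8])$", family))[[1]]
  if (length(m) == 0) {
    stop(sprintf("unknown wavelet family '%s'; supported: cgau1..cgau8", family),
         call. = FALSE)
  }
  if (!is.null(scales)) {
    scales <- as.numeric(scales)
    if (any(scales <= 0) || length(scales) < 1 ||
        (length(scales) > 1 && any(diff(scales) <= 0))) {
      stop("`scales` must be strictly positive and strictly increasing",
           call. = FALSE)
    }
  } else if (n_scales < 1) {
    stop("`n_scales` must be >= 1", call. = FALSE)
  }
  structure(list(family = family, order = as.integer(m[2]), scales = scales,
                 n_scales = as.integer(n_scales), freq_range = freq_range,
                 magnitude = isTRUE(magnitude)),
            class = "wavelet_spec")
}

resolve_scales <- function(spec, rate) {
  if (!is.null(spec$scales)) return(spec$scales)
  wav <- cgau_wavelet(spec$order)
  freqs <- exp(seq(log(spec$freq_range[2]), log(spec$freq_range[1]),
                   length.out = spec$n_scales))
  sort(wav$center_freq * rate / freqs)
}

# Linear convolution via FFT, complex-safe; returns length(x)+length(h)-1.
conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1
  N <- stats::nextn(n, 2)
  out <- stats::fft(stats::fft(c(x, rep(0, N - length(x)))) *
                    stats::fft(c(h, rep(0, N - length(h)))), inverse = TRUE) / N
  out[seq_len(n)]
}

#' Continuous wavelet transform tensorization
#'
#' Expands a 2-D epoch (channels x time) into a 3-D tensor
#' (channels x time x scales): per channel, the CWT coefficient at scale `a`
#' and position `b` is `a^{-1/2} * sum_n x[n] Conj(psi((n - b)/a))`, scales in
#' samples. With `magnitude = TRUE` (default) coefficient moduli are stored;
#' otherwise the complex coefficients.
#'
#' @param epoch A [recording_epoch()].
#' @param spec A [wavelet_spec()].
#' @return Array `c x T x S` with attributes `scales` (samples) and
#'   `pseudo_freqs` (Hz).
#' @export
cwt_tensorize <- function(epoch, spec = wavelet_spec()) {
  stopifnot(inherits(epoch, "recording_epoch"), inherits(spec, "wavelet_spec"))
  x <- epoch$samples
  scales <- resolve_scales(spec, epoch$rate)
  wav <- cgau_wavelet(spec$order)
  T_ <- ncol(x)
  c_ <- nrow(x)
  S <- length(scales)
  out <- array(if (spec$magnitude) 0 else as.complex(0), dim = c(c_, T_, S))
  for (s in seq_len(S)) {
    a <- scales[s]
    half <- ceiling(5 * a)  # effective Gaussian support
    k <- (-half):half
    g <- Conj(wav$psi(k / a)) / sqrt(a)
    # cross-correlation: C(b) = sum_k x[b + k] g[k] = full-conv with rev(g),
    # sample b at offset half + b.
    grev <- rev(g)
    for (ch in seq_len(c_)) {
      full <- conv_full(as.complex(x[ch, ]), grev)
      coefs <- full[(half + 1):(half + T_)]
      out[ch, , s] <- if (spec$magnitude) Mod(coefs) else coefs
    }
  }
  attr(out, "scales") <- scales
  attr(out, "pseudo_freqs") <- wav$center_freq * epoch$rate / scales
  out
}

#' Preprocess labeled epochs into a trial set of tensors
#'
#' The full tensorization chain: optional resampling, zero-phase low-pass
#' filtering, sliding-window segmentation, and (optionally) CWT expansion of
#' each window into a channels x time x scales tensor. Windows inherit their
#' source epoch's label and are grouped by epoch so grouped cross-validation
#' can keep them in one fold.
#'
#' @param epochs List of [recording_epoch()] objects.
#' @param labels One integer class label per epoch.
#' @param resample_hz Optional target rate applied before filtering.
#' @param cutoff_hz,order Low-pass settings, see [eeg_lowpass()]; `NULL`
#'   cutoff skips filtering.
#' @param window_s,step_s Sliding-window settings, see [sliding_windows()].
#' @param wavelet A [wavelet_spec()] for CWT tensorization, or `NULL` to keep
#'   2-D (channels x time) windows.
#' @return A [trial_set()] whose `groups` field records the source epoch.
#' @export
tensorize_epochs <- function(epochs, labels, resample_hz = NULL, cutoff_hz = 7,
                             order = 5, window_s = 0.5, step_s = 0.1,
                             wavelet = wavelet_spec()) {
  stopifnot(length(epochs) == length(labels))
  trials <- list()
  lab_out <- integer(0)
  grp_out <- character(0)
  for (e in seq_along(epochs)) {
    ep <- epochs[[e]]
    if (!is.null(resample_hz)) ep <- eeg_resample(ep, resample_hz)
    if (!is.null(cutoff_hz)) ep <- eeg_lowpass(ep, cutoff_hz, order)
    wins <- sliding_windows(ep, window_s, step_s)
    for (w in wins) {
      trials[[length(trials) + 1]] <-
        if (is.null(wavelet)) w$samples else cwt_tensorize(w, wavelet)
      lab_out <- c(lab_out, labels[e])
      grp_out <- c(grp_out, sprintf("epoch%04d", e))
    }
  }
  trial_set(trials, lab_out, groups = grp_out)
}
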