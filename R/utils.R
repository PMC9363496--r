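# Internal numeric helpers shared across modules.

# package-local memoization store (mel filterbanks etc.)
.fin_cache <- new.env(parent = emptyenv())

# Run `expr` under a given RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Periodic Hann window
#'
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @keywords internal
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

#' Fourier-method resampling
#'
#' Resamples a signal to a new length by truncating or zero-padding its
#' discrete Fourier spectrum, the same scheme used for band-limited
#' downsampling of hydrophone recordings before detection.
#'
#' @param x Numeric vector (mono waveform).
#' @param n_out Desired output length in samples.
#' @return Numeric vector of length `n_out`.
#' @export
resample_fourier <- function(x, n_out) {
  n_in <- length(x)
  stopifnot(n_in > 0, n_out > 0)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(real = rep(0, n_out))
  # number of positive-frequency bins to keep (excluding DC)
  nk <- min(n_in, n_out)
  half <- nk %/% 2
  Y[1] <- X[1]
  if (half >= 1) {
    idx <- seq_len(half)
    Y[1 + idx] <- X[1 + idx]
    Y[n_out + 1 - idx] <- X[n_in + 1 - idx]
  }
  if (nk %% 2 == 0 && half >= 1) {
    # split the shared Nyquist bin symmetrically
    if (n_out < n_in) {
      nyq <- X[1 + half] + X[n_in + 1 - half]
      Y[1 + half] <- nyq / 2
      Y[n_out + 1 - half] <- nyq / 2
    } else {
      Y[1 + half] <- X[1 + half] / 2
      Y[n_out + 1 - half] <- X[1 + half] / 2
    }
  }
  # inverse DFT carries 1/n_out; amplitude preservation multiplies by
  # n_out/n_in, leaving an overall 1/n_in
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

# Short-time Fourier transform power matrix.
# Centered frames, reflection padding, `hop` samples between frames.
# Returns list(power = [n_bins x n_frames], freq, time) where power is
# |FFT|^2 of the Hann-windowed frame zero-padded to `n_fft`.
stft_power <- function(x, sr, win_length, n_fft, hop) {
  stopifnot(length(x) >= 1, n_fft >= win_length)
  n <- length(x)
  n_frames <- ceiling(n / hop)
  centers <- (seq_len(n_frames) - 1) * hop + 1
  half <- win_length %/% 2
  # reflection of out-of-range sample indices (repeated until in range)
  reflect <- function(i) {
    while (any(bad <- i < 1 | i > n)) {
      i[i < 1] <- 2 - i[i < 1]
      i[i > n] <- 2 * n - i[i > n]
      if (n == 1) i[bad] <- 1
    }
    i
  }
  w <- hann_window(win_length)
  idx <- reflect(outer(seq_len(win_length) - 1, centers - half, `+`))
  frames <- matrix(0, nrow = n_fft, ncol = n_frames)
  frames[seq_len(win_length), ] <- x[idx] * w
  spec <- stats::mvfft(frames)
  n_bins <- n_fft %/% 2 + 1
  power <- abs(spec[seq_len(n_bins), , drop = FALSE])^2
  list(power = power,
       freq = (seq_len(n_bins) - 1) * sr / n_fft,
       time = (centers - 1) / sr)
}

# Band-limited power of a waveform via FFT masking, optionally restricted to
# a support index set. Used by the SNR mixing convention (15-25 Hz band).
band_power <- function(x, sr, band, support = NULL) {
  n <- length(x)
  f <- (seq_len(n) - 1) * sr / n
  f <- pmin(f, sr - f)
  X <- stats::fft(x)
  X[f < band[1] | f > band[2]] <- 0
  xb <- Re(stats::fft(X, inverse = TRUE)) / n
  if (!is.null(support)) xb <- xb[support]
  mean(xb^2)
}

is_sorted <- function(x) !is.unsorted(x, strictly = FALSE)
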