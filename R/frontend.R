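# Spectrogram frontend for the pulse detector: Fourier resampling to
# 200 Hz, mel power spectrogram, and trainable log compression.

#' Frontend configuration
#'
#' Geometry of the detector's mel-spectrogram frontend. With the defaults
#' the output frame rate is `target_rate / hop` = 6.25 Hz.
#'
#' @param target_rate Working sampling rate (Hz).
#' @param fft_size FFT length in samples.
#' @param hop Hop size in samples.
#' @param n_mels Number of mel bands.
#' @param f_range Frequency range covered by the filterbank (Hz).
#' @return A `fin_frontend_config` list.
#' @export
frontend_config <- function(target_rate = 200, fft_size = 256, hop = 32,
                            n_mels = 128, f_range = c(0, 100)) {
  stopifnot(target_rate > 0, fft_size > 0, hop > 0, n_mels > 1,
            f_range[2] <= target_rate / 2)
  structure(list(target_rate = target_rate, fft_size = fft_size, hop = hop,
                 n_mels = n_mels, f_range = f_range,
                 frame_rate = target_rate / hop),
            class = "fin_frontend_config")
}

#' Preprocess a waveform for detection
#'
#' Resamples to the target rate by the Fourier method and standardizes to
#' zero mean and unit variance (reducing sensitivity to absolute sound
#' exposure level).
#'
#' @param waveform Numeric mono waveform.
#' @param native_rate Its sampling rate in Hz (>= target rate).
#' @param target_rate Output rate in Hz.
#' @return Waveform at `target_rate`, standardized.
#' @export
preprocess <- function(waveform, native_rate, target_rate = 200) {
  stopifnot(native_rate >= target_rate, length(waveform) > 1)
  if (stats::sd(waveform) == 0) stop("constant (zero-variance) input")
  if (native_rate != target_rate) {
    n_out <- round(length(waveform) * target_rate / native_rate)
    waveform <- resample_fourier(waveform, n_out)
  }
  (waveform - mean(waveform)) / stats::sd(waveform)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank
#'
#' HTK-style triangular filters on the mel scale, evaluated at the FFT bin
#' frequencies.
#'
#' @param cfg A [frontend_config()].
#' @return Matrix `[n_mels x (fft_size/2 + 1)]`.
#' @export
mel_filterbank <- function(cfg) {
  key <- paste(cfg$target_rate, cfg$fft_size, cfg$n_mels,
               cfg$f_range[1], cfg$f_range[2], sep = "|")
  cached <- .fin_cache[[key]]
  if (!is.null(cached)) return(cached)
  n_bins <- cfg$fft_size %/% 2 + 1
  f_bins <- (seq_len(n_bins) - 1) * cfg$target_rate / cfg$fft_size
  m_pts <- seq(hz_to_mel(cfg$f_range[1]), hz_to_mel(cfg$f_range[2]),
               length.out = cfg$n_mels + 2)
  f_pts <- mel_to_hz(m_pts)
  fb <- matrix(0, nrow = cfg$n_mels, ncol = n_bins)
  for (i in seq_len(cfg$n_mels)) {
    lo <- f_pts[i]; ce <- f_pts[i + 1]; hi <- f_pts[i + 2]
    up <- (f_bins - lo) / max(ce - lo, 1e-12)
    dn <- (hi - f_bins) / max(hi - ce, 1e-12)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  .fin_cache[[key]] <- fb
  fb
}

#' Mel power spectrogram
#'
#' Hann-windowed STFT power mapped through the mel filterbank. Frames are
#' centered with reflection padding, so the number of frames is
#' `ceiling(n / hop)` and frame times are window centers.
#'
#' @param waveform Waveform at the frontend's target rate.
#' @param cfg A [frontend_config()].
#' @return List: `mel` matrix `[n_mels x T]`, `time` frame centers (s),
#'   `frame_rate` (Hz).
#' @export
mel_spectrogram <- function(waveform, cfg = frontend_config()) {
  if (length(waveform) < cfg$fft_size) {
    stop("input shorter than one FFT window")
  }
  st <- stft_power(waveform, cfg$target_rate, win_length = cfg$fft_size,
                   n_fft = cfg$fft_size, hop = cfg$hop)
  fb <- mel_filterbank(cfg)
  list(mel = fb %*% st$power, time = st$time, frame_rate = cfg$frame_rate)
}

#' Trainable log compression
#'
#' Elementwise `log10(1 + x * 10^a)`; `a` is a trainable scalar of the
#' detection model. Strictly monotone in `x` and maps 0 to 0 for every `a`.
#'
#' @param x Non-negative matrix (mel powers).
#' @param a Compression exponent.
#' @return Compressed matrix.
#' @export
compress <- function(x, a) {
  stopifnot(all(x >= 0))
  log10(1 + x * 10^a)
}
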