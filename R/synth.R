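# Synthetic fin-whale song generation: 20 Hz chirp pulses in brown noise,
# bi-gram-dependent inter-pulse intervals, and long-term pulse-record
# datasets with implanted trends.

#' Pulse model
#'
#' Describes one of the two Mediterranean 20 Hz pulse categories as a
#' Hann-enveloped linear chirp. Type A (the "classic" 20 Hz pulse, higher
#' pitched) is a downsweep; type B (the "back-beat") is nearly flat and
#' lower in frequency. The defaults place the two center-frequency modes
#' (~20.55 and ~19.35 Hz) on either side of the ~20 Hz type boundary, and
#' deliberately mid-bin on the 0.1 Hz trend-quantization grid: a center
#' sitting exactly on a bin edge would make the modal bin of a
#' zero-trend month an unstable coin flip, a degeneracy real pulse
#' populations do not have.
#'
#' @param type_label `"A"` or `"B"` selects a default model.
#' @param f_start,f_end Chirp start and end frequencies in Hz
#'   (`10 <= f_end <= f_start <= 30`).
#' @param duration Pulse duration in seconds.
#' @return A `fin_pulse_model` list.
#' @export
pulse_model <- function(type_label = c("A", "B"), f_start = NULL,
                        f_end = NULL, duration = NULL) {
  type_label <- match.arg(type_label)
  def <- if (type_label == "A") {
    list(f_start = 23.05, f_end = 18.05, duration = 0.8)
  } else {
    list(f_start = 19.85, f_end = 18.85, duration = 1.0)
  }
  m <- list(type_label = type_label,
            f_start = if (is.null(f_start)) def$f_start else f_start,
            f_end = if (is.null(f_end)) def$f_end else f_end,
            duration = if (is.null(duration)) def$duration else duration,
            amplitude_envelope = "hann")
  if (m$duration <= 0) stop("pulse duration must be positive")
  if (!(10 <= m$f_end && m$f_end <= m$f_start && m$f_start <= 30)) {
    stop("pulse frequencies must satisfy 10 <= f_end <= f_start <= 30 Hz")
  }
  structure(m, class = "fin_pulse_model")
}

#' Synthesize one pulse waveform
#'
#' Renders a pulse model as a unit-peak, Hann-windowed linear chirp.
#'
#' @param model A [pulse_model()].
#' @param sampling_rate Output rate in Hz; must be at least twice `f_start`.
#' @return Numeric waveform of `round(duration * sampling_rate)` samples.
#' @export
synth_pulse <- function(model, sampling_rate) {
  stopifnot(inherits(model, "fin_pulse_model"))
  if (model$duration <= 0) stop("pulse duration must be positive")
  if (sampling_rate < 2 * model$f_start) {
    stop("sampling_rate below the Nyquist requirement (2 * f_start)")
  }
  n <- round(model$duration * sampling_rate)
  if (n < 2) stop("pulse duration too short for this sampling rate")
  t <- (seq_len(n) - 1) / sampling_rate
  sweep_rate <- (model$f_end - model$f_start) / model$duration
  phase <- 2 * pi * (model$f_start * t + 0.5 * sweep_rate * t^2)
  w <- sin(phase) * hann_window(n)
  w / max(abs(w))
}

#' Reference center frequency of a pulse model
#'
#' Measures the -6 dB (quarter-maximum power) mid-point frequency of a clean
#' rendered pulse from a densely zero-padded periodogram. Used as the
#' ground-truth center frequency in synthetic tables; deliberately
#' independent of the spectro-temporal analysis path.
#'
#' @param model A [pulse_model()].
#' @param sampling_rate Rendering rate in Hz.
#' @return Center frequency in Hz.
#' @export
model_center_frequency <- function(model, sampling_rate = 1000) {
  w <- synth_pulse(model, sampling_rate)
  n_fft <- 2^ceiling(log2(length(w) * 64))
  spec <- abs(stats::fft(c(w, rep(0, n_fft - length(w)))))^2
  n_bins <- n_fft %/% 2 + 1
  E <- spec[seq_len(n_bins)]
  f <- (seq_len(n_bins) - 1) * sampling_rate / n_fft
  qm <- quarter_max_boundaries(E, f)
  (qm$left + qm$right) / 2
}

# Quarter-maximum (-6 dB in power) boundary search with linear
# interpolation, used both by the generator's reference measurement and by
# the pulse-analysis module.
quarter_max_boundaries <- function(E, f) {
  stopifnot(length(E) == length(f))
  peak <- which.max(E)
  thr <- E[peak] / 4
  if (!is.finite(thr) || thr <= 0) {
    return(list(left = NA_real_, right = NA_real_, valid = FALSE))
  }
  left <- NA_real_
  for (i in seq(peak - 1, 1)) {
    if (peak == 1) break
    if (E[i] < thr) {
      left <- f[i] + (thr - E[i]) / (E[i + 1] - E[i]) * (f[i + 1] - f[i])
      break
    }
  }
  right <- NA_real_
  n <- length(E)
  for (i in seq(peak + 1, n)) {
    if (peak == n) break
    if (E[i] < thr) {
      right <- f[i - 1] +
        (E[i - 1] - thr) / (E[i - 1] - E[i]) * (f[i] - f[i - 1])
      break
    }
  }
  list(left = left, right = right, valid = is.finite(left) && is.finite(right))
}

#' Brown-noise generator
#'
#' Zero-mean noise with a ~6 dB/octave falling power spectral density,
#' approximating sea ambient noise. Built as the cumulative sum of seeded
#' white Gaussian noise, first-order high-passed at 1 Hz to remove drift,
#' then standardized to unit variance.
#'
#' @param n_samples Number of samples (> 0).
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Optional integer seed; the same seed reproduces the noise.
#' @return Numeric waveform, mean ~0, variance 1.
#' @export
brown_noise <- function(n_samples, sampling_rate, seed = NULL) {
  stopifnot(n_samples > 0)
  x <- with_seed(seed, stats::rnorm(n_samples))
  b <- cumsum(x)
  key <- paste0("hp1|", sampling_rate)
  hp <- .fin_cache[[key]]
  if (is.null(hp)) {
    hp <- signal::butter(1, min(1 / (sampling_rate / 2), 0.99),
                         type = "high")
    .fin_cache[[key]] <- hp
  }
  # first-order IIR applied as FIR numerator + recursive denominator
  b <- stats::filter(b, hp$b, method = "convolution", sides = 1)
  b[is.na(b)] <- 0
  b <- as.numeric(stats::filter(b, -hp$a[-1], method = "recursive"))
  b <- b - mean(b)
  b / stats::sd(b)
}

#' Mix signal and noise at a target SNR
#'
#' Scales the noise so that the band-limited (15-25 Hz) power ratio between
#' signal and noise, measured over the signal's support (samples where the
#' signal is non-zero), equals `snr_db`. The band matches the band used by
#' the pulse SNR measurement, so synthesis SNR and measured SNR are
#' comparable.
#'
#' @param signal,noise Equal-length waveforms.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Measurement band in Hz.
#' @return `signal + scaled noise`.
#' @export
mix_at_snr <- function(signal, noise, snr_db, sampling_rate,
                       band = c(15, 25)) {
  stopifnot(length(signal) == length(noise), is.finite(snr_db))
  support <- which(abs(signal) > 1e-12)
  if (length(support) == 0) stop("signal has empty support")
  p_sig <- band_power(signal, sampling_rate, band, support)
  p_noise <- band_power(noise, sampling_rate, band, support)
  if (p_noise <= 0) stop("noise has zero power in the measurement band")
  scale <- sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
  signal + scale * noise
}

#' Synthesis configuration
#'
#' Parameters of the synthetic song generator. IPI means are anchored to the
#' 14.9 s interval reported for this population around 2008: the AB interval
#' is 2 s longer than AA/BA and BB is 11 s longer.
#'
#' @param sampling_rate Audio rate in Hz.
#' @param bigram_ipi_table Named mean IPIs (s) for AA, AB, BA, BB at
#'   `epoch_year`.
#' @param ipi_jitter_sd Gaussian IPI jitter sd (s), truncated so IPIs stay
#'   in (11, 45).
#' @param ipi_drift Linear IPI drift in s/year applied to every bi-gram.
#' @param cf_monthly_slope Intra-annual center-frequency slope in Hz/month
#'   over the August-to-February song season.
#' @param cf_jitter_sd Gaussian scatter of center frequencies (Hz).
#' @param snr_db Band-limited SNR of the mixed audio in dB.
#' @param transition First-order type transition matrix (rows A, B; row sums
#'   1).
#' @param epoch_year Year at which the IPI table applies.
#' @param seed Integer seed for all generator randomness.
#' @return A `fin_synth_config` list.
#' @export
synthesis_config <- function(sampling_rate = 200,
                             bigram_ipi_table = c(AA = 14.9, AB = 16.9,
                                                  BA = 14.9, BB = 25.9),
                             ipi_jitter_sd = 0.3,
                             ipi_drift = 0.1,
                             cf_monthly_slope = -0.1,
                             cf_jitter_sd = 0.2,
                             snr_db = 12,
                             transition = matrix(c(0.85, 0.15, 0.85, 0.15),
                                                 2, 2, byrow = TRUE,
                                                 dimnames = list(c("A", "B"),
                                                                 c("A", "B"))),
                             epoch_year = 2008,
                             seed = 1L) {
  stopifnot(all(bigram_ipi_table > 11), all(bigram_ipi_table < 45),
            all(c("AA", "AB", "BA", "BB") %in% names(bigram_ipi_table)),
            is.finite(snr_db), nrow(transition) == 2, ncol(transition) == 2,
            all(abs(rowSums(transition) - 1) < 1e-8), all(transition >= 0))
  structure(list(sampling_rate = sampling_rate,
                 bigram_ipi_table = bigram_ipi_table,
                 ipi_jitter_sd = ipi_jitter_sd,
                 ipi_drift = ipi_drift,
                 cf_monthly_slope = cf_monthly_slope,
                 cf_jitter_sd = cf_jitter_sd,
                 snr_db = snr_db,
                 transition = transition,
                 epoch_year = epoch_year,
                 seed = as.integer(seed),
                 models = list(A = pulse_model("A"), B = pulse_model("B"))),
            class = "fin_synth_config")
}

# sample an IPI for a bi-gram: Gaussian jitter truncated to (11, 45) s
sample_ipi <- function(mean_ipi, jitter_sd) {
  if (jitter_sd <= 0) return(mean_ipi)
  for (i in 1:100) {
    v <- mean_ipi + stats::rnorm(1, 0, jitter_sd)
    if (v > 11 && v < 45) return(v)
  }
  min(max(mean_ipi, 11 + 1e-6), 45 - 1e-6)
}

sample_type_chain <- function(n, transition) {
  p <- c(0.5, 0.5)
  for (i in 1:50) p <- as.numeric(p %*% transition)
  types <- character(n)
  types[1] <- sample(c("A", "B"), 1, prob = p)
  for (i in seq_len(n - 1)) {
    types[i + 1] <- sample(c("A", "B"), 1, prob = transition[types[i], ])
  }
  types
}

#' Synthesize a song with ground truth
#'
#' Places pulses by sampling the type chain and the bi-gram IPI table (plus
#' truncated Gaussian jitter), then mixes the pulse track into brown noise
#' at the configured SNR.
#'
#' @param config A [synthesis_config()].
#' @param duration Song duration in seconds; must fit at least two pulses.
#' @return A `fin_song` list: `waveform`, `sampling_rate`, and
#'   `ground_truth` (data frame with `onset_s`, `type`, `cf_hz`, `ipi_s`).
#' @export
synth_song <- function(config, duration) {
  stopifnot(inherits(config, "fin_synth_config"))
  sr <- config$sampling_rate
  margin <- 4.5
  with_seed(config$seed, {
    max_dur <- max(vapply(config$models, `[[`, 0, "duration"))
    onsets <- margin
    types <- sample_type_chain(1, config$transition)
    repeat {
      nxt <- sample(c("A", "B"), 1,
                    prob = config$transition[types[length(types)], ])
      bg <- paste0(types[length(types)], nxt)
      ipi <- sample_ipi(config$bigram_ipi_table[[bg]], config$ipi_jitter_sd)
      cand <- onsets[length(onsets)] + ipi
      if (cand + max_dur + margin > duration) break
      onsets <- c(onsets, cand)
      types <- c(types, nxt)
    }
    if (length(onsets) < 2) {
      stop("duration too short to place at least two pulses")
    }
    n <- round(duration * sr)
    sig <- numeric(n)
    centers <- vapply(config$models, model_center_frequency, 0,
                      sampling_rate = max(sr, 500))
    for (i in seq_along(onsets)) {
      pw <- synth_pulse(config$models[[types[i]]], sr)
      i0 <- round(onsets[i] * sr) + 1
      idx <- i0:(i0 + length(pw) - 1)
      keep <- idx <= n
      sig[idx[keep]] <- sig[idx[keep]] + pw[keep]
    }
    noise <- brown_noise(n, sr)
    audio <- mix_at_snr(sig, noise, config$snr_db, sr)
    gt <- data.frame(onset_s = onsets,
                     type = types,
                     cf_hz = as.numeric(centers[types]),
                     ipi_s = c(diff(onsets), NA_real_),
                     stringsAsFactors = FALSE)
    structure(list(waveform = audio, sampling_rate = sr, ground_truth = gt),
              class = "fin_song")
  })
}

#' Synthesize a multi-year pulse-record dataset
#'
#' Emits pulse records (no audio) across `n_years` song seasons
#' (August-February), with bi-gram IPI means drifting linearly at
#' `config$ipi_drift` (s/year, anchored at `config$epoch_year`) and center
#' frequencies following `config$cf_monthly_slope` within each season, with
#' Gaussian scatter. Intended as input to the trend analyses.
#'
#' @param config A [synthesis_config()].
#' @param start_year First calendar year.
#' @param n_years Number of years (>= 1).
#' @param pulses_per_month Approximate pulses generated per active month.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param seq_length Pulses per generated sequence.
#' @return Data frame of pulse records: `datetime`, `type`, `cf_hz`,
#'   `bw_hz`, `snr_db`, `ipi_s`, `seq_id`, `bigram`.
#' @export
synth_longterm_dataset <- function(config, start_year, n_years,
                                   pulses_per_month, seed = config$seed,
                                   seq_length = 20) {
  stopifnot(inherits(config, "fin_synth_config"), n_years >= 1)
  empty <- data.frame(datetime = as.POSIXct(character(), tz = "UTC"),
                      type = character(), cf_hz = numeric(),
                      bw_hz = numeric(), snr_db = numeric(),
                      ipi_s = numeric(), seq_id = integer(),
                      bigram = character(), stringsAsFactors = FALSE)
  if (pulses_per_month <= 0) return(empty)
  season_months <- c(8, 9, 10, 11, 12, 1, 2) # August -> February
  centers <- vapply(config$models, model_center_frequency, 0)
  with_seed(seed, {
    out <- list()
    seq_id <- 0L
    for (yi in seq_len(n_years) - 1L) {
      for (mi in seq_along(season_months)) {
        month <- season_months[mi]
        year <- start_year + yi + (mi > 5) # Jan/Feb spill into the next year
        n_seq <- max(1L, round(pulses_per_month / seq_length))
        for (s in seq_len(n_seq)) {
          seq_id <- seq_id + 1L
          n_p <- seq_length
          day <- sample(1:28, 1)
          t0 <- ISOdatetime(year, month, day, sample(0:23, 1),
                            sample(0:59, 1), 0, tz = "UTC")
          year_frac <- year + (month - 0.5) / 12
          drift <- config$ipi_drift * (year_frac - config$epoch_year)
          types <- sample_type_chain(n_p, config$transition)
          ipis <- numeric(n_p - 1)
          for (i in seq_len(n_p - 1)) {
            bg <- paste0(types[i], types[i + 1])
            ipis[i] <- sample_ipi(config$bigram_ipi_table[[bg]] + drift,
                                  config$ipi_jitter_sd)
          }
          t_rel <- c(0, cumsum(ipis))
          cf <- centers[types] + config$cf_monthly_slope * (mi - 1) +
            stats::rnorm(n_p, 0, config$cf_jitter_sd)
          out[[seq_id]] <- data.frame(
            datetime = t0 + t_rel,
            type = types,
            cf_hz = as.numeric(cf),
            bw_hz = stats::rnorm(n_p, 3.5, 0.4),
            snr_db = stats::rnorm(n_p, 12, 1.5),
            ipi_s = c(ipis, NA_real_),
            seq_id = seq_id,
            bigram = c(paste0(types[-n_p], types[-1]), NA_character_),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Generate labelled training segments
#'
#' Renders 5 s detector-training examples at the frontend rate: positives
#' contain one pulse (random type, random placement) mixed into brown noise
#' at a band SNR drawn uniformly from `snr_range`; negatives are brown
#' noise alone. Segments are standardized like [preprocess()] output.
#'
#' @param config A [synthesis_config()].
#' @param n_pos,n_neg Number of positive / negative segments.
#' @param seed Integer seed.
#' @param window_s Segment length in seconds.
#' @param snr_range Band SNR range (dB) for the positives.
#' @return List: `segments` (list of waveforms), `labels` (0/1 vector).
#' @export
synth_training_segments <- function(config, n_pos, n_neg,
                                    seed = config$seed, window_s = 5,
                                    snr_range = c(3, 15)) {
  stopifnot(inherits(config, "fin_synth_config"))
  sr <- config$sampling_rate
  n <- round(window_s * sr)
  with_seed(seed, {
    segs <- vector("list", n_pos + n_neg)
    for (i in seq_len(n_pos)) {
      type <- sample(c("A", "B"), 1)
      pw <- synth_pulse(config$models[[type]], sr)
      sig <- numeric(n)
      i0 <- sample.int(n - length(pw), 1)
      sig[i0:(i0 + length(pw) - 1)] <- pw
      snr <- stats::runif(1, snr_range[1], snr_range[2])
      seg <- mix_at_snr(sig, brown_noise(n, sr), snr, sr)
      segs[[i]] <- (seg - mean(seg)) / stats::sd(seg)
    }
    for (i in seq_len(n_neg)) {
      seg <- brown_noise(n, sr)
      segs[[n_pos + i]] <- (seg - mean(seg)) / stats::sd(seg)
    }
    list(segments = segs, labels = c(rep(1L, n_pos), rep(0L, n_neg)))
  })
}
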