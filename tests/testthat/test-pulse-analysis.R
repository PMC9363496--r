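# Spectro-temporal pulse measurement: analysis window, high-resolution
# spectrogram, precise time / envelope / SNR, bandwidth and frequency
# metrics.

test_that("analysis window band-passes and resamples to 2000 samples", {
  t <- (0:4799) / 200
  tone20 <- sin(2 * pi * 20 * t)
  win <- extract_window(tone20, 200, 12)
  expect_equal(length(win$waveform), 2000)
  expect_equal(win$rate, 250)
  expect_false(win$edge_padded)
  # 20 Hz passband center: gain ~ 1
  expect_equal(stats::sd(win$waveform), stats::sd(tone20), tolerance = 0.05)
  # 5 Hz: attenuated > 20 dB (zero-phase doubles the order-3 roll-off)
  tone5 <- sin(2 * pi * 5 * t)
  win5 <- extract_window(tone5, 200, 12)
  atten_db <- 20 * log10(stats::sd(tone5) / stats::sd(win5$waveform))
  expect_gt(atten_db, 20)
  # edge handling: reflection padding with a flag
  expect_true(extract_window(tone20, 200, 1)$edge_padded)
})

test_that("analysis spectrogram has ~0.24 Hz and ~0.03 s resolution", {
  x <- sin(2 * pi * 20 * (0:4799) / 200)
  S <- analysis_spectrogram(extract_window(x, 200, 12))
  expect_equal(round(S$df, 2), 0.24)
  expect_equal(round(S$dt, 2), 0.03)
  # stationary tone: every column peaks at the bin nearest 20 Hz
  target <- which.min(abs(S$freq - 20))
  inner <- 10:(ncol(S$power) - 10)
  expect_true(all(apply(S$power[, inner], 2, which.max) == target))
  # column profile is essentially time-constant away from the zero-phase
  # filter's edge transients (~0.5 s each side)
  core <- which(S$time > 1 & S$time < 7)
  peak_row <- S$power[target, core]
  expect_lt(diff(range(peak_row)) / max(peak_row), 0.05)
})

test_that("precise time, envelope and SNR match brute-force evaluation", {
  # pointwise cases
  f <- seq(10, 30, by = 0.25)
  tt <- seq(0, 8, by = 0.05)
  M <- matrix(0, length(f), length(tt))
  M[f == 20, tt == 3] <- 5
  S <- make_spec(M, f, tt)
  expect_equal(estimate_time(S), 3)
  # out-of-band energy is ignored
  M2 <- M; M2[f == 25, tt == 6] <- 50
  expect_equal(estimate_time(make_spec(M2, f, tt)), 3)
  # time-constant spectrogram: envelope identically zero
  M3 <- matrix(rep(stats::runif(length(f)), length(tt)), length(f))
  S3 <- make_spec(M3, f, tt)
  expect_equal(spectral_envelope(S3, 4), numeric(length(f)))
  # random matrices against the brute-force oracles
  for (seed in 1:20) {
    S <- rand_spec(seed)
    th <- estimate_time(S)
    expect_equal(th, oracle_time(S))
    E <- spectral_envelope(S, th)
    expect_equal(E, oracle_envelope(S, th))
    snr <- estimate_snr(S, E, th)
    expect_equal(snr$snr_db, oracle_snr(S, E, th))
  }
  # simple SNR ratios
  expect_equal(10 * log10(1), 0)
  S4 <- rand_spec(99)
  th4 <- estimate_time(S4)
  E4 <- spectral_envelope(S4, th4)
  out <- estimate_snr(S4, E4, th4)
  expect_equal(out$snr_db,
               10 * log10(out$e_pulse / out$e_background))
})

test_that("background subtraction removes any time-constant component", {
  # at a given pulse time, E(f) = max - median cancels any B(f) added to
  # every column
  S <- rand_spec(7)
  th <- estimate_time(S)
  E1 <- spectral_envelope(S, th)
  B <- stats::runif(length(S$freq), 0, 5)
  S2 <- make_spec(S$power + B, S$freq, S$time)
  E2 <- spectral_envelope(S2, th)
  expect_equal(E2, E1, tolerance = 1e-12)
})

test_that("quarter-max bandwidth matches triangular and Gaussian closed forms", {
  f <- seq(10, 30, by = 0.05)
  # triangle peaking at 20, zero at 18 and 22: crossings 18.5 / 21.5
  E <- pmax(0, 1 - abs(f - 20) / 2)
  m <- measure_bandwidth_center(E, f)
  expect_equal(m$center_frequency, 20, tolerance = 1e-9)
  expect_equal(m$bandwidth, 3, tolerance = 1e-9)
  # rectangle on [18, 22]
  Er <- as.numeric(f >= 18 & f <= 22)
  mr <- measure_bandwidth_center(Er, f)
  expect_equal(mr$center_frequency, 20, tolerance = 0.1)
  expect_equal(mr$bandwidth, 4, tolerance = 2 * 0.05)
  # Gaussian of sd sigma: width 2*sigma*sqrt(2 ln 4)
  for (sigma in c(0.5, 1, 1.5)) {
    Eg <- exp(-(f - 20)^2 / (2 * sigma^2))
    mg <- measure_bandwidth_center(Eg, f)
    expect_equal(mg$bandwidth, 2 * sigma * sqrt(2 * log(4)),
                 tolerance = 0.05)
    expect_equal(mg$center_frequency, 20, tolerance = 0.05)
  }
  # envelope never crossing the threshold: flagged invalid
  expect_false(measure_bandwidth_center(rep(1, length(f)), f)$valid)
})

test_that("SNR estimates scale linearly with the synthesis SNR", {
  # Eq. 3 measures peak-bin over median-bin power, which sits a constant
  # spectral-concentration gain above the band-power synthesis SNR; the
  # recovered *differences* must track the implanted differences
  est <- vapply(c(5, 10, 15), function(s) {
    vals <- vapply(1:5, function(r) {
      set.seed(1000 * s + r)
      pw <- synth_pulse(pulse_model("A"), 200)
      sig <- numeric(200 * 12)
      sig[1201:(1200 + length(pw))] <- pw
      x <- mix_at_snr(sig, brown_noise(length(sig), 200), s, 200)
      analyze_pulse(x, 200, 6.4)$snr_db
    }, 0)
    mean(vals)
  }, 0)
  expect_equal(est[2] - est[1], 5, tolerance = 3)
  expect_equal(est[3] - est[1], 10, tolerance = 3)
  expect_true(all(diff(est) > 0))
})

test_that("frequency metrics order correctly and match hand computation", {
  f <- seq(15, 25, by = 0.5)
  # symmetric envelope: peak = center = centroid
  Es <- exp(-(f - 20)^2 / 2)
  m <- choose_frequency_metric(Es, f)
  expect_equal(m$peak, 20)
  expect_equal(m$center, 20, tolerance = 0.01)
  expect_equal(m$centroid, 20, tolerance = 0.01)
  # right-skewed envelope: centroid above peak
  Ek <- stats::dgamma(f - 17, shape = 2, rate = 1.2)
  mk <- choose_frequency_metric(Ek, f)
  expect_gt(mk$centroid, mk$peak)
  # 5-bin hand computation
  f5 <- c(18, 19, 20, 21, 22)
  E5 <- c(1, 3, 5, 3, 2)
  m5 <- choose_frequency_metric(E5, f5)
  expect_equal(m5$centroid, sum(f5 * E5) / sum(E5))
  expect_equal(m5$peak, 20)
})
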