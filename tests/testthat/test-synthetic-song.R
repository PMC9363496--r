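# Synthetic song generator: pulses, noise, SNR mixing, songs, long-term
# datasets.

test_that("synth_pulse renders windowed chirps and rejects bad input", {
  # constant-frequency case: spectral peak at 20 Hz
  tone <- synth_pulse(pulse_model("A", f_start = 20, f_end = 20,
                                  duration = 1), 200)
  expect_equal(length(tone), 200)
  expect_equal(max(abs(tone)), 1)
  spec <- abs(stats::fft(c(tone, rep(0, 1848))))^2
  f <- (0:1023) * 200 / 2048
  expect_lt(abs(f[which.max(spec[1:1024])] - 20), 0.2)

  expect_error(pulse_model("A", duration = 0), "positive")
  expect_error(synth_pulse(pulse_model("A"), 30), "Nyquist")
})

test_that("type-A downsweep center frequency matches the dense-FFT oracle", {
  # oracle: periodogram of the known chirp, quarter-max midpoint by hand
  pm <- pulse_model("A")
  w <- synth_pulse(pm, 1000)
  n_fft <- 2^18
  spec <- abs(stats::fft(c(w, rep(0, n_fft - length(w)))))^2
  E <- spec[1:(n_fft / 2)]
  f <- (0:(n_fft / 2 - 1)) * 1000 / n_fft
  thr <- max(E) / 4
  pk <- which.max(E)
  li <- max(which(E[1:pk] < thr))
  ri <- pk + min(which(E[(pk + 1):length(E)] < thr))
  lerp <- function(i, j) f[i] + (thr - E[i]) / (E[j] - E[i]) * (f[j] - f[i])
  oracle_center <- (lerp(li, li + 1) + lerp(ri, ri - 1)) / 2
  expect_lt(abs(model_center_frequency(pm) - oracle_center), 0.05)
  # envelope-weighted sweep center stays near the nominal mid-sweep value
  expect_lt(abs(oracle_center - (pm$f_start + pm$f_end) / 2), 0.3)
})

test_that("brown noise is seeded, unit variance, with ~ -6 dB/octave PSD", {
  b1 <- brown_noise(4000, 200, seed = 5)
  b2 <- brown_noise(4000, 200, seed = 5)
  expect_identical(b1, b2)
  expect_lt(abs(stats::var(b1) - 1), 0.01)
  expect_lt(abs(mean(b1)), 0.05)
  # Welch-style PSD slope over 5-50 Hz (smoothed periodogram oracle)
  b <- brown_noise(200 * 60, 200, seed = 6)
  sp <- stats::spec.pgram(stats::ts(b, frequency = 200), spans = 31,
                          plot = FALSE)
  sel <- sp$freq > 5 & sp$freq < 50
  slope_db_oct <- 10 * log10(2) *
    stats::coef(stats::lm(log2(sp$spec[sel]) ~ log2(sp$freq[sel])))[[2]]
  expect_gt(slope_db_oct, -8)
  expect_lt(slope_db_oct, -4)
})

test_that("mix_at_snr hits the requested band power ratio", {
  pw <- synth_pulse(pulse_model("A"), 200)
  sig <- numeric(2000)
  sig[501:(500 + length(pw))] <- pw
  noise <- brown_noise(2000, 200, seed = 7)
  support <- which(abs(sig) > 1e-12)
  bp <- function(x) finsong:::band_power(x, 200, c(15, 25), support)
  for (s in c(0, -3)) {
    mixed <- mix_at_snr(sig, noise, s, 200)
    ratio <- bp(sig) / bp(mixed - sig)
    expect_equal(10 * log10(ratio), s, tolerance = 1e-6)
  }
  # -3 dB: noise band power is 10^0.3 ~ 2x the signal band power
  mixed <- mix_at_snr(sig, noise, -3, 200)
  expect_equal(bp(mixed - sig) / bp(sig), 10^0.3, tolerance = 1e-6)
  # very large SNR: output ~ signal
  mixed <- mix_at_snr(sig, noise, 120, 200)
  expect_lt(max(abs(mixed - sig)), 1e-4)
  expect_error(mix_at_snr(sig, numeric(2000), 0, 200), "zero power")
})

test_that("deterministic type chain gives evenly spaced onsets", {
  tr <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  cfg <- synthesis_config(bigram_ipi_table = c(AA = 15, AB = 17, BA = 15,
                                               BB = 26),
                          ipi_jitter_sd = 0, transition = tr, seed = 3)
  song <- synth_song(cfg, 120)
  gt <- song$ground_truth
  expect_true(all(gt$type == "A"))
  expect_equal(diff(gt$onset_s), rep(15, nrow(gt) - 1))
  expect_equal(gt$ipi_s[-nrow(gt)], diff(gt$onset_s))
})

test_that("song generation is deterministic and IPIs follow the bi-gram table", {
  cfg <- synthesis_config(seed = 9)
  s1 <- synth_song(cfg, 30 * 60)
  s2 <- synth_song(cfg, 30 * 60)
  expect_identical(s1$waveform, s2$waveform)
  expect_identical(s1$ground_truth, s2$ground_truth)
  gt <- s1$ground_truth
  expect_gt(nrow(gt), 50)
  # every ground-truth IPI within 3 jitter sd of its bi-gram mean
  bg <- paste0(gt$type[-nrow(gt)], gt$type[-1])
  dev <- abs(gt$ipi_s[-nrow(gt)] - cfg$bigram_ipi_table[bg])
  expect_true(all(dev <= 3 * cfg$ipi_jitter_sd))
  expect_error(synth_song(cfg, 20), "two pulses")
})

test_that("long-term dataset implants drifts and honours degenerate inputs", {
  cfg <- synthesis_config(seed = 21, ipi_drift = 0, cf_monthly_slope = 0)
  expect_equal(nrow(synth_longterm_dataset(cfg, 2010, 1, 0)), 0)
  d <- synth_longterm_dataset(cfg, 2010, 3, 200, seed = 21)
  expect_identical(d, synth_longterm_dataset(cfg, 2010, 3, 200, seed = 21))
  # null trends: per-trimester modal IPIs constant across years (+-1 bin)
  bg <- d[!is.na(d$bigram), ]
  tr <- ipi_trend(bg, "AA")
  expect_gt(nrow(tr$points), 3)
  expect_lt(diff(range(tr$points$modal_value)), 0.1 + 1e-9)
  # implanted drift recovered (light 3-seed version; the full 20-seed
  # experiment runs in the acceptance suite)
  slopes <- vapply(1:3, function(s) {
    cfgd <- synthesis_config(seed = s, ipi_drift = 0.1)
    dd <- synth_longterm_dataset(cfgd, 2008, 10, 300, seed = s)
    ipi_trend(dd[!is.na(dd$bigram), ], "AA")$regression$slope
  }, 0)
  expect_true(all(abs(slopes - 0.1) <= 0.02))
})

test_that("full pipeline recovers >= 90% of pulses on 20-min songs at 12 dB", {
  fx <- get_detector_fixture()
  pc <- pipeline_config()
  for (rep in 1:5) {
    song <- synth_song(synthesis_config(seed = 200 + rep, snr_db = 12),
                       20 * 60)
    wf <- preprocess(song$waveform, song$sampling_rate)
    det <- detect(predict_frames(fx$model, wf), fx$balance$threshold)
    rows <- do.call(rbind, lapply(det$time, function(tt) {
      analyze_pulse(wf, song$sampling_rate, tt)
    }))
    rows <- filter_pulses(rows)
    gt <- song$ground_truth
    # ground-truth pulse energy peaks near mid-pulse
    ref <- gt$onset_s + 0.4
    hit <- vapply(seq_len(nrow(gt)), function(i) {
      j <- which.min(abs(rows$t_s - ref[i]))
      abs(rows$t_s[j] - ref[i]) <= 1 &&
        abs(rows$cf_hz[j] - gt$cf_hz[i]) <= 0.5
    }, logical(1))
    expect_gte(mean(hit), 0.9)
  }
})
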