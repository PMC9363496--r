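# Independent brute-force oracles for the spectro-temporal measurements,
# written as literal loops over the definitions; they share no code with
# the implementation.

# build a pulse-spectrogram object from an arbitrary power matrix
make_spec <- function(power, freq, time) {
  structure(list(power = power, freq = freq, time = time,
                 df = diff(freq[1:2]), dt = diff(time[1:2]), start_s = 0),
            class = "fin_pulse_spectrogram")
}

rand_spec <- function(seed) {
  set.seed(seed)
  f <- seq(10, 30, by = 0.25)
  t <- seq(0, 8, by = 0.05)
  make_spec(matrix(stats::rexp(length(f) * length(t)), length(f)), f, t)
}

# precise pulse time: column of the maximum in the 18-22 Hz band
oracle_time <- function(S) {
  best <- -Inf; best_col <- NA
  for (j in seq_along(S$time)) {
    for (i in seq_along(S$freq)) {
      if (S$freq[i] >= 18 && S$freq[i] <= 22 && S$power[i, j] > best) {
        best <- S$power[i, j]; best_col <- j
      }
    }
  }
  S$time[best_col]
}

# envelope: 1.2 s max-pool around t_hat minus per-bin median over all t
oracle_envelope <- function(S, t_hat) {
  E <- numeric(length(S$freq))
  for (i in seq_along(S$freq)) {
    mx <- -Inf
    for (j in seq_along(S$time)) {
      if (S$time[j] >= t_hat - 0.6 && S$time[j] <= t_hat + 0.6) {
        mx <- max(mx, S$power[i, j])
      }
    }
    E[i] <- mx - stats::median(S$power[i, ])
  }
  E
}

# SNR: max envelope over median of 15-25 Hz away from [t_hat-1, t_hat+3]
oracle_snr <- function(S, E, t_hat) {
  vals <- c()
  for (i in seq_along(S$freq)) {
    for (j in seq_along(S$time)) {
      if (S$freq[i] >= 15 && S$freq[i] <= 25 &&
          (S$time[j] < t_hat - 1 || S$time[j] > t_hat + 3)) {
        vals <- c(vals, S$power[i, j])
      }
    }
  }
  10 * log10(max(E) / stats::median(vals))
}
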