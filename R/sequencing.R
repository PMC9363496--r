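# Sequence/bout grouping and pre-analysis quality filters.
#
# Pulses closer than 45 s belong to the same sequence; sequences closer
# than 2 h belong to the same bout. Quality filters: pulses need a
# bandwidth below 6 Hz and a center frequency in [18.5, 22.5] Hz;
# sequences need a mean SNR of at least 8 dB, at least 3 pulses, and all
# IPIs within [11, 45] s (any violation discards the whole sequence).
# Pulse-level filters run first, then sequence formation, then
# sequence-level filters, so sequence IPIs reflect retained pulses.

#' Inter-pulse intervals
#'
#' Successive differences of time-sorted pulse times.
#'
#' @param times Numeric pulse times in seconds, sorted ascending.
#' @return Numeric IPIs (length `length(times) - 1`).
#' @export
compute_ipis <- function(times) {
  if (is.unsorted(times)) stop("pulse times must be sorted ascending")
  diff(times)
}

#' Group pulses into sequences
#'
#' Greedy single-pass split at gaps of 45 s or more (strictly "less than
#' 45 s" keeps pulses together).
#'
#' @param records Data frame of pulse records with a `t_s` time column (s).
#' @param max_gap Splitting gap in seconds.
#' @return `records` with a `seq_id` integer column appended.
#' @export
group_sequences <- function(records, max_gap = 45) {
  if (nrow(records) == 0) {
    records$seq_id <- integer(0)
    return(records)
  }
  if (is.unsorted(records$t_s)) stop("records must be time-sorted")
  gaps <- diff(records$t_s)
  records$seq_id <- cumsum(c(1L, as.integer(gaps >= max_gap)))
  records
}

#' Group sequences into bouts
#'
#' Sequences whose boundary gap (start of one minus end of the previous) is
#' less than 2 h share a bout.
#'
#' @param records Data frame with `t_s` and `seq_id` columns.
#' @param max_gap Splitting gap in seconds (default 2 h).
#' @return `records` with a `bout_id` integer column appended.
#' @export
group_bouts <- function(records, max_gap = 7200) {
  if (nrow(records) == 0) {
    records$bout_id <- integer(0)
    return(records)
  }
  seq_ids <- unique(records$seq_id)
  starts <- vapply(seq_ids, function(s) min(records$t_s[records$seq_id == s]), 0)
  ends <- vapply(seq_ids, function(s) max(records$t_s[records$seq_id == s]), 0)
  o <- order(starts)
  bout_of_seq <- integer(length(seq_ids))
  bout_of_seq[o] <- cumsum(c(1L, as.integer(
    starts[o][-1] - ends[o][-length(o)] >= max_gap)))
  records$bout_id <- bout_of_seq[match(records$seq_id, seq_ids)]
  records
}

#' Pulse-level quality filter
#'
#' Retains pulses with bandwidth strictly below 6 Hz and center frequency
#' within the closed interval [18.5, 22.5] Hz; invalid (flagged)
#' measurements are dropped.
#'
#' @param records Pulse records with `bw_hz` and `cf_hz` columns.
#' @param max_bw Bandwidth bound (exclusive), Hz.
#' @param cf_range Center-frequency range (inclusive), Hz.
#' @return Filtered records.
#' @export
filter_pulses <- function(records, max_bw = 6, cf_range = c(18.5, 22.5)) {
  keep <- is.finite(records$bw_hz) & is.finite(records$cf_hz) &
    records$bw_hz < max_bw &
    records$cf_hz >= cf_range[1] & records$cf_hz <= cf_range[2]
  if ("valid" %in% names(records)) keep <- keep & records$valid
  records[keep, , drop = FALSE]
}

#' Sequence-level quality filter
#'
#' Keeps a sequence only if its mean SNR is at least 8 dB, it has at least
#' 3 pulses, and every IPI lies within [11, 45] s; any violating IPI
#' discards the whole sequence. Mean SNR is the arithmetic mean of the
#' per-pulse dB values.
#'
#' @param records Pulse records with `t_s`, `snr_db` and `seq_id` columns.
#' @param min_snr Minimum mean SNR (dB, inclusive).
#' @param min_pulses Minimum pulses per sequence (inclusive).
#' @param ipi_range Allowed IPI range in seconds (inclusive).
#' @return Records of surviving sequences.
#' @export
filter_sequences <- function(records, min_snr = 8, min_pulses = 3,
                             ipi_range = c(11, 45)) {
  if (nrow(records) == 0) return(records)
  keep_seq <- vapply(unique(records$seq_id), function(s) {
    r <- records[records$seq_id == s, ]
    if (nrow(r) < min_pulses) return(FALSE)
    if (mean(r$snr_db) < min_snr) return(FALSE)
    ipis <- compute_ipis(sort(r$t_s))
    all(ipis >= ipi_range[1] & ipis <= ipi_range[2])
  }, logical(1))
  records[records$seq_id %in% unique(records$seq_id)[keep_seq], ,
          drop = FALSE]
}
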