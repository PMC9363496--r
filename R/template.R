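# Spectrogram template-matching baseline detector.
#
# The averaged spectrogram of annotated pulses serves as a matched filter:
# segments are scored by the maximum over time lags of the normalized 2-D
# cross-correlation with the template (frequency axis kept aligned,
# mirroring the detector's no-frequency-convolution design). By default the
# correlation runs on the same compressed mel representation the CNN sees.

#' Build a pulse template
#'
#' Elementwise mean of example pulse spectrograms of identical shape.
#'
#' @param examples List of matrices (e.g. compressed mel spectrograms of
#'   annotated pulses).
#' @return A `fin_template` with the mean matrix and `n_source_examples`.
#' @export
build_template <- function(examples) {
  stopifnot(length(examples) >= 1)
  d <- dim(examples[[1]])
  for (e in examples) {
    if (!identical(dim(e), d)) stop("example spectrogram shape mismatch")
  }
  m <- Reduce(`+`, examples) / length(examples)
  structure(list(matrix = m, n_source_examples = length(examples)),
            class = "fin_template")
}

#' Template match score
#'
#' Slides the template along the time axis of a segment spectrogram and
#' returns the maximum normalized cross-correlation (both operands
#' zero-meaned and unit-normed per lag), making the score invariant to
#' segment amplitude scaling.
#'
#' @param segment Spectrogram matrix, at least as many columns as the
#'   template.
#' @param template A `fin_template`.
#' @param return_lags If `TRUE`, also return per-lag correlations.
#' @return Maximum correlation in `[-1, 1]` (or a list with `score`,
#'   `best_lag`, `correlation` when `return_lags`).
#' @export
match_score <- function(segment, template, return_lags = FALSE) {
  stopifnot(inherits(template, "fin_template"))
  tm <- template$matrix
  stopifnot(nrow(segment) == nrow(tm), ncol(segment) >= ncol(tm))
  tv <- as.numeric(tm) - mean(tm)
  tn <- sqrt(sum(tv^2))
  n_lags <- ncol(segment) - ncol(tm) + 1
  cors <- numeric(n_lags)
  for (lag in seq_len(n_lags)) {
    sub <- segment[, lag:(lag + ncol(tm) - 1)]
    sv <- as.numeric(sub) - mean(sub)
    sn <- sqrt(sum(sv^2))
    cors[lag] <- if (sn == 0 || tn == 0) 0 else sum(sv * tv) / (sn * tn)
  }
  if (return_lags) {
    list(score = max(cors), best_lag = which.max(cors), correlation = cors)
  } else {
    max(cors)
  }
}
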