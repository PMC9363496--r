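# ROC analysis and balance-point threshold selection.

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (a sample is
#' called positive when its score is >= the threshold) and records
#' sensitivity and specificity at each.
#'
#' @param scores Numeric scores (higher = more pulse-like).
#' @param labels Binary labels (1 = pulse present).
#' @return A `fin_roc` data frame with `threshold`, `sensitivity`,
#'   `specificity` and an `auc` attribute (trapezoidal area under the
#'   TPR-FPR curve).
#' @export
roc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to compute a ROC curve")
  }
  thr <- sort(unique(scores))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n_neg, 0)
  out <- data.frame(threshold = c(thr, Inf),
                    sensitivity = c(sens, 0),
                    specificity = c(spec, 1))
  fpr <- 1 - out$specificity
  o <- order(fpr, out$sensitivity)
  x <- c(0, fpr[o], 1); y <- c(0, out$sensitivity[o], 1)
  attr(out, "auc") <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  class(out) <- c("fin_roc", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' @param r A `fin_roc` from [roc()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(r) {
  stopifnot(inherits(r, "fin_roc"))
  attr(r, "auc")
}

#' Balance-point threshold
#'
#' The operating threshold where sensitivity and specificity are equal
#' (minimizing their absolute difference over the score grid); ties are
#' broken toward the higher-specificity threshold.
#'
#' @param r A `fin_roc` from [roc()].
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
balance_threshold <- function(r) {
  stopifnot(inherits(r, "fin_roc"))
  rr <- r[is.finite(r$threshold), ]
  d <- abs(rr$sensitivity - rr$specificity)
  best <- which(d == min(d))
  pick <- best[which.max(rr$specificity[best])]
  list(threshold = rr$threshold[pick],
       sensitivity = rr$sensitivity[pick],
       specificity = rr$specificity[pick])
}
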