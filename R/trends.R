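# Modal-value trend extraction and linear regression.
#
# Stereotypical IPIs: per calendar trimester and bi-gram, IPIs are
# quantized to 0.1 s and the most frequent bin is kept, subject to support
# gates (at least 100 transitions in the period, modal share above 5%).
# Intra-annual center frequencies: per month of year (pooled across
# years), quantized to 0.1 Hz, at least 200 pulses, regressed over the
# August-to-February ordering. Ordinary least squares gives slope,
# r-squared and the two-sided p-value for a zero slope.

#' Modal (most frequent) quantized value
#'
#' Values are quantized by flooring to the resolution grid; the most
#' frequent bin wins (lowest bin on ties). Returns `NULL` when the support
#' gates fail: fewer than `min_count` values, or a modal share not above
#' `min_fraction` (strict).
#'
#' @param values Numeric values.
#' @param resolution Quantization grid step (> 0).
#' @param min_count Minimum number of values in the period.
#' @param min_fraction Minimum (exclusive) modal share of the period.
#' @return List (`modal_value`, `support`, `fraction`) or `NULL`.
#' @export
modal_value <- function(values, resolution, min_count = 0,
                        min_fraction = 0) {
  stopifnot(resolution > 0)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0 || n < min_count) return(NULL)
  bins <- floor(values / resolution + 1e-9) * resolution
  tab <- table(bins)
  top <- which.max(tab) # which.max takes the first (lowest bin) on ties
  frac <- as.numeric(tab[top]) / n
  if (frac <= min_fraction) return(NULL)
  list(modal_value = as.numeric(names(tab)[top]),
       support = n, fraction = frac)
}

#' Ordinary least-squares regression
#'
#' @param x,y Numeric vectors (>= 3 points, `x` not constant).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   t-test on the slope).
#' @export
linreg <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("x must not be constant")
  if (stats::sd(y) == 0) {
    return(list(slope = 0, intercept = y[1], r_squared = 0, p_value = 1))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4])
}

fractional_year <- function(datetime) {
  lt <- as.POSIXlt(datetime, tz = "UTC")
  lt$year + 1900 + (lt$yday + 0.5) / 365.25
}

#' Inter-annual stereotypical IPI trend
#'
#' For one bi-gram label, groups transitions by calendar trimester
#' (quarter), takes the modal IPI at 0.1 s resolution subject to the
#' support gates, and regresses the modal IPI on the trimester mid-point
#' expressed as a fractional year. The slope is in s/year.
#'
#' @param bigrams Data frame with `bigram`, `ipi_s`, `datetime` columns
#'   (e.g. from [label_bigrams()] with dates attached).
#' @param bigram_label One of "AA", "AB", "BA", "BB".
#' @param resolution IPI quantization (s).
#' @param min_count Minimum transitions per trimester.
#' @param min_fraction Minimum (exclusive) modal share.
#' @return List: `points` (data frame of trend points) and `regression`
#'   (`NULL` when fewer than 3 points survive the gates).
#' @export
ipi_trend <- function(bigrams, bigram_label, resolution = 0.1,
                      min_count = 100, min_fraction = 0.05) {
  b <- bigrams[bigrams$bigram == bigram_label & is.finite(bigrams$ipi_s), ]
  lt <- as.POSIXlt(b$datetime, tz = "UTC")
  year <- lt$year + 1900
  quarter <- (lt$mon %/% 3) + 1
  key <- paste0(year, "-Q", quarter)
  pts <- lapply(unique(key), function(kk) {
    i <- which(key == kk)
    mv <- modal_value(b$ipi_s[i], resolution, min_count, min_fraction)
    if (is.null(mv)) return(NULL)
    data.frame(period = kk,
               year_frac = year[i][1] + (quarter[i][1] - 0.5) / 4,
               modal_value = mv$modal_value,
               support = mv$support, fraction = mv$fraction,
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  reg <- NULL
  if (!is.null(pts) && nrow(pts) >= 3 && stats::sd(pts$year_frac) > 0) {
    reg <- linreg(pts$year_frac, pts$modal_value)
  }
  list(points = pts, regression = reg)
}

# month-of-year -> index on the August..February song-season ordering
season_month_index <- function(month) {
  idx <- ifelse(month >= 8, month - 8, month + 4)
  idx[month >= 3 & month <= 7] <- NA_integer_
  idx
}

#' Intra-annual center-frequency trend
#'
#' Groups pulses by month of year (pooled across years), takes the modal
#' center frequency at 0.1 Hz resolution for months with at least
#' `min_count` pulses, and regresses the modal value over the
#' August-to-February month ordering (August = 0, ..., February = 6);
#' months outside that span are excluded. The slope is in Hz/month.
#'
#' @param records Pulse records with `cf_hz` and `datetime` columns.
#' @param resolution Frequency quantization (Hz).
#' @param min_count Minimum pulses per month.
#' @return List: `points` and `regression` (as in [ipi_trend()]).
#' @export
monthly_cf_trend <- function(records, resolution = 0.1, min_count = 200) {
  r <- records[is.finite(records$cf_hz), ]
  month <- as.POSIXlt(r$datetime, tz = "UTC")$mon + 1
  idx <- season_month_index(month)
  pts <- lapply(sort(unique(idx[!is.na(idx)])), function(mi) {
    i <- which(!is.na(idx) & idx == mi)
    mv <- modal_value(r$cf_hz[i], resolution, min_count, 0)
    if (is.null(mv)) return(NULL)
    data.frame(month_index = mi,
               month = month[i][1],
               modal_value = mv$modal_value,
               support = mv$support, fraction = mv$fraction)
  })
  pts <- do.call(rbind, pts)
  reg <- NULL
  if (!is.null(pts) && nrow(pts) >= 3 && stats::sd(pts$month_index) > 0) {
    reg <- linreg(pts$month_index, pts$modal_value)
  }
  list(points = pts, regression = reg)
}

#' Merge literature trend points
#'
#' Appends externally published stereotypical-IPI measurements (year,
#' value, bi-gram) to a trend-point table, flagged by origin, so
#' regressions can be run with or without them.
#'
#' @param points Trend points from [ipi_trend()] (may be `NULL`).
#' @param overlay Data frame with `year_frac`, `modal_value` and optionally
#'   `bigram` columns; may be empty.
#' @return Combined data frame with an `origin` column ("measured" or
#'   "literature").
#' @export
literature_overlay <- function(points, overlay = NULL) {
  if (is.null(points)) {
    points <- data.frame(period = character(), year_frac = numeric(),
                         modal_value = numeric(), support = integer(),
                         fraction = numeric(), stringsAsFactors = FALSE)
  }
  points$origin <- rep("measured", nrow(points))
  if (is.null(overlay) || nrow(overlay) == 0) return(points)
  add <- data.frame(period = sprintf("lit-%0.1f", overlay$year_frac),
                    year_frac = overlay$year_frac,
                    modal_value = overlay$modal_value,
                    support = NA_integer_, fraction = NA_real_,
                    origin = "literature", stringsAsFactors = FALSE)
  rbind(points, add)
}
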