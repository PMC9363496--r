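# Gaussian-mixture pulse-type classification and bi-gram analysis.
#
# Pulse types A ("classic" 20 Hz pulse, higher pitched) and B ("back-beat")
# are separated by a 2-component univariate GMM on center frequency, fitted
# by EM; the decision threshold is the equal-posterior frequency between
# the two means. A 3-component bivariate GMM on (center frequency, time to
# next pulse) groups the AA/AB/BA bi-grams for the frequency-IPI
# correlation analysis.

#' Fit a 2-component univariate GMM
#'
#' EM on center frequencies with a seeded quantile-split initialization,
#' best of `restarts` runs, tolerance 1e-6 on the log-likelihood, at most
#' `max_iter` iterations. The per-iteration log-likelihood trace is kept in
#' the fit (it is non-decreasing, a standard EM guarantee asserted in the
#' test suite).
#'
#' @param x Numeric values (center frequencies, Hz); needs >= 2 distinct
#'   values.
#' @param seed Integer seed for the restart initializations.
#' @param restarts Number of EM restarts.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return A `fin_gmm1d`: `weight`, `mean`, `sd` (length-2 each, ordered by
#'   mean), `loglik`, `loglik_trace`.
#' @export
fit_gmm_1d <- function(x, seed = 1L, restarts = 5, max_iter = 500,
                       tol = 1e-6) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) stop("need at least 2 distinct values")
  n <- length(x)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      if (r == 1) {
        split <- stats::median(x)
        g1 <- x[x <= split]; g2 <- x[x > split]
        if (length(g2) == 0) { g2 <- max(x); g1 <- x[x < max(x)] }
        mu <- c(mean(g1), mean(g2))
        sdv <- pmax(c(stats::sd(g1), stats::sd(g2)), 1e-3, na.rm = TRUE)
        sdv[!is.finite(sdv)] <- stats::sd(x)
        w <- c(length(g1), length(g2)) / n
      } else {
        mu <- sort(sample(x, 2))
        sdv <- rep(stats::sd(x) / 2, 2)
        w <- c(0.5, 0.5)
      }
      ll_old <- -Inf
      trace <- numeric(0)
      for (it in seq_len(max_iter)) {
        d1 <- w[1] * stats::dnorm(x, mu[1], sdv[1])
        d2 <- w[2] * stats::dnorm(x, mu[2], sdv[2])
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        ll <- sum(log(tot))
        trace <- c(trace, ll)
        if (abs(ll - ll_old) < tol) break
        ll_old <- ll
        r1 <- d1 / tot; r2 <- 1 - r1
        n1 <- sum(r1); n2 <- sum(r2)
        w <- c(n1, n2) / n
        mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
        sdv <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                      sum(r2 * (x - mu[2])^2) / n2))
        sdv <- pmax(sdv, 1e-4)
      }
      if (is.null(best) || ll > best$loglik) {
        best <- list(weight = w, mean = mu, sd = sdv, loglik = ll,
                     loglik_trace = trace)
      }
    }
  })
  o <- order(best$mean)
  structure(list(weight = best$weight[o], mean = best$mean[o],
                 sd = best$sd[o], loglik = best$loglik,
                 loglik_trace = best$loglik_trace),
            class = "fin_gmm1d")
}

#' Type-discrimination threshold
#'
#' The frequency between the two component means where the weighted
#' component densities are equal (equal posterior probability). Set
#' `weighted = FALSE` for the unweighted density intersection.
#'
#' @param g A `fin_gmm1d`.
#' @param weighted Use mixture weights (default) or plain densities.
#' @return Threshold in Hz.
#' @export
type_threshold <- function(g, weighted = TRUE) {
  stopifnot(inherits(g, "fin_gmm1d"))
  w <- if (weighted) g$weight else c(1, 1)
  f <- function(x) {
    log(w[1]) + stats::dnorm(x, g$mean[1], g$sd[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, g$mean[2], g$sd[2], log = TRUE)
  }
  stats::uniroot(f, lower = g$mean[1], upper = g$mean[2],
                 extendInt = "no", tol = 1e-10)$root
}

#' Assign pulse types by threshold
#'
#' Center frequency strictly above the threshold is type A (the higher
#' pitched pulse); at or below is type B.
#'
#' @param records Pulse records with a `cf_hz` column.
#' @param threshold Discrimination threshold in Hz.
#' @return `records` with a `type` column.
#' @export
assign_types <- function(records, threshold) {
  records$type <- ifelse(records$cf_hz > threshold, "A", "B")
  records
}

#' Label bi-grams within a sequence
#'
#' One bi-gram per consecutive pulse pair, labelled (earlier type, later
#' type), carrying the pair's IPI and the earlier pulse's center frequency.
#'
#' @param records Time-sorted typed pulse records of one sequence, with
#'   `t_s`, `type`, `cf_hz` (and optionally `datetime`).
#' @return Data frame: `bigram`, `ipi_s`, `cf_hz`, and `datetime` when
#'   available.
#' @export
label_bigrams <- function(records) {
  n <- nrow(records)
  if (n < 2) {
    return(data.frame(bigram = character(), ipi_s = numeric(),
                      cf_hz = numeric(), stringsAsFactors = FALSE))
  }
  if (is.unsorted(records$t_s)) stop("records must be time-sorted")
  out <- data.frame(bigram = paste0(records$type[-n], records$type[-1]),
                    ipi_s = diff(records$t_s),
                    cf_hz = records$cf_hz[-n],
                    stringsAsFactors = FALSE)
  if ("datetime" %in% names(records)) out$datetime <- records$datetime[-n]
  out
}

#' Fit a 3-component bivariate GMM
#'
#' Full-covariance EM on (center frequency, time to next pulse), restricted
#' to IPIs within [14, 20] s, approximating the AA/AB/BA bi-gram groups
#' (BB pairs fall outside the IPI gate). Initialized by seeded k-means;
#' hard assignments by maximum posterior.
#'
#' @param cf Center frequencies (Hz).
#' @param ipi Time to next pulse (s), same length.
#' @param seed Integer seed.
#' @param k Number of components.
#' @param ipi_gate Inclusive IPI range (s) restricting the fit.
#' @param max_iter,tol EM controls.
#' @return A `fin_gmm2d`: `weight`, `mean` (k x 2), `cov` (list of 2x2),
#'   `assignment`, `loglik`, `loglik_trace`, `kept` (index of rows inside
#'   the IPI gate).
#' @export
fit_gmm_2d <- function(cf, ipi, seed = 1L, k = 3, ipi_gate = c(14, 20),
                       max_iter = 500, tol = 1e-6) {
  stopifnot(length(cf) == length(ipi))
  kept <- which(is.finite(cf) & is.finite(ipi) &
                  ipi >= ipi_gate[1] & ipi <= ipi_gate[2])
  X <- cbind(cf[kept], ipi[kept])
  n <- nrow(X)
  if (n < k) stop("need at least ", k, " points inside the IPI gate")
  # standardize for the distance-based init and EM conditioning
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  km <- with_seed(seed, stats::kmeans(Z, centers = k, nstart = 5))
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  mu <- km$centers
  covs <- lapply(seq_len(k), function(j) {
    Zj <- Z[km$cluster == j, , drop = FALSE]
    if (nrow(Zj) < 3) diag(2) else stats::cov(Zj) + diag(1e-6, 2)
  })
  ll_old <- -Inf; trace <- numeric(0)
  dmv <- function(Z, m, S) {
    L <- chol(S)
    d <- forwardsolve(t(L), t(Z) - m)
    exp(-0.5 * colSums(d^2)) / (2 * pi * prod(diag(L)))
  }
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dmv(Z, mu[j, ], covs[[j]]),
                   numeric(n))
    dens <- matrix(dens, n, k)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * Z) / nk[j]
      Zc <- sweep(Z, 2, mu[j, ])
      covs[[j]] <- crossprod(Zc * sqrt(resp[, j])) / nk[j] + diag(1e-6, 2)
    }
  }
  dens <- vapply(seq_len(k), function(j) w[j] * dmv(Z, mu[j, ], covs[[j]]),
                 numeric(n))
  assignment <- max.col(matrix(dens, n, k))
  # back-transform parameters to the original scale
  mu_orig <- sweep(sweep(mu, 2, scl, "*"), 2, ctr, "+")
  covs_orig <- lapply(covs, function(S) S * tcrossprod(scl))
  structure(list(weight = w, mean = mu_orig, cov = covs_orig,
                 assignment = assignment, loglik = ll_old,
                 loglik_trace = trace, kept = kept),
            class = "fin_gmm2d")
}

#' Pearson correlation per group
#'
#' Two-sided Pearson test between center frequency and IPI within each
#' assigned mixture group.
#'
#' @param cf,ipi Numeric vectors.
#' @param group Group labels (e.g. GMM assignments), same length.
#' @return Data frame: `group`, `n`, `r`, `p_value` (`NA` with a warning
#'   for zero-variance groups).
#' @export
pearson_by_group <- function(cf, ipi, group) {
  stopifnot(length(cf) == length(ipi), length(cf) == length(group))
  groups <- sort(unique(group))
  out <- lapply(groups, function(g) {
    i <- which(group == g)
    if (length(i) < 3) stop("group ", g, " has fewer than 3 points")
    if (stats::sd(cf[i]) == 0 || stats::sd(ipi[i]) == 0) {
      warning("zero-variance group ", g)
      return(data.frame(group = g, n = length(i), r = NA_real_,
                        p_value = NA_real_))
    }
    ct <- stats::cor.test(cf[i], ipi[i], method = "pearson")
    data.frame(group = g, n = length(i), r = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' Kullback-Leibler divergence between the two components
#'
#' Closed-form univariate Gaussian KL. The symmetrized (Jeffreys)
#' divergence is reported as the headline value, with both directed values
#' alongside; units are nats.
#'
#' @param g A `fin_gmm1d`.
#' @return List: `symmetrized`, `kl_12`, `kl_21` (nats).
#' @export
component_kl <- function(g) {
  stopifnot(inherits(g, "fin_gmm1d"))
  kl <- function(m1, s1, m2, s2) {
    log(s2 / s1) + (s1^2 + (m1 - m2)^2) / (2 * s2^2) - 0.5
  }
  k12 <- kl(g$mean[1], g$sd[1], g$mean[2], g$sd[2])
  k21 <- kl(g$mean[2], g$sd[2], g$mean[1], g$sd[1])
  list(symmetrized = k12 + k21, kl_12 = k12, kl_21 = k21)
}
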