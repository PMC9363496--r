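# Gaussian-mixture type classification, bi-gram labelling and the
# frequency-IPI mixture analysis.

test_that("EM threshold sits at the analytic equal-posterior point", {
  # symmetric case: threshold at the midpoint
  set.seed(80)
  x <- c(stats::rnorm(2000, 19, 0.3), stats::rnorm(2000, 21, 0.3))
  g <- fit_gmm_1d(x, seed = 80)
  expect_equal(type_threshold(g), 20, tolerance = 0.05)
  # stated mixture: means 19.3 / 20.6, sds 0.4, n = 5000
  set.seed(81)
  x2 <- c(stats::rnorm(2500, 19.3, 0.4), stats::rnorm(2500, 20.6, 0.4))
  g2 <- fit_gmm_1d(x2, seed = 81)
  # closed-form root of equal weighted densities of the true mixture
  analytic <- stats::uniroot(function(v) {
    0.5 * stats::dnorm(v, 19.3, 0.4) - 0.5 * stats::dnorm(v, 20.6, 0.4)
  }, c(19.3, 20.6))$root
  expect_lt(abs(type_threshold(g2) - analytic), 0.1)
  # the fitted component means recover the generating parameters
  expect_equal(g2$mean, c(19.3, 20.6), tolerance = 0.1)
  expect_error(fit_gmm_1d(rep(1, 10)), "distinct")
})

test_that("EM log-likelihood is non-decreasing and matches mclust", {
  set.seed(82)
  x <- c(stats::rnorm(1000, 19.3, 0.4), stats::rnorm(1000, 20.6, 0.4))
  g <- fit_gmm_1d(x, seed = 82)
  expect_true(all(diff(g$loglik_trace) >= -1e-8))
  if (requireNamespace("mclust", quietly = TRUE)) {
    suppressMessages(library(mclust)) # Mclust resolves helpers unqualified
    ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(sort(g$mean), sort(as.numeric(ref$parameters$mean)),
                 tolerance = 0.05)
  }
})

test_that("type assignment uses the strict-above rule with ties to B", {
  rec <- data.frame(cf_hz = c(20.5, 19.96, 19.5))
  out <- assign_types(rec, 19.96)
  expect_equal(out$type, c("A", "B", "B"))
})

test_that("bi-gram labelling pairs consecutive pulses in order", {
  rec <- data.frame(t_s = c(0, 17, 32), type = c("A", "B", "A"),
                    cf_hz = c(20.5, 19.3, 20.6))
  bg <- label_bigrams(rec)
  expect_equal(bg$bigram, c("AB", "BA"))
  expect_equal(bg$ipi_s, c(17, 15))
  expect_equal(bg$cf_hz, c(20.5, 19.3))
  expect_equal(nrow(label_bigrams(rec[1, ])), 0)
  # random typed sequence matches a pairwise oracle
  set.seed(83)
  n <- 40
  r2 <- data.frame(t_s = sort(stats::runif(n, 0, 600)),
                   type = sample(c("A", "B"), n, TRUE),
                   cf_hz = stats::runif(n, 19, 21))
  bg2 <- label_bigrams(r2)
  for (i in seq_len(n - 1)) {
    expect_equal(bg2$bigram[i], paste0(r2$type[i], r2$type[i + 1]))
    expect_equal(bg2$ipi_s[i], r2$t_s[i + 1] - r2$t_s[i])
  }
})

test_that("bivariate mixture separates bi-gram clusters with high purity", {
  set.seed(84)
  n <- 400
  truth <- sample(1:3, n, TRUE)
  mu <- rbind(c(20.6, 14.9), c(20.6, 16.9), c(19.3, 14.9))
  cf <- mu[truth, 1] + stats::rnorm(n, 0, 0.15)
  ipi <- mu[truth, 2] + stats::rnorm(n, 0, 0.25)
  g <- fit_gmm_2d(cf, ipi, seed = 84)
  expect_true(all(diff(g$loglik_trace) >= -1e-6))
  tab <- table(truth[g$kept], g$assignment)
  purity <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gt(purity, 0.95)
  # cluster means ordered consistently with the generator means
  expect_equal(dim(g$mean), c(3, 2))
  expect_error(fit_gmm_2d(numeric(0), numeric(0)), "at least")
})

test_that("per-group Pearson analysis matches the closed form", {
  x <- c(1, 2, 3, 4, 5)
  out <- pearson_by_group(x, 2 * x + 1, rep(1, 5))
  expect_equal(out$r, 1)
  # textbook 5-point set against the hand formula
  y <- c(2, 1, 4, 3, 5)
  hand <- sum((x - 3) * (y - 3)) /
    sqrt(sum((x - 3)^2) * sum((y - 3)^2))
  expect_equal(pearson_by_group(x, y, rep(1, 5))$r, hand)
  # independent simulated cf and IPI: |r| < 0.1 at n = 1000
  set.seed(85)
  out2 <- pearson_by_group(stats::rnorm(1000), stats::rnorm(1000),
                           rep(1, 1000))
  expect_lt(abs(out2$r), 0.1)
  expect_warning(pearson_by_group(rep(1, 5), y, rep(1, 5)),
                 "zero-variance")
})

test_that("component KL divergence matches the Gaussian closed form", {
  mk <- function(m, s) structure(list(weight = c(0.5, 0.5), mean = m,
                                      sd = s, loglik = 0,
                                      loglik_trace = 0),
                                 class = "fin_gmm1d")
  expect_equal(component_kl(mk(c(20, 20), c(0.4, 0.4)))$symmetrized, 0)
  expect_equal(component_kl(mk(c(0, 1), c(1, 1)))$symmetrized, 1)
  # monotone in mean separation at fixed sds
  kls <- vapply(c(0.5, 1, 1.5, 2), function(d) {
    component_kl(mk(c(0, d), c(0.4, 0.4)))$symmetrized
  }, 0)
  expect_true(all(diff(kls) > 0))
})

test_that("classified synthetic pulses recover ground-truth types", {
  cfg <- synthesis_config(seed = 86)
  song <- synth_song(cfg, 30 * 60)
  gt <- song$ground_truth
  cf_obs <- gt$cf_hz + stats::rnorm(nrow(gt), 0, 0.2)
  g <- fit_gmm_1d(cf_obs, seed = 86)
  lab <- assign_types(data.frame(cf_hz = cf_obs), type_threshold(g))
  expect_gt(mean(lab$type == gt$type), 0.9)
})
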