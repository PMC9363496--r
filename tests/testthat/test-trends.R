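# Modal-value extraction, support gates and trend regressions.

test_that("modal value quantizes by flooring and applies support gates", {
  mv <- modal_value(c(15.14, 15.12, 15.27), 0.1)
  expect_equal(mv$modal_value, 15.1)
  expect_equal(mv$support, 3)
  # count gate
  expect_null(modal_value(stats::runif(50), 0.1, min_count = 100))
  # fraction gate is strict
  expect_null(modal_value(c(1.01, 1.11), 0.1, min_fraction = 0.5))
  expect_false(is.null(modal_value(c(1.01, 1.02, 1.11), 0.1,
                                   min_fraction = 0.5)))
  # histogram oracle: 1000 draws of N(15.4, 0.3^2)
  set.seed(90)
  x <- stats::rnorm(1000, 15.4, 0.3)
  expect_lt(abs(modal_value(x, 0.1)$modal_value - 15.4), 0.1 + 1e-9)
  # tie-break: lowest bin wins
  expect_equal(modal_value(c(1.05, 1.15), 0.1)$modal_value, 1.0)
})

test_that("quantization commutes with rescaling to unit bins", {
  set.seed(91)
  x <- stats::runif(200, 10, 20)
  res <- 0.1
  a <- modal_value(x, res)$modal_value
  b <- modal_value(floor(x / res + 1e-9), 1)$modal_value * res
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("support gates are monotone", {
  set.seed(92)
  x <- stats::rnorm(500, 15, 0.5)
  for (mc in c(0, 100, 400, 600)) {
    lo <- modal_value(x, 0.1, min_count = mc)
    hi <- modal_value(x, 0.1, min_count = mc + 200)
    if (is.null(lo)) expect_null(hi)
  }
  for (mf in c(0, 0.02, 0.05, 0.5)) {
    lo <- modal_value(x, 0.1, min_fraction = mf)
    hi <- modal_value(x, 0.1, min_fraction = mf + 0.2)
    if (is.null(lo)) expect_null(hi)
  }
})

test_that("linear regression matches the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  r <- linreg(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  rc <- linreg(x, rep(3, 5))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  expect_error(linreg(rep(1, 5), x), "constant")
  # 6-point set against the normal-equations oracle
  set.seed(93)
  x6 <- c(0.5, 1.1, 2.3, 2.9, 4.2, 5.0)
  y6 <- c(1.2, 0.8, 2.5, 2.2, 3.9, 4.4)
  X <- cbind(1, x6)
  beta <- solve(t(X) %*% X, t(X) %*% y6)
  r6 <- linreg(x6, y6)
  expect_equal(r6$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r6$slope, beta[2], tolerance = 1e-10)
})

test_that("null synthetic datasets yield near-zero trend slopes", {
  cfg <- synthesis_config(seed = 94, ipi_drift = 0, cf_monthly_slope = 0)
  d <- synth_longterm_dataset(cfg, 2008, 6, 300, seed = 94)
  bg <- d[!is.na(d$bigram), ]
  tr <- ipi_trend(bg, "AA")
  expect_lt(abs(tr$regression$slope), 0.02)
  cf <- monthly_cf_trend(d)
  expect_lt(abs(cf$regression$slope), 0.02)
  # gates populate the trend points with the documented fields
  expect_true(all(tr$points$fraction > 0.05))
  expect_true(all(tr$points$support >= 100))
  expect_true(all(cf$points$support >= 200))
})

test_that("implanted slopes are recovered at the published gates", {
  # 800 pulses/month keeps every bi-gram (AB/BA carry ~13% of transitions)
  # above the 100-transition trimester gate
  cfg <- synthesis_config(seed = 95, ipi_drift = 0.1,
                          cf_monthly_slope = -0.1)
  d <- synth_longterm_dataset(cfg, 2008, 10, 800, seed = 95)
  bg <- d[!is.na(d$bigram), ]
  for (lb in c("AA", "AB", "BA")) {
    tr <- ipi_trend(bg, lb)
    expect_false(is.null(tr$regression))
    expect_lt(abs(tr$regression$slope - 0.1), 0.02)
    expect_gt(tr$regression$r_squared, 0.7)
  }
  cf <- monthly_cf_trend(d)
  expect_lt(abs(cf$regression$slope - (-0.1)), 0.03)
})

test_that("literature overlay flags external points without altering data", {
  cfg <- synthesis_config(seed = 96, ipi_drift = 0.1)
  d <- synth_longterm_dataset(cfg, 2010, 5, 300, seed = 96)
  tr <- ipi_trend(d[!is.na(d$bigram), ], "AA")
  merged0 <- literature_overlay(tr$points, NULL)
  expect_equal(nrow(merged0), nrow(tr$points))
  expect_true(all(merged0$origin == "measured"))
  lit <- data.frame(year_frac = c(1999.5, 2008.0),
                    modal_value = c(14.0, 14.9))
  merged <- literature_overlay(tr$points, lit)
  expect_equal(nrow(merged), nrow(tr$points) + 2)
  expect_equal(sum(merged$origin == "literature"), 2)
  # regression with vs without the overlay differs only via the new points
  r_without <- linreg(tr$points$year_frac, tr$points$modal_value)
  r_with <- linreg(merged$year_frac, merged$modal_value)
  expect_false(isTRUE(all.equal(r_without$slope, r_with$slope)))
  back <- merged[merged$origin == "measured", ]
  expect_equal(linreg(back$year_frac, back$modal_value)$slope,
               r_without$slope)
})
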