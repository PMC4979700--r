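test_that("input validation rejects unusable series", {
  expect_error(bcp_fit(c(1, 2)), "at least 3")
  expect_error(bcp_fit(c(1, NA, 2, 3)), "missing")
  expect_error(bcp_fit(1:10, iterations = 0), "positive")
})

test_that("a constant series shows no high-probability change", {
  fit <- bcp_fit(rep(3, 30), seed = 1)
  expect_lt(max(fit$posterior_prob), 0.5)
})

test_that("a large mean step is localised with high probability", {
  set.seed(4)
  x <- c(rnorm(10, 0, 0.01), rnorm(10, 5, 0.01))
  fit <- bcp_fit(x, seed = 2)
  expect_identical(which.max(fit$posterior_prob), 11L)
  expect_gt(max(fit$posterior_prob), 0.9)
  # posterior mean stays inside the observed range and tracks the step
  expect_true(all(fit$posterior_mean >= min(x) &
                    fit$posterior_mean <= max(x)))
  expect_lt(mean(fit$posterior_mean[1:10]), 1)
  expect_gt(mean(fit$posterior_mean[11:20]), 4)
})

test_that("fits are reproducible under a fixed seed", {
  set.seed(9)
  x <- cumsum(rnorm(25))
  f1 <- bcp_fit(x, iterations = 2000, burn_in = 1000, seed = 33)
  f2 <- bcp_fit(x, iterations = 2000, burn_in = 1000, seed = 33)
  expect_identical(f1$posterior_prob, f2$posterior_prob)
  expect_identical(f1$posterior_mean, f2$posterior_mean)
})

test_that("posterior change probabilities are location-equivariant", {
  set.seed(14)
  x <- c(rnorm(12, 1, 0.5), rnorm(12, 3, 0.5))
  f1 <- bcp_fit(x, seed = 5)
  f2 <- bcp_fit(x + 100, seed = 5)
  expect_lt(max(abs(f1$posterior_prob - f2$posterior_prob)), 0.02)
})

test_that("transition detection follows the earliest qualifying peak", {
  mk <- function(prob, series) {
    structure(list(dates = as.Date("2012-04-01") + seq_along(series) - 1,
                   series = series, posterior_mean = series,
                   posterior_prob = prob,
                   mcmc = list()), class = "changepoint_result")
  }
  r <- detect_transition(mk(c(0.1, 0.2, 0.6, 0.4), c(1, 1, 2.2, 2.0)))
  expect_true(r$detected)
  expect_identical(r$index, 3L)
  expect_equal(r$fold_change, 2.2)

  none <- detect_transition(mk(c(0.1, 0.5, 0.3, 0.2), c(1, 2, 2, 2)))
  expect_false(none$detected)

  # plateau resolves to its earliest position
  plat <- detect_transition(mk(c(0, 0.2, 0.7, 0.7, 0.3, 0.9, 0.1),
                               c(1, 1, 2, 2, 2, 3, 3)))
  expect_identical(plat$index, 3L)

  # baseline window limits the fold-change denominator
  lim <- detect_transition(mk(c(0, 0, 0, 0, 0.8), c(10, 10, 1, 1, 3)),
                           baseline_days = 2)
  expect_equal(lim$fold_change, 3)
  expect_identical(lim$baseline_days_used, 2L)
})
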