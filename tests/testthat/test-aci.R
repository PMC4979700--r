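test_that("the band index matches hand evaluation", {
  expect_identical(aci_band(c(5, 5, 5, 5)), 0)
  expect_equal(aci_band(c(1, 3, 1, 3)), 0.75)
  # ratio is invariant to positive scaling
  x <- c(2, 7, 3, 9, 4)
  for (k in c(0.5, 3, 100)) {
    expect_equal(aci_band(k * x), aci_band(x))
  }
})

test_that("degenerate band series are rejected", {
  expect_error(aci_band(5), "shorter than 2")
  expect_error(aci_band(c(1, NA, 2)), "non-finite")
  expect_error(aci_band(c(-3, 1, 1), band = "1250"), "1250")
})

test_that("a constant dB offset lowers the index", {
  x <- c(30, 45, 32, 50, 31)
  expect_lt(aci_band(x + 10), aci_band(x))
  expect_gt(aci_band(x - 10), aci_band(x))
})

test_that("sorting a series never increases the index", {
  set.seed(21)
  for (i in 1:20) {
    x <- abs(rnorm(50, 40, 8)) + 1
    expect_lte(aci_band(sort(x)), aci_band(x))
  }
})

test_that("gaps break the adjacent-difference chain", {
  x <- c(10, 20, 10, 20)
  # without gaps: (10+10+10)/60 = 0.5; dropping the middle difference: 20/60
  expect_equal(aci_band(x), 0.5)
  expect_equal(aci_band(x, gap_breaks = 2), 20 / 60)
})

test_that("the daily index sums the per-band indices", {
  s <- flat_spec(100, centers = c(1250, 1600, 2000, 2500, 3150, 4000,
                                  5000, 6300), value = 40)
  res <- aci_total(s, date = as.Date("2012-04-01"))
  expect_identical(res$aci_tot, 0)
  expect_identical(res$band_count, 8L)

  set.seed(3)
  v <- matrix(abs(rnorm(100 * 8, 40, 5)), ncol = 8)
  s2 <- band_spectrogram(v, c(1250, 1600, 2000, 2500, 3150, 4000, 5000,
                              6300))
  r2 <- aci_total(s2)
  expect_equal(r2$aci_tot, sum(r2$per_band), tolerance = 1e-12)
  expect_identical(r2$n_seconds, 100L)
  expect_true(all(r2$per_band >= 0))
  # each column agrees with the scalar implementation
  expect_equal(unname(r2$per_band[3]), aci_band(v[, 3]))
})

test_that("fine-resolution ACI separates stationary from modulated sound", {
  sr <- 22000  # frame-aligned: 0.01 s = 220 samples, 3000 Hz = 30 cycles
  t <- (0:(sr * 2 - 1)) / sr
  steady <- sin(2 * pi * 3000 * t)
  am <- steady * (0.55 + 0.45 * sin(2 * pi * 1.7 * t))
  a_steady <- aci_fine(steady, sr)
  a_am <- aci_fine(am, sr)
  expect_lt(a_steady, 0.01 * a_am)
  # determinism
  expect_identical(aci_fine(am, sr), a_am)
})

test_that("inserted chirps raise the fine-resolution ACI above noise", {
  sr <- 22050
  set.seed(5)
  noise <- rnorm(sr * 3) * 0.05
  withchirps <- noise
  for (i in 0:9) {
    chirp <- dawnchorus:::.render_chirp(2000, 5000, 0.1, sr) * 0.5
    at <- i * floor(0.28 * sr) + 1
    withchirps[at:(at + length(chirp) - 1)] <-
      withchirps[at:(at + length(chirp) - 1)] + chirp
  }
  expect_gt(aci_fine(withchirps, sr), aci_fine(noise, sr))
})
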