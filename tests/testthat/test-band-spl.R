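sr <- 22050

test_that("a pure tone lands in its nominal band", {
  t <- (0:(sr * 2 - 1)) / sr
  x <- sin(2 * pi * 1000 * t)
  spec <- audio_to_band_spl(x, sr)
  pow <- 10^(spec$values[1, ] / 10)
  expect_gt(pow[spec$band_centers == 1000] / sum(pow), 0.9)
  # level agrees with the direct band-masked FFT oracle
  oracle <- 10 * log10(oracle_band_power(x[1:sr], sr,
                                         1000 * 10^(-1 / 20),
                                         1000 * 10^(1 / 20)))
  expect_lt(abs(spec$values[1, spec$band_centers == 1000] - oracle), 0.5)
})

test_that("calibration offsets shift every cell additively", {
  set.seed(1)
  x <- rnorm(sr) * 0.05
  s1 <- audio_to_band_spl(x, sr, calibration_offset = 3)
  s2 <- audio_to_band_spl(x, sr, calibration_offset = 17.5)
  expect_equal(as.vector(s2$values - s1$values),
               rep(14.5, length(s1$values)))
})

test_that("digital silence hits the dB floor without errors", {
  s <- audio_to_band_spl(rep(0, sr), sr)
  expect_true(all(s$values == -120))
  s90 <- audio_to_band_spl(rep(0, sr), sr, calibration_offset = 90)
  expect_true(all(s90$values == -30))
})

test_that("band energies conserve the power of band-limited noise", {
  set.seed(7)
  n <- sr
  white <- rnorm(n)
  # confine to the analysis range so the band set covers all the energy
  spec_f <- stats::fft(white)
  freqs <- c(0:(n %/% 2), -(((n - 1) %/% 2):1)) * (sr / n)
  spec_f[abs(freqs) < 50 | abs(freqs) > 6000] <- 0
  x <- Re(stats::fft(spec_f, inverse = TRUE)) / n
  s <- audio_to_band_spl(x, sr)
  total_bands <- 10 * log10(sum(10^(s$values[1, ] / 10)))
  total_rms <- 10 * log10(mean(x^2))
  expect_lt(abs(total_bands - total_rms), 1)
})

test_that("a +6 dB gain raises every band by 6 dB", {
  set.seed(2)
  x <- rnorm(sr * 2) * 0.03
  s1 <- audio_to_band_spl(x, sr)
  s2 <- audio_to_band_spl(2 * x, sr)
  expect_true(all(abs((s2$values - s1$values) - 20 * log10(2)) < 0.1))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(audio_to_band_spl(rnorm(100), sr), "shorter than 1 s")
  bad <- rnorm(sr)
  bad[123] <- NaN
  expect_error(audio_to_band_spl(bad, sr), "123")
})

test_that("bands above the Nyquist-supported range are dropped with warning", {
  set.seed(3)
  x <- rnorm(9000)
  expect_warning(s <- audio_to_band_spl(x, 9000), "omitted")
  expect_lt(max(s$band_centers) * 10^(1 / 20), 4500)
})

test_that("hourly L50 is the median of per-second broadband levels", {
  # single 1000-Hz band (A-weight ~ 0 there) makes levels transparent
  aw <- a_weighting_db(1000)
  one_hour <- flat_spec(3600, centers = 1000, value = 60 - aw,
                        start_local = "2012-04-16 06:00:00")
  l <- hourly_L50(one_hour)
  expect_identical(l$hour_of_day, 6L)
  expect_equal(l$L50, 60, tolerance = 1e-10)
  expect_identical(l$n_seconds, 3600L)

  v <- matrix(c(50, 60, 70) - aw, ncol = 1)
  s3 <- band_spectrogram(v, 1000,
                         start_time = as.POSIXct("2012-04-16 05:00:00",
                                                 tz = "UTC"))
  expect_equal(hourly_L50(s3)$L50, 60, tolerance = 1e-10)
})

test_that("L50 peaks within an hour of sunrise on a dawn-chorus day", {
  win <- dawn_window(58.4563, -135.8660, as.Date("2012-04-16"), -8)
  sunrise_sec <- as.numeric(win$sunrise) -
    as.numeric(as.POSIXct("2012-04-16", tz = "UTC"))
  set.seed(11)
  vals <- matrix(rnorm(86400 * 2, 30, 0.5), ncol = 2)
  # songs concentrated +/- 30 min around sunrise
  active <- round(sunrise_sec) + (-1800:1800)
  vals[active, ] <- vals[active, ] + 15
  s24 <- band_spectrogram(vals, c(2000, 2500),
                          start_time = as.POSIXct("2012-04-16", tz = "UTC") -
                            (-8) * 3600,
                          utc_offset = -8)
  l <- hourly_L50(s24)
  peak_hour <- l$hour_of_day[which.max(l$L50)]
  expect_lte(abs(peak_hour + 0.5 - sunrise_sec / 3600), 1)
})

test_that("band-SPL CSV round-trips", {
  set.seed(4)
  s <- audio_to_band_spl(rnorm(2 * sr) * 0.1, sr, calibration_offset = 90,
                         start_time = as.POSIXct("2012-04-16 13:45:00",
                                                 tz = "UTC"),
                         utc_offset = -8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_band_spl_csv(s, path)
  back <- read_band_spl_csv(path, calibration_offset = 90)
  expect_equal(back$values, s$values, tolerance = 0.006,
               ignore_attr = TRUE)
  expect_identical(back$band_centers, s$band_centers)
  expect_equal(back$utc_offset, s$utc_offset)
  expect_equal(as.numeric(back$start_time), as.numeric(s$start_time))
})
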