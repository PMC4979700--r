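make_whistle_scene <- function(onset_s = 3, snr_db = 20, dur_total = 10,
                               sr = 22050, f0 = 3000, dur_s = 0.5,
                               seed = 1) {
  set.seed(seed)
  amb <- 10^(-60 / 20)
  x <- rnorm(dur_total * sr) * amb
  n <- round(dur_s * sr)
  syl <- sin(2 * pi * f0 * (0:(n - 1)) / sr) * dawnchorus:::.hann(n)
  syl <- syl * amb * 10^(snr_db / 20) / stats::sd(syl)
  at <- round(onset_s * sr) + 1
  x[at:(at + n - 1)] <- x[at:(at + n - 1)] + syl
  x
}

test_that("noise-only audio yields no detections at a high threshold", {
  set.seed(2)
  x <- rnorm(22050 * 10) * 1e-3
  spec <- stft_spectrogram(x, 22050)
  cfg <- detector_config(c(2500, 5850), snr_threshold = 30)
  expect_identical(nrow(detect_calls(spec, cfg)), 0L)
})

test_that("a single whistle is found once, at the right time", {
  x <- make_whistle_scene()
  spec <- stft_spectrogram(x, 22050)
  cfg <- detector_config(c(2500, 5850), min_duration = 0.2,
                         max_duration = 1.0, snr_threshold = 10)
  det <- detect_calls(spec, cfg)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$onset_s - 3), 0.2)
  expect_gt(det$peak_snr, 10)

  # duration filter: demand longer calls than the 0.5-s whistle
  cfg_long <- detector_config(c(2500, 5850), min_duration = 0.8,
                              max_duration = 1.0, snr_threshold = 10)
  expect_identical(nrow(detect_calls(spec, cfg_long)), 0L)
})

test_that("raising the threshold never increases the detection count", {
  cfg_scene <- scene_config(pre_arrival_rate = 0, post_arrival_rate = 60,
                            species = default_species_templates()[1],
                            seed = 6)
  day <- synthesize_day(cfg_scene, as.Date("2012-04-10"), duration_s = 120)
  spec <- stft_spectrogram(day$samples, day$sample_rate)
  counts <- vapply(c(5, 10, 15, 20, 30), function(thr) {
    nrow(detect_calls(spec, detector_config(c(2500, 5850),
                                            min_duration = 0.2,
                                            max_duration = 1.0,
                                            snr_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detections are invariant to a global gain change", {
  x <- make_whistle_scene(seed = 3)
  cfg <- detector_config(c(2500, 5850), min_duration = 0.2,
                         max_duration = 1.0, snr_threshold = 10)
  d0 <- detect_calls(stft_spectrogram(x, 22050), cfg)
  dup <- detect_calls(stft_spectrogram(x * 2, 22050), cfg)     # +6 dB
  ddn <- detect_calls(stft_spectrogram(x / 2, 22050), cfg)     # -6 dB
  expect_identical(d0$onset_s, dup$onset_s)
  expect_identical(d0$onset_s, ddn$onset_s)
  expect_equal(d0$peak_snr, dup$peak_snr, tolerance = 1e-8)
})

test_that("evaluation counts matches, misses and false alarms", {
  truth <- data.frame(species = "w", onset_s = seq(10, 100, by = 10),
                      duration_s = 0.5, freq_low = 2500, freq_high = 5850)
  dets <- data.frame(onset_s = truth$onset_s + 0.2, duration_s = 0.5,
                     peak_snr = 15, freq_low = 2500, freq_high = 5850,
                     species = "w")
  ev <- evaluate_detections(dets, truth, match_tolerance_s = 1)
  expect_identical(ev$true_positives, 10L)
  expect_identical(ev$false_positives, 0L)
  expect_equal(ev$fn_rate, 0)

  ev8 <- evaluate_detections(dets[1:8, ], truth, match_tolerance_s = 1)
  expect_identical(ev8$true_positives, 8L)
  expect_identical(ev8$false_negatives, 2L)
  expect_equal(ev8$fn_rate, 0.2)

  # order invariance
  shuffled <- dets[sample(nrow(dets)), ]
  evs <- evaluate_detections(shuffled, truth, match_tolerance_s = 1)
  expect_identical(evs$true_positives, ev$true_positives)

  # band mismatch prevents matching
  off_band <- dets
  off_band$freq_low <- 7000
  off_band$freq_high <- 9000
  expect_identical(evaluate_detections(off_band, truth,
                                       match_tolerance_s = 1)$true_positives,
                   0L)
})

test_that("false-negative correction is the inverse-sensitivity estimator", {
  expect_equal(correct_counts(80, 0.2), 100)
  expect_equal(correct_counts(c(a = 10, b = 20), 0), c(a = 10, b = 20))
  df <- correct_counts(data.frame(date = as.Date("2012-04-01"),
                                  count = 45), 0.1)
  expect_equal(df$corrected, 50)
  expect_error(correct_counts(10, 0.96), "cap")
  expect_error(correct_counts(10, -0.1), "\\[0, 1\\)")
})

test_that("detector configs are validated", {
  expect_error(detector_config(c(5850, 2500)), "freq_range")
  expect_error(detector_config(c(2500, 5850), min_duration = 0), "duration")
  expect_error(detector_config(c(2500, 5850), snr_threshold = -3),
               "snr_threshold")
  expect_error(detect_calls(stft_spectrogram(rnorm(22050), 22050),
                            detector_config(c(2500, 15000))),
               "outside")
})

test_that("selection tables carry the standard columns", {
  det <- data.frame(onset_s = 1, duration_s = 0.5, peak_snr = 12,
                    freq_low = 2500, freq_high = 5850, species = "w")
  path <- withr::local_tempfile(fileext = ".txt")
  write_selection_table(det, path)
  tab <- utils::read.delim(path, check.names = FALSE)
  expect_true(all(c("Begin Time (s)", "End Time (s)", "Low Freq (Hz)",
                    "High Freq (Hz)") %in% names(tab)))
  expect_equal(tab$`End Time (s)`, 1.5)
})
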