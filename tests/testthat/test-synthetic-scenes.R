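test_that("template and config invariants are enforced", {
  expect_error(species_template("x", "tonal_whistle", c(5000, 2500), 0.5),
               "freq_range")
  expect_error(species_template("x", "tonal_whistle", c(2500, 5000), -1),
               "syllable_duration")
  expect_error(scene_config(arrival_day = as.Date("2012-06-01")),
               "arrival_day")
  expect_error(scene_config(pre_arrival_rate = -1), "non-negative")
  expect_error(scene_config(sample_rate = 8000), "22050")
  expect_error(sample_call_log(scene_config(), as.Date("2011-01-01")),
               "outside season")
})

test_that("zero post-arrival rate yields no events and noise-only audio", {
  cfg <- scene_config(pre_arrival_rate = 0, post_arrival_rate = 0,
                      weather_events = NULL, seed = 5)
  day <- synthesize_day(cfg, as.Date("2012-04-10"), duration_s = 5)
  expect_identical(nrow(day$truth), 0L)
  # pure Gaussian floor: sample RMS close to the configured level
  expect_lt(abs(20 * log10(stats::sd(day$samples)) - cfg$noise_floor), 1)
})

test_that("Poisson event counts match the configured rate", {
  # one species at 60 songs/h over the 3-h window: mean count 180
  counts <- vapply(1:50, function(s) {
    cfg <- scene_config(pre_arrival_rate = 0, post_arrival_rate = 60,
                        species = default_species_templates()[1],
                        seed = s)
    nrow(sample_call_log(cfg, as.Date("2012-04-10")))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 180), 3 * sqrt(180))
})

test_that("generation is deterministic for a fixed config and date", {
  cfg <- scene_config(seed = 12)
  a <- synthesize_day(cfg, as.Date("2012-04-02"), duration_s = 10)
  b <- synthesize_day(cfg, as.Date("2012-04-02"), duration_s = 10)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  s1 <- synthesize_day_spl(cfg, as.Date("2012-04-02"))
  s2 <- synthesize_day_spl(cfg, as.Date("2012-04-02"))
  expect_identical(s1$spec$values, s2$spec$values)
})

test_that("a season emits one artifact per day with matching truth dates", {
  cfg <- scene_config(season = as.Date(c("2012-04-01", "2012-04-10")),
                      arrival_day = as.Date("2012-04-06"), seed = 31)
  dir <- withr::local_tempdir()
  out <- synthesize_season(cfg, output = "audio", dir = dir,
                           duration_s = 5)
  expect_length(out$days, 10)
  expect_true(all(file.exists(unlist(out$days))))
  expect_identical(nrow(out$weather), 10L)

  # full-window truth: one call log per day, dates spanning the season,
  # with every pre-arrival day quieter than every post-arrival day at
  # rates 2 vs 40 songs/h
  full <- synthesize_season(cfg, output = "spl")
  expect_setequal(format(unique(full$truth$date)),
                  format(seq(cfg$season[1], cfg$season[2], by = "day")))
  daily <- table(factor(format(full$truth$date),
                        levels = format(seq(cfg$season[1], cfg$season[2],
                                            by = "day"))))
  expect_lt(max(daily[1:5]), min(daily[6:10]))
})

test_that("a one-day season runs", {
  cfg <- scene_config(season = as.Date(c("2012-04-01", "2012-04-01")),
                      arrival_day = as.Date("2012-04-01"), seed = 2)
  out <- synthesize_season(cfg)
  expect_length(out$days, 1)
  expect_identical(nrow(out$weather), 1L)
})

test_that("rendered songs confine >= 90% of energy to the template band", {
  sr <- 22050
  for (tpl in default_species_templates()) {
    for (seed in 1:3) {
      set.seed(seed)
      song <- dawnchorus:::.render_song(tpl, sr)
      inband <- oracle_band_power(song, sr, tpl$freq_range[1],
                                  tpl$freq_range[2])
      total <- mean(song^2)
      expect_gt(inband / total, 0.9)
    }
  }
})

test_that("wav files round-trip through the PCM writer and reader", {
  x <- sin(2 * pi * 440 * (0:22049) / 22050) * 0.5
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 22050, path)
  back <- read_wav(path)
  expect_identical(back$sample_rate, 22050L)
  expect_equal(back$samples, x, tolerance = 1 / 32768)
  # quantised signals reproduce exactly
  write_wav(back$samples, 22050, path)
  expect_identical(read_wav(path)$samples, back$samples)
})
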