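#' Species song template for synthetic scenes
#'
#' Describes one synthetic "species" by its spectro-temporal song
#' structure. Three structures are supported, mirroring the song types of
#' the common spring vocalists the analysis is aimed at: a constant-pitch
#' tonal whistle (thrush-like, e.g. 2500--5850 Hz), a complex
#' frequency-modulated sequence of chirps (wren-like, 3--9 kHz), and an
#' intermediate repeated two-note phrase (kinglet-like).
#'
#' @param name species label.
#' @param song_type `"tonal_whistle"`, `"fm_complex"` or `"phrase"`.
#' @param freq_range numeric `(low, high)` in Hz, `0 < low < high`.
#' @param syllable_duration seconds per syllable, > 0.
#' @param syllables_per_song syllable count per song bout.
#' @param source_level dB above the ambient noise floor.
#' @return object of class `species_template`.
#' @export
species_template <- function(name,
                             song_type = c("tonal_whistle", "fm_complex",
                                           "phrase"),
                             freq_range, syllable_duration,
                             syllables_per_song = 1, source_level = 20) {
  song_type <- match.arg(song_type)
  if (length(freq_range) != 2 || freq_range[1] <= 0 ||
      freq_range[1] >= freq_range[2]) {
    stop("freq_range must be (low, high) with 0 < low < high")
  }
  if (syllable_duration <= 0) stop("syllable_duration must be positive")
  if (syllables_per_song < 1) stop("syllables_per_song must be >= 1")
  structure(list(name = name, song_type = song_type,
                 freq_range = as.numeric(freq_range),
                 syllable_duration = syllable_duration,
                 syllables_per_song = as.integer(syllables_per_song),
                 source_level = source_level),
            class = "species_template")
}

# inter-syllable gap as a fraction of syllable duration
.syllable_gap_frac <- 0.3

.song_duration <- function(tpl) {
  k <- tpl$syllables_per_song
  k * tpl$syllable_duration +
    (k - 1) * .syllable_gap_frac * tpl$syllable_duration
}

#' Default three-species template set
#'
#' A whistler (simple tonal song, 2500--5850 Hz), a complex
#' frequency-modulated singer (3--9 kHz), and an intermediate two-note
#' phrase singer -- the three song structures the dawn-chorus analyses are
#' validated against.
#'
#' @return list of [species_template()] objects.
#' @export
default_species_templates <- function() {
  list(
    species_template("whistler", "tonal_whistle", c(2500, 5850),
                     syllable_duration = 0.6, syllables_per_song = 1,
                     source_level = 25),
    species_template("fm_singer", "fm_complex", c(3000, 9000),
                     syllable_duration = 0.15, syllables_per_song = 5,
                     source_level = 22),
    species_template("phraser", "phrase", c(2500, 6000),
                     syllable_duration = 0.2, syllables_per_song = 4,
                     source_level = 22)
  )
}

#' Configuration of a synthetic dawn-chorus season
#'
#' Encodes the study design the synthetic scenes emulate: a site at high
#' northern latitude, a late-winter-to-spring season, a step increase in
#' daily song rate on the arrival day of migrant songbirds, ambient noise,
#' and intermittent broadband wind/rain events. Daily song onsets follow a
#' homogeneous Poisson process per species within the 3-h dawn window at
#' `pre_arrival_rate` songs/h before `arrival_day` and `post_arrival_rate`
#' on and after it.
#'
#' The synthetic recorder is "calibrated" so that digital full scale maps
#' to `calibration_offset` dB SPL; the ambient floor of `noise_floor` dB re
#' full scale therefore sits at `noise_floor + calibration_offset` dB SPL
#' (positive absolute levels, as the index analysis requires).
#'
#' @param site list with `lat`, `lon` (degrees) and `utc_offset` (hours).
#' @param season `Date` vector `(first, last)`, inclusive.
#' @param arrival_day `Date` inside `season`.
#' @param pre_arrival_rate,post_arrival_rate songs per hour per species,
#'   >= 0.
#' @param species list of [species_template()]; default
#'   [default_species_templates()].
#' @param noise_floor ambient RMS level, dB re digital full scale.
#' @param spl_jitter_sd per-cell dB jitter of the ambient floor in
#'   SPL-domain scenes (sensor + background variability).
#' @param weather_events `NULL` or data.frame with columns `date`,
#'   `start_s`, `duration_s`, `low_hz`, `high_hz`, `level_db` (dB above
#'   ambient).
#' @param sample_rate Hz, >= 22050 so the 6300 Hz band (and the FM singer's
#'   9 kHz reach) are representable.
#' @param calibration_offset dB mapping full scale to absolute SPL.
#' @param seed integer master seed; per-day streams are derived from it.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(site = list(lat = 58.4563, lon = -135.8660,
                                     utc_offset = -8),
                         season = as.Date(c("2012-03-01", "2012-04-29")),
                         arrival_day = as.Date("2012-03-30"),
                         pre_arrival_rate = 2,
                         post_arrival_rate = 40,
                         species = default_species_templates(),
                         noise_floor = -60,
                         spl_jitter_sd = 0.5,
                         weather_events = NULL,
                         sample_rate = 22050,
                         calibration_offset = 90,
                         seed = 1) {
  season <- as.Date(season)
  arrival_day <- as.Date(arrival_day)
  if (length(season) != 2 || is.na(season[1]) || season[1] > season[2]) {
    stop("season must be a valid (first, last) date pair")
  }
  if (arrival_day < season[1] || arrival_day > season[2]) {
    stop("arrival_day must lie inside the season")
  }
  if (pre_arrival_rate < 0 || post_arrival_rate < 0) {
    stop("song rates must be non-negative")
  }
  if (sample_rate < 22050) {
    stop("sample_rate must be at least 22050 Hz")
  }
  for (tpl in species) {
    stopifnot(inherits(tpl, "species_template"))
    if (tpl$freq_range[2] >= sample_rate / 2) {
      stop("template '", tpl$name, "' exceeds the Nyquist frequency")
    }
  }
  if (!is.null(weather_events)) {
    need <- c("date", "start_s", "duration_s", "low_hz", "high_hz",
              "level_db")
    if (!all(need %in% names(weather_events))) {
      stop("weather_events needs columns: ", paste(need, collapse = ", "))
    }
    weather_events$date <- as.Date(weather_events$date)
  }
  structure(list(site = site, season = season, arrival_day = arrival_day,
                 pre_arrival_rate = pre_arrival_rate,
                 post_arrival_rate = post_arrival_rate,
                 species = species, noise_floor = noise_floor,
                 spl_jitter_sd = spl_jitter_sd,
                 weather_events = weather_events,
                 sample_rate = sample_rate,
                 calibration_offset = calibration_offset,
                 seed = as.integer(seed)),
            class = "scene_config")
}

.scene_day_seed <- function(config, date, stream = 0) {
  day_index <- as.numeric(as.Date(date) - config$season[1])
  # double arithmetic: products exceed 32-bit range long before 2^53
  as.integer((as.numeric(config$seed) * 1000003 + day_index * 7919 +
                stream * 500009) %% 2147483647)
}

.window_seconds <- 10800L  # 3-h dawn window

#' Draw the ground-truth call log for one day
#'
#' Poisson song onsets per species over the 3-h dawn window, at the pre- or
#' post-arrival rate depending on the date. Deterministic per
#' `(config, date)`: a per-day RNG stream is derived from the master seed.
#'
#' @param config a [scene_config()].
#' @param date a `Date` inside the season.
#' @return data.frame (`species`, `date`, `onset_s`, `duration_s`,
#'   `freq_low`, `freq_high`), sorted by onset.
#' @export
sample_call_log <- function(config, date) {
  date <- as.Date(date)
  if (date < config$season[1] || date > config$season[2]) {
    stop("date ", format(date), " outside season [",
         format(config$season[1]), ", ", format(config$season[2]), "]")
  }
  set.seed(.scene_day_seed(config, date))
  rate <- if (date >= config$arrival_day) config$post_arrival_rate
          else config$pre_arrival_rate
  hours <- .window_seconds / 3600
  rows <- list()
  for (tpl in config$species) {
    n <- stats::rpois(1, rate * hours)
    if (n == 0) next
    dur <- .song_duration(tpl)
    onset <- sort(stats::runif(n, 0, .window_seconds - dur))
    rows[[length(rows) + 1]] <- data.frame(
      species = tpl$name, date = date, onset_s = onset, duration_s = dur,
      freq_low = tpl$freq_range[1], freq_high = tpl$freq_range[2])
  }
  if (!length(rows)) {
    return(data.frame(species = character(0), date = as.Date(character(0)),
                      onset_s = numeric(0), duration_s = numeric(0),
                      freq_low = numeric(0), freq_high = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$onset_s), , drop = FALSE]
}

# ---- waveform rendering -------------------------------------------------

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

# one syllable as a linear chirp f1 -> f2 with a Hann envelope
.render_chirp <- function(f1, f2, dur, sr) {
  n <- max(2L, round(dur * sr))
  t <- (seq_len(n) - 1) / sr
  phase <- 2 * pi * (f1 * t + (f2 - f1) / (2 * dur) * t^2)
  sin(phase) * .hann(n)
}

# margin keeps syllable pitch away from the template band edges so that the
# spectral-confinement invariant (>= 90 % in-band energy) holds despite
# envelope sidebands
.pitch_range <- function(freq_range, margin = 0.08) {
  span <- freq_range[2] - freq_range[1]
  c(freq_range[1] + margin * span, freq_range[2] - margin * span)
}

.render_song <- function(tpl, sr) {
  pr <- .pitch_range(tpl$freq_range)
  k <- tpl$syllables_per_song
  gap_n <- round(.syllable_gap_frac * tpl$syllable_duration * sr)
  syl <- switch(tpl$song_type,
    tonal_whistle = {
      f0 <- stats::runif(1, pr[1], pr[2])
      lapply(seq_len(k), function(i) {
        n <- max(2L, round(tpl$syllable_duration * sr))
        t <- (seq_len(n) - 1) / sr
        # slight vibrato jitter around the constant pitch
        f <- f0 * (1 + 0.002 * sin(2 * pi * 6 * t + stats::runif(1, 0, 2 * pi)))
        sin(2 * pi * cumsum(f) / sr) * .hann(n)
      })
    },
    fm_complex = {
      lapply(seq_len(k), function(i) {
        fs <- sort(stats::runif(2, pr[1], pr[2]))
        if (stats::runif(1) < 0.5) fs <- rev(fs)
        .render_chirp(fs[1], fs[2], tpl$syllable_duration, sr)
      })
    },
    phrase = {
      fa <- stats::runif(1, pr[1], mean(pr))
      fb <- stats::runif(1, mean(pr), pr[2])
      lapply(seq_len(k), function(i) {
        f <- if (i %% 2 == 1) fa else fb  # repeated two-note motif
        n <- max(2L, round(tpl$syllable_duration * sr))
        sin(2 * pi * f * (seq_len(n) - 1) / sr) * .hann(n)
      })
    })
  gap <- rep(0, gap_n)
  parts <- vector("list", 2 * k - 1)
  parts[seq(1, 2 * k - 1, by = 2)] <- syl
  if (k > 1) parts[seq(2, 2 * k - 2, by = 2)] <- list(gap)
  unlist(parts)
}

# band-limited pink-ish noise burst (1/f amplitude slope inside the band)
.render_weather_burst <- function(n, sr, low_hz, high_hz) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- c(0:(n %/% 2), -(((n - 1) %/% 2):1)) * (sr / n)
  af <- abs(freqs)
  gain <- ifelse(af >= low_hz & af <= high_hz, 1 / sqrt(pmax(af, low_hz)), 0)
  burst <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  burst / stats::sd(burst)
}

#' Synthesize one day of dawn-chorus audio with ground truth
#'
#' Renders the 3-h dawn window for `date`: Gaussian ambient noise at the
#' configured floor, each ground-truth song as amplitude-enveloped
#' tonal/FM synthesis at `source_level` dB above ambient, and any
#' configured weather events as additive band-limited pink-noise bursts.
#' Output is bit-reproducible for the same `(config, date)`.
#'
#' @param config a [scene_config()].
#' @param date a `Date` inside the season.
#' @param duration_s optionally render only the first `duration_s` seconds
#'   of the window (desk-scale scenes for testing; default the full 10800
#'   s). The returned truth is restricted to songs fully inside the
#'   rendered span.
#' @return list with `samples`, `sample_rate`, `truth` (call-log
#'   data.frame), and `window_seconds` rendered.
#' @export
synthesize_day <- function(config, date, duration_s = NULL) {
  stopifnot(inherits(config, "scene_config"))
  date <- as.Date(date)
  truth <- sample_call_log(config, date)  # validates date, sets day seed
  sr <- config$sample_rate
  win_s <- if (is.null(duration_s)) .window_seconds
           else min(as.numeric(duration_s), .window_seconds)
  n <- round(win_s * sr)
  amb_rms <- 10^(config$noise_floor / 20)

  # fresh sub-stream so audio rendering does not disturb the event draw
  set.seed(.scene_day_seed(config, date, stream = 1))
  samples <- stats::rnorm(n, sd = amb_rms)

  keep <- truth$onset_s + truth$duration_s <= win_s
  truth <- truth[keep, , drop = FALSE]
  tpl_by_name <- stats::setNames(config$species,
                                 vapply(config$species, `[[`, "", "name"))
  if (nrow(truth)) {
    for (r in seq_len(nrow(truth))) {
      tpl <- tpl_by_name[[truth$species[r]]]
      song <- .render_song(tpl, sr)
      # scale so song RMS sits source_level dB above the ambient RMS
      song <- song * amb_rms * 10^(tpl$source_level / 20) /
        max(stats::sd(song), 1e-12)
      i0 <- round(truth$onset_s[r] * sr) + 1L
      idx <- i0:min(i0 + length(song) - 1L, n)
      samples[idx] <- samples[idx] + song[seq_along(idx)]
    }
  }

  ev <- config$weather_events
  if (!is.null(ev)) {
    ev <- ev[ev$date == date, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      if (ev$start_s[r] >= win_s) next
      m <- round(min(ev$duration_s[r], win_s - ev$start_s[r]) * sr)
      burst <- .render_weather_burst(m, sr, ev$low_hz[r], ev$high_hz[r])
      burst <- burst * amb_rms * 10^(ev$level_db[r] / 20)
      i0 <- round(ev$start_s[r] * sr) + 1L
      idx <- i0:(i0 + m - 1L)
      samples[idx] <- samples[idx] + burst
    }
  }
  list(samples = samples, sample_rate = sr, truth = truth,
       window_seconds = win_s)
}

#' Synthesize one day directly in the SPL domain
#'
#' Season-scale analyses (daily ACI, change-point detection) operate on the
#' one-second band-SPL matrix, so the generator can paint that matrix
#' directly instead of rendering and re-analysing hours of audio: ambient
#' floor plus per-cell dB jitter, each ground-truth song energy-added at
#' `source_level` dB above ambient into the bands its frequency range
#' covers for the seconds it spans, and weather events likewise across
#' their band extent. Shares its ground truth draw with [synthesize_day()].
#'
#' @inheritParams synthesize_day
#' @return list with `spec` (a [band_spectrogram()] covering the dawn
#'   window) and `truth`.
#' @export
synthesize_day_spl <- function(config, date) {
  stopifnot(inherits(config, "scene_config"))
  date <- as.Date(date)
  truth <- sample_call_log(config, date)
  set.seed(.scene_day_seed(config, date, stream = 2))

  centers <- third_octave_centers()
  base_spl <- config$noise_floor + config$calibration_offset
  n_sec <- .window_seconds
  values <- matrix(stats::rnorm(n_sec * length(centers), mean = base_spl,
                                sd = config$spl_jitter_sd),
                   nrow = n_sec)

  add_energy <- function(values, secs, bands, level_spl) {
    block <- values[secs, bands, drop = FALSE]
    values[secs, bands] <- 10 * log10(10^(block / 10) + 10^(level_spl / 10))
    values
  }
  if (nrow(truth)) {
    for (r in seq_len(nrow(truth))) {
      secs <- (floor(truth$onset_s[r]):
                 floor(truth$onset_s[r] + truth$duration_s[r])) + 1L
      secs <- secs[secs >= 1 & secs <= n_sec]
      bands <- which(centers >= truth$freq_low[r] &
                       centers <= truth$freq_high[r])
      if (!length(secs) || !length(bands)) next
      tpl_level <- base_spl +
        config$species[[match(truth$species[r],
          vapply(config$species, `[[`, "", "name"))]]$source_level
      values <- add_energy(values, secs, bands, tpl_level)
    }
  }
  ev <- config$weather_events
  if (!is.null(ev)) {
    ev <- ev[ev$date == date, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      secs <- (floor(ev$start_s[r]):
                 floor(ev$start_s[r] + ev$duration_s[r])) + 1L
      secs <- secs[secs >= 1 & secs <= n_sec]
      bands <- which(centers >= ev$low_hz[r] & centers <= ev$high_hz[r])
      if (!length(secs) || !length(bands)) next
      values <- add_energy(values, secs, bands, base_spl + ev$level_db[r])
    }
  }

  win <- dawn_window(config$site$lat, config$site$lon, date,
                     config$site$utc_offset)
  spec <- band_spectrogram(values, centers,
                           start_time = win$start -
                             config$site$utc_offset * 3600,
                           utc_offset = config$site$utc_offset,
                           weighting = "flat",
                           calibration_offset = config$calibration_offset)
  list(spec = spec, truth = truth, window = win)
}

#' Synthesize a full season
#'
#' Runs the per-day generator over every day of the season and aggregates
#' the ground truth and a daily weather covariate table (linear seasonal
#' temperature ramp plus Gaussian daily noise, wind/humidity/pressure
#' variates, and a weather-event indicator).
#'
#' @param config a [scene_config()].
#' @param output `"spl"` (default) for per-day band-SPL matrices, or
#'   `"audio"` to write one 16-bit PCM WAV per day.
#' @param dir directory for WAV output (required for `output = "audio"`);
#'   files are named `SITE_YYYYMMDD.wav`.
#' @param site_name file-name prefix for audio output.
#' @param duration_s passed to [synthesize_day()] for audio output.
#' @return list with `days` (named list, per-day generator output or WAV
#'   paths), `truth` (season call log), `weather` (daily covariates
#'   data.frame).
#' @export
synthesize_season <- function(config, output = c("spl", "audio"),
                              dir = NULL, site_name = "SITE",
                              duration_s = NULL) {
  stopifnot(inherits(config, "scene_config"))
  output <- match.arg(output)
  dates <- seq(config$season[1], config$season[2], by = "day")
  if (!length(dates)) stop("empty season")
  if (output == "audio" && is.null(dir)) {
    stop("dir is required for audio output")
  }

  days <- list()
  truths <- list()
  for (d in seq_along(dates)) {
    date <- dates[d]
    key <- format(date)
    if (output == "spl") {
      day <- synthesize_day_spl(config, date)
      days[[key]] <- day
      truths[[key]] <- day$truth
    } else {
      day <- synthesize_day(config, date, duration_s = duration_s)
      path <- file.path(dir, sprintf("%s_%s.wav", site_name,
                                     format(date, "%Y%m%d")))
      write_wav(day$samples, day$sample_rate, path)
      days[[key]] <- path
      truths[[key]] <- day$truth
    }
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL

  set.seed(as.integer((as.numeric(config$seed) * 48271) %% 2147483647))
  n <- length(dates)
  frac <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  has_event <- if (is.null(config$weather_events)) rep(FALSE, n) else
    dates %in% config$weather_events$date
  weather <- data.frame(
    date = dates,
    temperature = -2 + 10 * frac + stats::rnorm(n, sd = 1.5),
    wind = stats::rlnorm(n, meanlog = 1, sdlog = 0.4) +
      ifelse(has_event, 6, 0),
    humidity = pmin(100, pmax(30, 70 + stats::rnorm(n, sd = 8) +
                                ifelse(has_event, 15, 0))),
    pressure = 1010 + stats::rnorm(n, sd = 5),
    weather_event = has_event)
  list(days = days, truth = truth, weather = weather)
}
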