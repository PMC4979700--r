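#' Construct a band spectrogram object
#'
#' A `band_spectrogram` is the package's central container: a
#' seconds-by-bands matrix of sound pressure levels (dB), one row per elapsed
#' second (row k covers samples `[k*sr, (k+1)*sr)`), one column per nominal
#' one-third-octave band centre.
#'
#' @param values numeric matrix, seconds x bands, finite dB values.
#' @param band_centers nominal centre frequencies (Hz), strictly increasing,
#'   drawn from the standard nominal series.
#' @param start_time `POSIXct` (UTC) timestamp of the first row.
#' @param utc_offset hours to add to UTC for local civil time.
#' @param weighting `"flat"` or `"A"`; records whether the A-curve has
#'   already been applied to `values`.
#' @param calibration_offset dB added during conversion (0 = uncalibrated
#'   digital reference).
#' @return object of class `band_spectrogram`.
#' @export
band_spectrogram <- function(values, band_centers,
                             start_time = as.POSIXct("2000-01-01", tz = "UTC"),
                             utc_offset = 0,
                             weighting = c("flat", "A"),
                             calibration_offset = 0) {
  weighting <- match.arg(weighting)
  values <- as.matrix(values)
  band_centers <- as.numeric(band_centers)
  if (ncol(values) != length(band_centers)) {
    stop("values must have one column per band centre")
  }
  if (length(band_centers) > 1 && any(diff(band_centers) <= 0)) {
    stop("band_centers must be strictly increasing")
  }
  if (!all(band_centers %in% .nominal_third_octave_series)) {
    stop("band_centers must be drawn from the standard nominal series")
  }
  if (!all(is.finite(values))) stop("all SPL values must be finite")
  colnames(values) <- format(band_centers)
  structure(
    list(values = values, band_centers = band_centers,
         start_time = start_time, utc_offset = utc_offset,
         weighting = weighting, calibration_offset = calibration_offset),
    class = "band_spectrogram"
  )
}

#' @export
print.band_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<band_spectrogram> %d s x %d bands (%s-%s Hz), %s-weighted, cal %+g dB\n",
    nrow(x$values), length(x$band_centers), format(min(x$band_centers)),
    format(max(x$band_centers)), x$weighting, x$calibration_offset))
  cat("  start:", format(x$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      sprintf("UTC%+g\n", x$utc_offset))
  invisible(x)
}

#' @export
dim.band_spectrogram <- function(x) dim(x$values)

#' Convert waveform audio to calibrated one-third-octave band SPL
#'
#' Each full second of audio is transformed with an FFT and bin powers are
#' aggregated into the one-third-octave band containing the bin frequency
#' (band edges at `centre * 10^(+/-1/20)`). Column j of the result is
#' `10*log10` of the mean squared pressure within band j over that second,
#' plus `calibration_offset`. Zero-power cells are floored at `db_floor`
#' (default -120 dB re digital full scale) before calibration so silence
#' stays finite.
#'
#' @param samples numeric waveform, full scale = 1 (as from [read_wav()]).
#' @param sample_rate sampling rate in Hz.
#' @param calibration_offset dB added to every cell; supplies the absolute
#'   reference of the recorder's calibration chain (0 = uncalibrated).
#' @param weighting `"flat"` (default) or `"A"`; with `"A"` the standard
#'   A-curve gain at each band centre is added to that band's levels.
#' @param band_centers nominal band centres to compute; bands whose upper
#'   edge exceeds the Nyquist frequency are omitted with a warning.
#' @param start_time,utc_offset recording start metadata (see
#'   [band_spectrogram()]).
#' @param db_floor dB floor for zero-power cells, re digital full scale.
#' @return a [band_spectrogram()].
#' @export
audio_to_band_spl <- function(samples, sample_rate,
                              calibration_offset = 0,
                              weighting = c("flat", "A"),
                              band_centers = third_octave_centers(),
                              start_time = as.POSIXct("2000-01-01", tz = "UTC"),
                              utc_offset = 0,
                              db_floor = -120) {
  weighting <- match.arg(weighting)
  sr <- as.integer(round(sample_rate))
  if (length(samples) < sr) stop("audio shorter than 1 s")
  bad <- which(!is.finite(samples))
  if (length(bad)) stop("non-finite sample at index ", bad[1])

  edges <- third_octave_edges(band_centers)
  nyquist <- sr / 2
  supported <- edges[, "upper"] <= nyquist
  if (!any(supported)) stop("sample rate too low for any requested band")
  if (!all(supported)) {
    warning(sum(!supported), " band(s) above Nyquist-supported range omitted")
    band_centers <- band_centers[supported]
    edges <- edges[supported, , drop = FALSE]
  }

  n_sec <- length(samples) %/% sr
  freqs <- 0:(sr %/% 2)  # 1 Hz resolution on 1-s frames
  # map each FFT bin to the band whose passband contains it (tiny nominal-
  # series gaps between adjacent passbands get no band and are dropped)
  band_of <- rep(NA_integer_, length(freqs))
  for (j in seq_along(band_centers)) {
    band_of[freqs >= edges[j, "lower"] & freqs < edges[j, "upper"]] <- j
  }
  in_band <- !is.na(band_of)

  values <- matrix(db_floor, nrow = n_sec, ncol = length(band_centers))
  half <- sr %/% 2 + 1L
  # one-sided mean-square scaling: interior bins count twice (Parseval)
  scale2 <- c(1, rep(2, half - 2L), if (sr %% 2 == 0) 1 else 2) / sr^2
  grp <- band_of[in_band]
  sel <- which(in_band)
  for (k in seq_len(n_sec)) {
    x <- samples[((k - 1L) * sr + 1L):(k * sr)]
    p <- Mod(stats::fft(x)[1:half])^2 * scale2
    bp <- as.vector(rowsum(p[sel], grp))
    present <- sort(unique(grp))
    vals <- rep(0, length(band_centers))
    vals[present] <- bp
    values[k, ] <- ifelse(vals > 0, pmax(10 * log10(vals), db_floor), db_floor)
  }
  values <- values + calibration_offset
  if (weighting == "A") {
    values <- sweep(values, 2, a_weighting_db(band_centers), "+")
  }
  band_spectrogram(values, band_centers, start_time = start_time,
                   utc_offset = utc_offset, weighting = weighting,
                   calibration_offset = calibration_offset)
}

#' Hourly broadband A-weighted median levels (L50)
#'
#' For each clock hour (local civil time) the per-second broadband level is
#' the energy sum over all bands after A-weighting; L50 is the median of
#' those per-second levels. L50 characterises the background soundscape and
#' its dawn-chorus peak sits within about an hour of sunrise, which is what
#' motivates the dawn analysis window.
#'
#' @param spec a [band_spectrogram()]; the A-curve is applied internally for
#'   flat-weighted input.
#' @return data.frame with `hour_of_day` (0--23, local), `L50` (dB), and
#'   `n_seconds`; hours with no data are omitted.
#' @export
hourly_L50 <- function(spec) {
  stopifnot(inherits(spec, "band_spectrogram"))
  v <- spec$values
  if (spec$weighting == "flat") {
    v <- sweep(v, 2, a_weighting_db(spec$band_centers), "+")
  }
  broadband <- 10 * log10(rowSums(10^(v / 10)))
  local <- spec$start_time + spec$utc_offset * 3600 +
    (seq_len(nrow(v)) - 1)
  hour <- as.integer(format(local, "%H", tz = "UTC"))
  agg <- vapply(sort(unique(hour)), function(h) {
    x <- broadband[hour == h]
    c(h, stats::median(x), length(x))
  }, numeric(3))
  data.frame(hour_of_day = as.integer(agg[1, ]), L50 = agg[2, ],
             n_seconds = as.integer(agg[3, ]))
}

#' Write / read a band spectrogram as CSV
#'
#' ISO-8601 per-second timestamps (local civil time with explicit UTC
#' offset) in the first column, one column per nominal band centre, dB to
#' two decimals.
#'
#' @param spec a [band_spectrogram()].
#' @param path output path.
#' @return `path` invisibly; for the reader, a [band_spectrogram()].
#' @export
write_band_spl_csv <- function(spec, path) {
  stopifnot(inherits(spec, "band_spectrogram"))
  local <- spec$start_time + spec$utc_offset * 3600 +
    (seq_len(nrow(spec$values)) - 1)
  off <- spec$utc_offset
  off_str <- sprintf("%+03d:%02d", trunc(off), abs(round((off %% 1) * 60)))
  df <- data.frame(
    time = paste0(format(local, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), off_str),
    round(spec$values, 2), check.names = FALSE)
  names(df) <- c("time", format(spec$band_centers))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_band_spl_csv
#' @param weighting,calibration_offset metadata restored on read (the CSV
#'   itself stores only times and levels).
#' @export
read_band_spl_csv <- function(path, weighting = "flat",
                              calibration_offset = 0) {
  df <- utils::read.csv(path, check.names = FALSE)
  tstr <- df[[1]]
  off_str <- substring(tstr[1], 20)
  sgn <- if (substring(off_str, 1, 1) == "-") -1 else 1
  hh <- as.numeric(substring(off_str, 2, 3))
  mm <- as.numeric(substring(off_str, 5, 6))
  utc_offset <- sgn * (hh + mm / 60)
  local0 <- as.POSIXct(substring(tstr[1], 1, 19), tz = "UTC",
                       format = "%Y-%m-%dT%H:%M:%S")
  band_spectrogram(as.matrix(df[, -1, drop = FALSE]),
                   as.numeric(names(df)[-1]),
                   start_time = local0 - utc_offset * 3600,
                   utc_offset = utc_offset,
                   weighting = weighting,
                   calibration_offset = calibration_offset)
}
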