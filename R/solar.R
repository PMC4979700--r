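#' Local sunrise time from solar geometry
#'
#' Computes upper-limb sunrise (standard refraction, solar zenith 90.833
#' degrees) with the NOAA solar-position equations (Meeus-derived Julian-
#' century polynomials for solar longitude, declination, and the equation of
#' time), so no network almanac is needed. Accurate to about one minute at
#' mid latitudes.
#'
#' Civil timestamps in this package carry explicit user-supplied UTC
#' offsets; no daylight-saving database is consulted.
#'
#' @param lat,lon site coordinates in decimal degrees (east/north positive).
#'   `|lat|` should be below the polar circle; under polar day/night no
#'   sunrise exists.
#' @param date a `Date` (or string coercible to one).
#' @param utc_offset hours added to UTC for local civil time.
#' @return `POSIXct` local civil sunrise (clock reading; printed as UTC), or
#'   `NA` when the sun does not rise/set on that date (polar condition).
#' @examples
#' sunrise_time(58.4563, -135.8660, as.Date("2012-04-16"), utc_offset = -8)
#' @export
sunrise_time <- function(lat, lon, date, utc_offset) {
  date <- as.Date(date)
  stopifnot(is.finite(lat), is.finite(lon), abs(lat) <= 90)
  jd0 <- as.numeric(date) + 2440587.5  # Julian date at 00:00 UT
  # first pass at local solar noon, second pass at the sunrise estimate
  t_ut_min <- 720 - 4 * lon
  for (pass in 1:2) {
    sp <- .noaa_solar_params(jd0 + t_ut_min / 1440)
    cos_ha <- cos(.d2r(90.833)) / (cos(.d2r(lat)) * cos(.d2r(sp$decl))) -
      tan(.d2r(lat)) * tan(.d2r(sp$decl))
    if (!is.finite(cos_ha) || cos_ha < -1 || cos_ha > 1) {
      return(as.POSIXct(NA))  # polar day or night: no sunrise
    }
    ha <- .r2d(acos(cos_ha))
    noon_ut_min <- 720 - 4 * lon - sp$eqtime
    t_ut_min <- noon_ut_min - 4 * ha  # sunrise, minutes UT
  }
  local_min <- t_ut_min + 60 * utc_offset
  as.POSIXct(as.numeric(date) * 86400 + local_min * 60,
             origin = "1970-01-01", tz = "UTC")
}

.d2r <- function(x) x * pi / 180
.r2d <- function(x) x * 180 / pi

# Solar declination (deg) and equation of time (min) at a Julian date (UT).
.noaa_solar_params <- function(jd) {
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(.d2r(gmas)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(.d2r(2 * gmas)) * (0.019993 - 0.000101 * jc) +
    sin(.d2r(3 * gmas)) * 0.000289
  truelong <- gmls + eqctr
  omega <- 125.04 - 1934.136 * jc
  applong <- truelong - 0.00569 - 0.00478 * sin(.d2r(omega))
  mobliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- mobliq + 0.00256 * cos(.d2r(omega))
  decl <- .r2d(asin(sin(.d2r(obliq)) * sin(.d2r(applong))))
  vary <- tan(.d2r(obliq / 2))^2
  eqtime <- 4 * .r2d(vary * sin(2 * .d2r(gmls)) - 2 * ecc * sin(.d2r(gmas)) +
    4 * ecc * vary * sin(.d2r(gmas)) * cos(2 * .d2r(gmls)) -
    0.5 * vary^2 * sin(4 * .d2r(gmls)) -
    1.25 * ecc^2 * sin(2 * .d2r(gmas)))
  list(decl = decl, eqtime = eqtime)
}

#' Dawn-chorus analysis window for a site and date
#'
#' The window runs from 0.5 h before to 2.5 h after local sunrise (3 h
#' total), where broadband L50 peaks and songbird activity concentrates.
#'
#' @inheritParams sunrise_time
#' @return object of class `dawn_window` with `date`, `sunrise`, `start`,
#'   `end` (local civil `POSIXct`).
#' @export
dawn_window <- function(lat, lon, date, utc_offset) {
  sr <- sunrise_time(lat, lon, date, utc_offset)
  if (is.na(sr)) stop("no sunrise on ", format(as.Date(date)),
                      " at latitude ", lat, " (polar condition)")
  structure(list(date = as.Date(date), sunrise = sr,
                 start = sr - 0.5 * 3600, end = sr + 2.5 * 3600),
            class = "dawn_window")
}

#' @export
print.dawn_window <- function(x, ...) {
  cat(sprintf("<dawn_window> %s  sunrise %s  window [%s, %s)\n",
              format(x$date), format(x$sunrise, "%H:%M:%S", tz = "UTC"),
              format(x$start, "%H:%M:%S", tz = "UTC"),
              format(x$end, "%H:%M:%S", tz = "UTC")))
  invisible(x)
}

#' Restrict a band spectrogram to the dawn window
#'
#' Keeps the rows whose (local civil) second timestamps fall in
#' `[window$start, window$end)`; columns are unchanged. A warning is issued
#' when the recording only partially covers the window (the available rows
#' are returned) or not at all (empty result).
#'
#' @param spec a [band_spectrogram()].
#' @param window a [dawn_window()].
#' @return a [band_spectrogram()] with at most 10800 rows.
#' @export
extract_dawn_window <- function(spec, window) {
  stopifnot(inherits(spec, "band_spectrogram"),
            inherits(window, "dawn_window"))
  local0 <- as.numeric(spec$start_time) + spec$utc_offset * 3600
  sec_times <- local0 + (seq_len(nrow(spec$values)) - 1)
  keep <- sec_times >= as.numeric(window$start) &
    sec_times < as.numeric(window$end)
  n_expected <- round(as.numeric(window$end) - as.numeric(window$start))
  if (sum(keep) == 0) {
    warning("recording does not cover the dawn window; empty result")
  } else if (sum(keep) < n_expected) {
    warning(sprintf("recording covers only %d of %d window seconds",
                    sum(keep), n_expected))
  }
  first <- if (any(keep)) which(keep)[1] else 1L
  band_spectrogram(spec$values[keep, , drop = FALSE], spec$band_centers,
                   start_time = spec$start_time + (first - 1),
                   utc_offset = spec$utc_offset,
                   weighting = spec$weighting,
                   calibration_offset = spec$calibration_offset)
}
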