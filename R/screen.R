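#' Flag seconds obscured by wind, rain or anthropogenic noise
#'
#' Wind and rain concentrate energy at low frequencies, so a second is
#' flagged when its energy-summed level over the bands at or below
#' `low_band_ceiling` exceeds a robust baseline of that same quantity by at
#' least `threshold_db_above_baseline`. The baseline is the median of the
#' low-band series over the whole window by default; a rolling median
#' (`baseline_window_s`, odd number of seconds) can be used instead for
#' recordings much longer than the events of interest. The flagging is
#' baseline-relative, hence invariant to calibration offset, and a uniformly
#' elevated (constantly windy) day produces no flags.
#'
#' @param spec a [band_spectrogram()] (flat-weighted, full band range).
#' @param low_band_ceiling highest band centre (Hz) counted as
#'   weather-dominated; default 800.
#' @param threshold_db_above_baseline flag threshold in dB; default 10.
#' @param baseline_window_s `NULL` (default) for a whole-window median
#'   baseline, or an odd window length in seconds for a rolling median.
#' @return logical vector, one element per second, `TRUE` = obscured.
#' @export
flag_obscured_seconds <- function(spec, low_band_ceiling = 800,
                                  threshold_db_above_baseline = 10,
                                  baseline_window_s = NULL) {
  stopifnot(inherits(spec, "band_spectrogram"))
  low <- spec$band_centers <= low_band_ceiling
  if (!any(low)) stop("no bands at or below ", low_band_ceiling, " Hz")
  level <- 10 * log10(rowSums(10^(spec$values[, low, drop = FALSE] / 10)))
  if (is.null(baseline_window_s)) {
    baseline <- stats::median(level)
  } else {
    k <- as.integer(baseline_window_s)
    if (k %% 2 == 0) k <- k + 1L
    k <- min(k, if (length(level) %% 2 == 1) length(level)
             else length(level) - 1L)
    baseline <- stats::runmed(level, k, endrule = "median")
  }
  as.vector(level - baseline >= threshold_db_above_baseline)
}

#' Apply the 25 % obscuration exclusion rule
#'
#' A day is excluded when strictly more than 25 % of its window seconds are
#' flagged as obscured; a day at exactly 25 % is retained.
#'
#' @param date the day the mask belongs to.
#' @param flag_mask logical per-second mask from [flag_obscured_seconds()].
#' @param max_fraction exclusion threshold (default 0.25), exceeded strictly.
#' @return data.frame (one row) with `date`, `fraction_obscured`,
#'   `excluded`, and the mask in an attribute `flag_mask`.
#' @export
apply_exclusion_rule <- function(date, flag_mask, max_fraction = 0.25) {
  if (length(flag_mask) == 0) stop("empty flag mask")
  frac <- mean(flag_mask)
  out <- data.frame(date = as.Date(date), fraction_obscured = frac,
                    excluded = frac > max_fraction)
  attr(out, "flag_mask") <- flag_mask
  out
}

#' Restrict a band spectrogram to an analysis frequency range
#'
#' Index analysis is limited to frequencies above the anthropogenic-noise
#' range; with the standard nominal series and the defaults this keeps
#' exactly the 8 bands 1250, 1600, 2000, 2500, 3150, 4000, 5000 and 6300 Hz.
#'
#' @param spec a [band_spectrogram()].
#' @param min_freq,max_freq inclusive nominal-centre limits in Hz.
#' @return a [band_spectrogram()] with the retained columns.
#' @export
restrict_bands <- function(spec, min_freq = 1250, max_freq = 6300) {
  stopifnot(inherits(spec, "band_spectrogram"))
  keep <- spec$band_centers >= min_freq & spec$band_centers <= max_freq
  if (!any(keep)) {
    stop("no nominal band centres in [", min_freq, ", ", max_freq, "] Hz")
  }
  band_spectrogram(spec$values[, keep, drop = FALSE],
                   spec$band_centers[keep],
                   start_time = spec$start_time,
                   utc_offset = spec$utc_offset,
                   weighting = spec$weighting,
                   calibration_offset = spec$calibration_offset)
}
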