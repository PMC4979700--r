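#' Acoustic Complexity Index for one band
#'
#' For a per-second SPL series within one one-third-octave band,
#' \deqn{ACI_f = \frac{\sum_{t=1}^{n-1} |SPL_t - SPL_{t+1}|}{\sum_{t=1}^{n} SPL_t}.}
#' The numerator sums the absolute SPL differences between adjacent seconds
#' over the dawn window; the denominator is the total SPL of the band over
#' the window. The index is high for intermittent biotic sound (calls
#' alternating with silence between adjacent seconds) and low for steady
#' noise. It is evaluated on the dB SPL values directly; because a constant
#' dB offset changes only the denominator, calibrated absolute levels are
#' required for comparability across sites and years.
#'
#' Differences are never taken across gaps: if `gap_breaks` marks positions,
#' the adjacent-difference chain restarts after each marked index.
#'
#' @param series numeric per-second SPL values (dB) for one band; length
#'   at least 2, all finite, with a strictly positive sum.
#' @param gap_breaks optional integer positions `i` after which second `i+1`
#'   is not contiguous with second `i` (missing data in between).
#' @param band label used in error messages.
#' @return `ACI_f`, dimensionless and non-negative for positive SPL input.
#' @examples
#' aci_band(c(1, 3, 1, 3))  # (2+2+2)/(1+3+1+3) = 0.75
#' @export
aci_band <- function(series, gap_breaks = integer(0), band = "?") {
  if (length(series) < 2) stop("band ", band, ": series shorter than 2")
  if (!all(is.finite(series))) stop("band ", band, ": non-finite SPL")
  denom <- sum(series)
  if (denom <= 0) stop("band ", band, ": non-positive total SPL (",
                       format(denom), "); calibrated positive levels required")
  d <- abs(diff(series))
  if (length(gap_breaks)) {
    drop <- gap_breaks[gap_breaks >= 1 & gap_breaks < length(series)]
    if (length(drop)) d <- d[-drop]
  }
  sum(d) / denom
}

#' Daily Acoustic Complexity Index over all retained bands
#'
#' Computes `ACI_f` per band on a band-restricted dawn-window spectrogram
#' and sums over the `N` retained bands:
#' \deqn{ACI_{tot} = \sum_{f=1}^{N} ACI_f.}
#'
#' @param spec a [band_spectrogram()] already restricted to the analysis
#'   bands (see [restrict_bands()]) and to the dawn window.
#' @param date day label carried into the result.
#' @param gap_breaks passed to [aci_band()] for every band.
#' @return object of class `aci_result`: list with `date`, `per_band`
#'   (named numeric, one `ACI_f` per band centre), `aci_tot`, `n_seconds`,
#'   `band_count`.
#' @export
aci_total <- function(spec, date = as.Date(NA), gap_breaks = integer(0)) {
  stopifnot(inherits(spec, "band_spectrogram"))
  per_band <- vapply(seq_along(spec$band_centers), function(j) {
    aci_band(spec$values[, j], gap_breaks = gap_breaks,
             band = format(spec$band_centers[j]))
  }, numeric(1))
  names(per_band) <- format(spec$band_centers)
  structure(list(date = as.Date(date), per_band = per_band,
                 aci_tot = sum(per_band), n_seconds = nrow(spec$values),
                 band_count = length(per_band)),
            class = "aci_result")
}

#' @export
print.aci_result <- function(x, ...) {
  cat(sprintf("<aci_result> %s  ACI_tot = %.4f over %d bands, %d s\n",
              format(x$date), x$aci_tot, x$band_count, x$n_seconds))
  invisible(x)
}

#' Fine-resolution Acoustic Complexity Index on raw audio
#'
#' The classic STFT formulation: magnitudes on ~0.01-s frames with ~86.1 Hz
#' frequency bins; per bin, adjacent-frame absolute magnitude differences
#' are summed and normalised by that bin's magnitude sum over the whole
#' window, then summed over the bins inside `freq_range`. This resolution
#' tracks fast frequency-modulated song; the coarse one-second band index
#' tracks call/silence alternation.
#'
#' @param samples waveform (full scale 1).
#' @param sample_rate Hz.
#' @param window_s frame length in seconds (default 0.01, non-overlapping).
#' @param freq_resolution target FFT bin width in Hz (default 86.1; the FFT
#'   length is `round(sample_rate / freq_resolution)`, zero-padding the
#'   frame if needed).
#' @param freq_range bins with centre frequencies inside this range (Hz)
#'   enter the sum; default the 1250--6300 Hz analysis range.
#' @return scalar fine-resolution ACI.
#' @export
aci_fine <- function(samples, sample_rate, window_s = 0.01,
                     freq_resolution = 86.1, freq_range = c(1250, 6300)) {
  wlen <- max(2L, as.integer(round(window_s * sample_rate)))
  nfft <- max(wlen, as.integer(round(sample_rate / freq_resolution)))
  n_frames <- length(samples) %/% wlen
  if (n_frames < 2) stop("audio too short for two analysis frames")
  frames <- matrix(0, nrow = nfft, ncol = n_frames)
  frames[seq_len(wlen), ] <- samples[seq_len(wlen * n_frames)]
  mags <- Mod(stats::mvfft(frames))[seq_len(nfft %/% 2 + 1L), , drop = FALSE]
  freqs <- (0:(nfft %/% 2)) * (sample_rate / nfft)
  keep <- freqs >= freq_range[1] & freqs <= freq_range[2]
  m <- mags[keep, , drop = FALSE]
  num <- rowSums(abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]))
  den <- rowSums(m)
  # bins carrying no appreciable energy are numerical noise, not signal
  ok <- den > max(den) * 1e-9
  sum(num[ok] / den[ok])
}
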