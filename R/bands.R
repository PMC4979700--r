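#' Standard nominal one-third-octave band centre frequencies
#'
#' The base-10 nominal series (IEC 61260 style) restricted by default to the
#' 12.5--6300 Hz analysis range used for acoustic monitoring of songbird
#' habitat. Band edges sit at `centre * 10^(+/-1/20)` so each band spans one
#' third of a decade-based octave.
#'
#' @param min_freq,max_freq inclusive limits (Hz) on the nominal centres
#'   returned.
#' @return numeric vector of nominal centre frequencies in Hz, increasing.
#' @examples
#' third_octave_centers()            # 12.5 ... 6300, 28 bands
#' third_octave_centers(1250, 6300)  # the 8 ACI analysis bands
#' @export
third_octave_centers <- function(min_freq = 12.5, max_freq = 6300) {
  centers <- .nominal_third_octave_series
  centers[centers >= min_freq & centers <= max_freq]
}

# Nominal base-10 series; the full audible set so callers can request bands
# beyond the default monitoring range.
.nominal_third_octave_series <- c(
  12.5, 16, 20, 25, 31.5, 40, 50, 63, 80, 100,
  125, 160, 200, 250, 315, 400, 500, 630, 800, 1000,
  1250, 1600, 2000, 2500, 3150, 4000, 5000, 6300, 8000, 10000,
  12500, 16000, 20000
)

#' Band edges for nominal one-third-octave centres
#'
#' @param centers nominal centre frequencies (Hz).
#' @return two-column matrix (`lower`, `upper`) of passband edges in Hz,
#'   `centre * 10^(-1/20)` and `centre * 10^(1/20)`.
#' @export
third_octave_edges <- function(centers) {
  cbind(lower = centers * 10^(-1 / 20), upper = centers * 10^(1 / 20))
}

#' A-weighting gain at given frequencies
#'
#' Standard IEC 61672 A-curve, used to weight per-band levels before
#' broadband energy summation (e.g. for hourly L50 summaries).
#'
#' @param freq frequencies in Hz.
#' @return gain in dB (0 dB at 1 kHz by normalisation).
#' @export
a_weighting_db <- function(freq) {
  f2 <- freq^2
  ra <- (12194^2 * f2^2) /
    ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  20 * log10(ra) + 2.0
}
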