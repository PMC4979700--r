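# Independent oracles used by the tests. These deliberately use different
# algorithms / code paths than the package implementation they check.

# Exact posterior of the product-partition change-point model by full
# enumeration of all 2^(n-1) partitions (n <= ~12). The w-integral is done
# with stats::integrate (adaptive), not the fixed quadrature the sampler
# uses.
bcp_enumerate <- function(x, p0 = 0.2, w0 = 0.2) {
  n <- length(x)
  xbar <- mean(x)
  ssx <- sum(x^2)
  n_part <- 2^(n - 1)
  logw <- numeric(n_part)
  is_change <- matrix(FALSE, n_part, n)
  for (mask in 0:(n_part - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n - 1)]
    starts <- c(1, which(bits == 1) + 1)
    ends <- c(starts[-1] - 1, n)
    k <- length(starts) - 1
    S2b <- sum(vapply(seq_along(starts), function(j) {
      s <- sum(x[starts[j]:ends[j]])
      s^2 / (ends[j] - starts[j] + 1)
    }, numeric(1)))
    W <- max(ssx - S2b, 0)
    B <- max(S2b - n * xbar^2, 0)
    lp <- lbeta(k + 1, n - k) + pbeta(p0, k + 1, n - k, log.p = TRUE)
    iw <- stats::integrate(function(w) {
      w^(k / 2) * (W + B * w)^(-(n - 1) / 2)
    }, 0, w0, rel.tol = 1e-10)$value
    logw[mask + 1] <- lp + log(iw)
    is_change[mask + 1, which(bits == 1) + 1] <- TRUE
  }
  wts <- exp(logw - max(logw))
  wts <- wts / sum(wts)
  colSums(is_change * wts)
}

# NOAA "general solar position" low-accuracy sunrise (Fourier-series
# equation of time and declination), with one fixed-point refinement of
# the evaluation time. Returns sunrise in minutes UTC from midnight.
oracle_sunrise_utc_min <- function(lat, lon, date) {
  doy <- as.integer(strftime(date, "%j"))
  f <- function(hour_utc) {
    g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
    eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                          0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
    decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
      0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
      0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
    zen <- 90.833 * pi / 180
    latr <- lat * pi / 180
    cosha <- cos(zen) / (cos(latr) * cos(decl)) - tan(latr) * tan(decl)
    ha <- acos(pmin(1, pmax(-1, cosha))) * 180 / pi
    720 - 4 * (lon + ha) - eqtime
  }
  m <- f(12)
  f(m / 60)
}

# local-civil sunrise minutes from midnight for the implementation result
local_minutes <- function(ts, date) {
  (as.numeric(ts) - as.numeric(as.POSIXct(paste(date), tz = "UTC"))) / 60
}

# In-band mean-square power by direct FFT masking of the raw waveform
# (no framing, no band aggregation table) -- the band-energy oracle.
oracle_band_power <- function(x, sr, low, high) {
  n <- length(x)
  spec <- stats::fft(x)
  freqs <- c(0:(n %/% 2), -(((n - 1) %/% 2):1)) * (sr / n)
  mask <- abs(freqs) >= low & abs(freqs) < high
  sum(Mod(spec[mask])^2) / n^2
}

# flat band spectrogram helper for window/screen tests
flat_spec <- function(n_sec, centers = c(1250, 1600), value = 50,
                      start_local = "2012-04-16 00:00:00",
                      utc_offset = -8) {
  band_spectrogram(matrix(value, nrow = n_sec, ncol = length(centers)),
                   centers,
                   start_time = as.POSIXct(start_local, tz = "UTC") -
                     utc_offset * 3600,
                   utc_offset = utc_offset)
}

# a season shared by several test files; small but long enough for the
# association and diversity properties
shared_season <- local({
  cache <- new.env()
  function(seed = 401) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cfg <- scene_config(season = as.Date(c("2012-03-01", "2012-03-30")),
                          arrival_day = as.Date("2012-03-16"),
                          seed = seed)
      cache[[key]] <- list(config = cfg, season = synthesize_season(cfg))
    }
    cache[[key]]
  }
})
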