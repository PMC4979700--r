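#' Detector configuration for band-limited energy detection
#'
#' Parameters of a time-frequency energy detector for one species'
#' calls: the frequency band searched, the admissible call duration range,
#' the SNR threshold above the running background, and the STFT analysis
#' grid. Defaults for band and duration should come from the species'
#' song description (see [species_template()]).
#'
#' @param freq_range `(low, high)` Hz band searched.
#' @param min_duration,max_duration admissible event duration in seconds,
#'   `0 < min <= max`.
#' @param snr_threshold dB above the running background required to flag a
#'   frame; > 0.
#' @param min_gap events closer than this (seconds) are merged.
#' @param window_s,overlap STFT frame length (s) and fractional overlap.
#' @param background_window_s span (seconds) of the per-frequency-bin
#'   running-median background estimate.
#' @param species_label label stamped onto detections.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(freq_range, min_duration = 0.1,
                            max_duration = 2, snr_threshold = 10,
                            min_gap = 0.1, window_s = 0.05, overlap = 0.5,
                            background_window_s = 60,
                            species_label = "unknown") {
  if (length(freq_range) != 2 || freq_range[1] >= freq_range[2]) {
    stop("freq_range must be (low, high) with low < high")
  }
  if (min_duration <= 0 || min_duration > max_duration) {
    stop("need 0 < min_duration <= max_duration")
  }
  if (snr_threshold <= 0) stop("snr_threshold must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  structure(list(freq_range = as.numeric(freq_range),
                 min_duration = min_duration, max_duration = max_duration,
                 snr_threshold = snr_threshold, min_gap = min_gap,
                 window_s = window_s, overlap = overlap,
                 background_window_s = background_window_s,
                 species_label = species_label),
            class = "detector_config")
}

#' Short-time Fourier power spectrogram
#'
#' Hann-windowed frames at the configured length and overlap; power per
#' bin (one-sided).
#'
#' @param samples waveform (full scale 1).
#' @param sample_rate Hz.
#' @param window_s frame length in seconds.
#' @param overlap fractional frame overlap in `[0, 1)`.
#' @return list with `power` (bins x frames), `freqs` (Hz), `times` (frame
#'   onset seconds), `frame_step` (s).
#' @export
stft_spectrogram <- function(samples, sample_rate, window_s = 0.05,
                             overlap = 0.5) {
  wlen <- max(4L, as.integer(round(window_s * sample_rate)))
  step <- max(1L, as.integer(round(wlen * (1 - overlap))))
  n_frames <- (length(samples) - wlen) %/% step + 1L
  if (n_frames < 2) stop("audio too short for two STFT frames")
  win <- .hann(wlen)
  idx <- outer(seq_len(wlen), (seq_len(n_frames) - 1L) * step, "+")
  frames <- matrix(samples[idx], nrow = wlen) * win
  half <- wlen %/% 2 + 1L
  power <- Mod(stats::mvfft(frames))[seq_len(half), , drop = FALSE]^2
  list(power = power,
       freqs = (seq_len(half) - 1) * (sample_rate / wlen),
       times = (seq_len(n_frames) - 1L) * step / sample_rate,
       frame_step = step / sample_rate)
}

#' Band-limited energy detection of calls
#'
#' Flags STFT frames whose in-band energy exceeds the in-band
#' running-median background by at least the SNR threshold, merges
#' contiguous (and nearly contiguous) flagged frames into events, and
#' keeps events whose duration falls inside the configured range. The
#' background is a per-frequency-bin running median over
#' `background_window_s`, which scales with any global gain change, so
#' detections are gain-invariant.
#'
#' @param spec output of [stft_spectrogram()].
#' @param config a [detector_config()].
#' @return data.frame of detections: `onset_s`, `duration_s`, `peak_snr`
#'   (dB), `freq_low`, `freq_high`, `species` (zero rows when nothing is
#'   detected).
#' @export
detect_calls <- function(spec, config) {
  stopifnot(inherits(config, "detector_config"))
  if (config$freq_range[1] < min(spec$freqs) - 1e-9 ||
      config$freq_range[2] > max(spec$freqs) + 1e-9) {
    stop("detector band outside the spectrogram frequency range")
  }
  in_band <- spec$freqs >= config$freq_range[1] &
    spec$freqs <= config$freq_range[2]
  p <- spec$power[in_band, , drop = FALSE]
  n_frames <- ncol(p)
  # per-bin running median over background_window_s, evaluated on a coarse
  # 5-s grid (the background varies slowly; calls are sub-second)
  grid_step <- max(1L, as.integer(round(5 / spec$frame_step)))
  half_win <- max(1L, as.integer(round(config$background_window_s /
                                         spec$frame_step / 2)))
  grid <- seq(1L, n_frames, by = grid_step)
  bg_grid <- vapply(grid, function(g) {
    idx <- max(1L, g - half_win):min(n_frames, g + half_win)
    apply(p[, idx, drop = FALSE], 1, stats::median)
  }, numeric(nrow(p)))
  if (is.null(dim(bg_grid))) bg_grid <- matrix(bg_grid, nrow = nrow(p))
  nearest <- pmin(length(grid),
                  pmax(1L, as.integer(round((seq_len(n_frames) - 1) /
                                              grid_step)) + 1L))
  energy <- colSums(p)
  bg_energy <- pmax(colSums(bg_grid)[nearest], 1e-300)
  snr <- 10 * log10(pmax(energy, 1e-300) / bg_energy)
  flagged <- snr >= config$snr_threshold

  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_snr = numeric(0), freq_low = numeric(0),
                      freq_high = numeric(0), species = character(0))
  if (!any(flagged)) return(empty)

  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  seg <- data.frame(start = starts[on], end = ends[on])
  # merge runs separated by less than min_gap
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      gap_s <- (seg$start[i] - merged$end[nrow(merged)] - 1) *
        spec$frame_step
      if (gap_s < config$min_gap) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  onset <- spec$times[seg$start]
  dur <- (seg$end - seg$start + 1) * spec$frame_step
  peak <- vapply(seq_len(nrow(seg)),
                 function(i) max(snr[seg$start[i]:seg$end[i]]), numeric(1))
  keep <- dur >= config$min_duration & dur <= config$max_duration
  if (!any(keep)) return(empty)
  data.frame(onset_s = onset[keep], duration_s = dur[keep],
             peak_snr = peak[keep], freq_low = config$freq_range[1],
             freq_high = config$freq_range[2],
             species = config$species_label)
}

#' Evaluate detections against ground truth
#'
#' Greedy one-to-one matching: truth events (earliest first) are paired
#' with the closest unmatched detection whose onset lies within
#' `match_tolerance_s` and whose band overlaps the event's frequency
#' range. Matching is invariant to detection order (ties resolve to the
#' earliest onset). The false-negative rate is `FN / (TP + FN)`.
#'
#' @param detections data.frame from [detect_calls()]; an optional `date`
#'   column restricts matches to the same date.
#' @param truth ground-truth call log (see [sample_call_log()]).
#' @param match_tolerance_s onset tolerance in seconds.
#' @return object of class `detector_evaluation`: `true_positives`,
#'   `false_positives`, `false_negatives`, `fn_rate`, `precision`,
#'   `recall`.
#' @export
evaluate_detections <- function(detections, truth, match_tolerance_s = 1) {
  use_dates <- "date" %in% names(detections) && "date" %in% names(truth)
  det_date <- if (use_dates) as.Date(detections$date)
              else rep(as.Date("2000-01-01"), nrow(detections))
  tru_date <- if (use_dates) as.Date(truth$date)
              else rep(as.Date("2000-01-01"), nrow(truth))
  used <- rep(FALSE, nrow(detections))
  tp <- 0L
  ord <- order(tru_date, truth$onset_s)
  for (i in ord) {
    cand <- which(!used & det_date == tru_date[i] &
                    abs(detections$onset_s - truth$onset_s[i]) <=
                      match_tolerance_s &
                    detections$freq_low <= truth$freq_high[i] &
                    detections$freq_high >= truth$freq_low[i])
    if (!length(cand)) next
    d <- abs(detections$onset_s[cand] - truth$onset_s[i])
    best <- cand[order(d, detections$onset_s[cand])][1]
    used[best] <- TRUE
    tp <- tp + 1L
  }
  fp <- sum(!used)
  fn <- nrow(truth) - tp
  structure(list(true_positives = tp, false_positives = fp,
                 false_negatives = fn,
                 fn_rate = if (tp + fn > 0) fn / (tp + fn) else 0,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = "detector_evaluation")
}

#' @export
print.detector_evaluation <- function(x, ...) {
  cat(sprintf(
    "<detector_evaluation> TP %d  FP %d  FN %d  recall %.3f  precision %.3f  FN-rate %.3f\n",
    x$true_positives, x$false_positives, x$false_negatives,
    x$recall, x$precision, x$fn_rate))
  invisible(x)
}

#' Correct daily counts for the detector's false-negative rate
#'
#' The standard inverse-sensitivity estimator: with a fraction `fn_rate`
#' of true events missed, the corrected abundance is
#' `count / (1 - fn_rate)`.
#'
#' @param daily_counts named numeric vector (or data.frame with `date`,
#'   `count`) of true detections per date.
#' @param fn_rate annual false-negative rate in `[0, fn_cap)`.
#' @param fn_cap refuse correction above this rate (default 0.95; a
#'   detector missing that much is unreliable).
#' @return same shape as the input with corrected counts.
#' @export
correct_counts <- function(daily_counts, fn_rate, fn_cap = 0.95) {
  if (fn_rate < 0 || fn_rate >= 1) stop("fn_rate must be in [0, 1)")
  if (fn_rate >= fn_cap) {
    stop("fn_rate ", format(fn_rate), " exceeds the reliability cap ",
         format(fn_cap))
  }
  if (is.data.frame(daily_counts)) {
    daily_counts$corrected <- daily_counts$count / (1 - fn_rate)
    daily_counts
  } else {
    daily_counts / (1 - fn_rate)
  }
}

#' Write detections as a Raven-style selection table
#'
#' Tab-separated selection table with the conventional column names so
#' detections can be reviewed in standard bioacoustics tools.
#'
#' @param detections data.frame from [detect_calls()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(detections, path) {
  df <- data.frame(
    Selection = seq_len(nrow(detections)),
    View = "Spectrogram 1", Channel = 1,
    `Begin Time (s)` = detections$onset_s,
    `End Time (s)` = detections$onset_s + detections$duration_s,
    `Low Freq (Hz)` = detections$freq_low,
    `High Freq (Hz)` = detections$freq_high,
    Score = detections$peak_snr,
    Species = detections$species,
    check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
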