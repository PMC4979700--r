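#' Bayesian change-point analysis of a daily series
#'
#' Fits the Barry--Hartigan product-partition model by Gibbs sampling: the
#' series is partitioned into contiguous blocks of constant mean, with a
#' uniform `U(0, p0)` prior on the per-position change probability and a
#' uniform `U(0, w0)` prior on the noise-to-total variance ratio
#' `w = sigma^2 / (sigma^2 + sigma0^2)`. `posterior_prob[i]` is the fraction
#' of post-burn-in sweeps in which a new block begins at position `i`
#' (`posterior_prob[1]` is 0 by convention); `posterior_mean` is the
#' Rao-Blackwellised per-position estimate of the underlying mean,
#' shrunk toward the grand mean by the conditional posterior weight of `w`.
#'
#' Excluded or missing days must be dropped before fitting (the sampler
#' treats the series as contiguous); carry the dates alongside.
#'
#' @param series numeric daily values (e.g. `ACI_tot`), length >= 3, no
#'   missing values.
#' @param iterations post-burn-in MCMC sweeps kept for the posterior
#'   summaries (default 10000).
#' @param burn_in initial sweeps run and discarded first (default 5000).
#' @param seed integer seed for reproducibility (sets R's RNG); `NULL`
#'   leaves the RNG state alone.
#' @param p0,w0 upper limits of the uniform priors (default 0.2 each).
#' @param dates optional `Date` vector aligned with `series`.
#' @return object of class `changepoint_result`: `dates`, `series`,
#'   `posterior_mean`, `posterior_prob`, `mcmc` (iterations, burn_in, seed,
#'   p0, w0).
#' @export
bcp_fit <- function(series, iterations = 10000, burn_in = 5000,
                    seed = NULL, p0 = 0.2, w0 = 0.2, dates = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3) stop("series must have at least 3 points")
  if (anyNA(series) || !all(is.finite(series))) {
    stop("series contains missing or non-finite values; drop excluded days first")
  }
  if (iterations <= 0 || burn_in < 0) stop("iterations must be positive")
  if (!is.null(dates) && length(dates) != n) {
    stop("dates must align with series")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (stats::var(series) == 0) {
    # degenerate flat series: posterior mass sits on the null partition
    res <- list(posterior_prob = rep(0, n), posterior_mean = series)
  } else {
    gl <- gauss_legendre(48, 0, w0)
    res <- .bcp_gibbs_cpp(series, iterations + burn_in, burn_in,
                          p0, w0, gl$nodes, gl$weights)
  }
  structure(list(dates = dates, series = series,
                 posterior_mean = res$posterior_mean,
                 posterior_prob = res$posterior_prob,
                 mcmc = list(iterations = iterations, burn_in = burn_in,
                             seed = seed, p0 = p0, w0 = w0)),
            class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf(
    "<changepoint_result> n = %d, max P(change) = %.3f at position %d\n",
    length(x$series), max(x$posterior_prob), which.max(x$posterior_prob)))
  invisible(x)
}

#' Gauss-Legendre quadrature nodes and weights
#'
#' Golub--Welsch construction (eigendecomposition of the Jacobi matrix),
#' rescaled to `[a, b]`. Used for the one-dimensional prior integral of the
#' change-point model's variance-ratio parameter.
#'
#' @param m number of nodes.
#' @param a,b integration limits.
#' @return list with `nodes` and `weights`.
#' @export
gauss_legendre <- function(m, a = -1, b = 1) {
  i <- seq_len(m - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, m, m)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = (nodes[ord] + 1) / 2 * (b - a) + a,
       weights = weights[ord] * (b - a) / 2)
}

#' Detect the spring transition from change-point output
#'
#' Finds the earliest (strict) local maximum of the posterior change
#' probability that exceeds `threshold` (plateaus resolve to their earliest
#' index; a boundary counts as lower than its neighbour). The fold-change
#' is that day's value divided by the mean of the values on the retained
#' days strictly before it, limited to the most recent `baseline_days`.
#'
#' @param result a [bcp_fit()] result.
#' @param threshold posterior probability defining a "high" probability of
#'   change (default 0.5, exceeded strictly).
#' @param baseline_days how many preceding days enter the fold-change
#'   baseline (default `Inf` = all preceding retained days).
#' @return object of class `transition`: `detected` (logical), and when
#'   detected `index`, `date`, `prob`, `fold_change`, `baseline_days_used`.
#' @export
detect_transition <- function(result, threshold = 0.5, baseline_days = Inf) {
  stopifnot(inherits(result, "changepoint_result"))
  p <- result$posterior_prob
  r <- rle(p)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nruns <- length(r$values)
  idx <- NA_integer_
  for (m in seq_len(nruns)) {
    higher_prev <- m > 1 && r$values[m - 1] > r$values[m]
    higher_next <- m < nruns && r$values[m + 1] > r$values[m]
    if (!higher_prev && !higher_next && r$values[m] > threshold) {
      idx <- as.integer(starts[m])
      break
    }
  }
  if (is.na(idx)) {
    return(structure(list(detected = FALSE, threshold = threshold),
                     class = "transition"))
  }
  base_idx <- seq_len(idx - 1)
  if (is.finite(baseline_days)) {
    base_idx <- utils::tail(base_idx, baseline_days)
  }
  fold <- if (length(base_idx)) {
    result$series[idx] / mean(result$series[base_idx])
  } else NA_real_
  structure(list(detected = TRUE, index = idx,
                 date = if (!is.null(result$dates)) result$dates[idx] else NULL,
                 prob = p[idx], fold_change = fold,
                 baseline_days_used = length(base_idx),
                 threshold = threshold),
            class = "transition")
}

#' @export
print.transition <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("<transition> none detected (no peak above %.2f)\n",
                x$threshold))
  } else {
    cat(sprintf(
      "<transition> position %d%s  P(change) = %.2f  fold-change = %.2f over %d baseline day(s)\n",
      x$index,
      if (!is.null(x$date)) paste0(" (", format(x$date), ")") else "",
      x$prob, x$fold_change, x$baseline_days_used))
  }
  invisible(x)
}
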