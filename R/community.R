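#' Vocalization diversity indices for one sample
#'
#' Species richness, Shannon diversity (natural log, nats) and
#' Gini-Simpson diversity from a table of per-species (or pseudo-species)
#' vocalization counts:
#' `H = -sum(p_i * log(p_i))`, `D = 1 - sum(p_i^2)` with `p_i` the count
#' proportions. All three are invariant to label order and to scaling the
#' total count.
#'
#' @param counts non-negative integer counts, optionally named by species
#'   label; or a data.frame with columns `species` and `count`.
#' @return data.frame (one row) with `richness`, `shannon`, `simpson`.
#' @examples
#' diversity_indices(c(a = 10, b = 10, c = 10, d = 10))  # H = log(4)
#' @export
diversity_indices <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- tapply(counts$count, counts$species, sum)
  }
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("total count must be positive")
  p <- counts / sum(counts)
  data.frame(richness = length(p),
             shannon = -sum(p * log(p)),
             simpson = 1 - sum(p^2))
}

#' Association between daily ACI and a predictor
#'
#' Ordinary least squares of daily `ACI_tot` on a per-day predictor (call
#' counts of one species, temperature, wind, ...), optionally after
#' centering both variables within date groups when several analysis
#' windows share a date. The scientific claim carried by this model is the
#' sign and strength of the association -- a positive slope for call
#' counts is what licenses ACI as an activity index.
#'
#' @param aci numeric daily `ACI_tot` values.
#' @param predictor numeric per-day values, same length.
#' @param dates optional grouping dates for `grouping =
#'   "within_date_centered"`.
#' @param grouping `"none"` (default) or `"within_date_centered"`.
#' @return object of class `association_result`: `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `r_squared`, `p_value`, `n`, `grouping`.
#' @export
associate_aci <- function(aci, predictor, dates = NULL,
                          grouping = c("none", "within_date_centered")) {
  grouping <- match.arg(grouping)
  ok <- is.finite(aci) & is.finite(predictor)
  aci <- aci[ok]
  predictor <- predictor[ok]
  if (length(aci) < 3) stop("need at least 3 paired non-missing days")
  if (stats::var(predictor) == 0) stop("zero-variance predictor")
  if (grouping == "within_date_centered") {
    if (is.null(dates)) stop("dates required for within-date centering")
    dates <- dates[ok]
    aci <- aci - stats::ave(aci, dates)
    predictor <- predictor - stats::ave(predictor, dates)
  }
  fit <- stats::lm(aci ~ predictor)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 slope_se = s$coefficients[2, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 intercept_se = s$coefficients[1, 2],
                 r_squared = s$r.squared,
                 p_value = s$coefficients[2, 4],
                 n = length(aci), grouping = grouping),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> slope %.4g +/- %.4g, R^2 = %.3f, p = %.3g, n = %d%s\n",
    x$slope, x$slope_se, x$r_squared, x$p_value, x$n,
    if (x$grouping != "none") paste0(" (", x$grouping, ")") else ""))
  invisible(x)
}
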