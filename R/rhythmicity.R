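#' Autocorrelogram of an activity series
#'
#' Computes the mean-centered, variance-normalized autocorrelation
#' \deqn{r_k = \frac{\sum_{i=1}^{N-k}(y_i-\bar y)(y_{i+k}-\bar y)}
#'                  {\sum_{i=1}^{N}(y_i-\bar y)^2}}
#' for lags \eqn{k = 0 \ldots} `max_lag_hours`. The lag-independent
#' denominator guarantees \eqn{r_0 = 1} and \eqn{|r_k| \le 1}. Circadian
#' behaviour shows as a peak near the 24 h lag.
#'
#' @param series An `activity_series`; not constant, and covering at least
#'   twice `max_lag_hours` of data.
#' @param max_lag_hours Maximum lag, in hours (default 48).
#' @return Object of class `autocorrelogram`: a list with `acf` (correlation
#'   by lag, starting at lag 0), `lag_hours`, `n_bins` and `bin_width`.
#' @examples
#' s <- simulate_forager(forager_params(amplitude = 0.9, seed = 1))$series
#' ac <- autocorrelogram(rebin(s, 30))
#' @export
autocorrelogram <- function(series, max_lag_hours = 48) {
  stopifnot(inherits(series, "activity_series"))
  y <- as.numeric(series$counts)
  n <- length(y)
  max_lag_bins <- as.integer(round(max_lag_hours * 60 / series$bin_width))
  if (n * series$bin_width < 2 * max_lag_hours * 60)
    stop("series too short: need at least ", 2 * max_lag_hours,
         " h of data for a ", max_lag_hours, " h maximum lag")
  if (stats::var(y) == 0)
    stop("constant series: autocorrelation undefined (zero variance)")
  # stats::acf with demean = TRUE uses divisor-N sums in numerator and
  # denominator, so the ratio equals the direct-sum definition above.
  r <- as.numeric(stats::acf(y, lag.max = max_lag_bins, plot = FALSE,
                             demean = TRUE)$acf)
  structure(
    list(acf = r,
         lag_hours = (0:max_lag_bins) * series$bin_width / 60,
         n_bins = n,
         bin_width = series$bin_width),
    class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("<autocorrelogram> %d bins of %d min, lags 0-%.1f h\n",
              x$n_bins, x$bin_width, max(x$lag_hours)))
  invisible(x)
}

#' Rhythm strength statistic from an autocorrelogram
#'
#' Selects the circadian peak of the autocorrelogram — the highest interior
#' local maximum within the lag search window (default 18–30 h), falling back
#' to the window maximum when no interior local maximum exists — and scales
#' its height by the 95 % white-noise confidence line \eqn{2/\sqrt{N}}, where
#' N is the number of bins analyzed. The ratio is the rhythmicity statistic
#' (RS); by convention RS > 1.5 indicates rhythmic behaviour and RS ≤ 1.5 is
#' classified arrhythmic. The lag of the selected peak estimates the
#' free-running period.
#'
#' @param acf An `autocorrelogram` (or a bare numeric acf vector, in which
#'   case `n_bins` and `bin_width` must be given).
#' @param search_window Numeric length-2 lag window in hours to search for
#'   the circadian peak (default `c(18, 30)`).
#' @param rs_threshold Classification threshold (default 1.5; inclusive on
#'   the arrhythmic side).
#' @param n_bins,bin_width Only needed when `acf` is a bare numeric vector.
#' @return Object of class `rhythmicity_result` with fields `acf`, `n_bins`,
#'   `confidence_line`, `peak_lag_hours`, `peak_height`, `rs`, `label`,
#'   `estimated_period_hours`.
#' @export
rhythm_statistic <- function(acf, search_window = c(18, 30),
                             rs_threshold = 1.5,
                             n_bins = NULL, bin_width = NULL) {
  if (inherits(acf, "autocorrelogram")) {
    r <- acf$acf; lag_h <- acf$lag_hours; n_bins <- acf$n_bins
  } else {
    if (is.null(n_bins) || is.null(bin_width))
      stop("'n_bins' and 'bin_width' are required with a bare acf vector")
    r <- as.numeric(acf)
    lag_h <- (seq_along(r) - 1) * bin_width / 60
  }
  if (length(search_window) != 2L || diff(search_window) <= 0)
    stop("'search_window' must be an increasing (lo, hi) pair of hours")
  if (max(lag_h) < search_window[2])
    stop("autocorrelogram covers lags up to ", max(lag_h),
         " h; search window extends to ", search_window[2], " h")
  in_win <- which(lag_h >= search_window[1] & lag_h <= search_window[2])
  # interior local maxima: r[k-1] <= r[k] >= r[k+1], excluding series ends
  cand <- in_win[in_win > 1L & in_win < length(r)]
  is_locmax <- r[cand] >= r[cand - 1L] & r[cand] >= r[cand + 1L]
  sel <- if (any(is_locmax)) {
    loc <- cand[is_locmax]
    loc[which.max(r[loc])]
  } else in_win[which.max(r[in_win])]
  conf <- 2 / sqrt(n_bins)
  rs <- r[sel] / conf
  structure(
    list(acf = r, n_bins = n_bins, confidence_line = conf,
         peak_lag_hours = lag_h[sel], peak_height = r[sel], rs = rs,
         label = if (rs <= rs_threshold) "arrhythmic" else "rhythmic",
         estimated_period_hours = lag_h[sel],
         rs_threshold = rs_threshold,
         search_window = search_window,
         constant_series = FALSE),
    class = "rhythmicity_result")
}

#' @export
print.rhythmicity_result <- function(x, ...) {
  cat(sprintf("<rhythmicity_result> RS = %.3f (%s)\n", x$rs, x$label))
  if (x$constant_series) {
    cat("  constant series: autocorrelation undefined, classified arrhythmic\n")
  } else {
    cat(sprintf("  peak %.3f at lag %.1f h; 95%% line 2/sqrt(%d) = %.4f\n",
                x$peak_height, x$peak_lag_hours, x$n_bins, x$confidence_line))
    cat(sprintf("  estimated period: %.1f h\n", x$estimated_period_hours))
  }
  invisible(x)
}

#' Rhythmicity analysis of an activity series
#'
#' Convenience wrapper: rebins the series to the analysis bin width
#' (default 30 min), computes the autocorrelogram, and derives the
#' rhythmicity statistic. A constant (zero-variance) series, for which the
#' autocorrelation is undefined, is classified arrhythmic with `rs = 0` and
#' `constant_series = TRUE`.
#'
#' @param series An `activity_series` at any bin width dividing the analysis
#'   width.
#' @param analysis_bin_width Bin width for analysis, minutes (default 30).
#' @param max_lag_hours Maximum autocorrelation lag (default 48 h).
#' @inheritParams rhythm_statistic
#' @return A `rhythmicity_result`.
#' @export
rhythmicity <- function(series, analysis_bin_width = 30,
                        max_lag_hours = 48, search_window = c(18, 30),
                        rs_threshold = 1.5) {
  s <- rebin(series, analysis_bin_width)
  if (stats::var(as.numeric(s$counts)) == 0) {
    return(structure(
      list(acf = NULL, n_bins = length(s$counts),
           confidence_line = 2 / sqrt(length(s$counts)),
           peak_lag_hours = NA_real_, peak_height = NA_real_, rs = 0,
           label = "arrhythmic", estimated_period_hours = NA_real_,
           rs_threshold = rs_threshold, search_window = search_window,
           constant_series = TRUE),
      class = "rhythmicity_result"))
  }
  ac <- autocorrelogram(s, max_lag_hours = max_lag_hours)
  rhythm_statistic(ac, search_window = search_window,
                   rs_threshold = rs_threshold)
}

#' Proportion of arrhythmic subjects in a group
#'
#' @param results Non-empty list of `rhythmicity_result` objects.
#' @return A list with `percent` (100 × arrhythmic/total), `n_arrhythmic`
#'   and `n`.
#' @export
arrhythmic_proportion <- function(results) {
  if (!length(results)) stop("empty collection of rhythmicity results")
  stopifnot(all(vapply(results, inherits, TRUE, "rhythmicity_result")))
  lab <- vapply(results, function(r) r$label, "")
  list(percent = 100 * sum(lab == "arrhythmic") / length(lab),
       n_arrhythmic = sum(lab == "arrhythmic"),
       n = length(lab))
}
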