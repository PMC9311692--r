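# FFT dominant-frequency / movement-period analysis. The dominant frequency
# of a channel is read off the one-sided amplitude spectrum: if the
# maximum-power bin (DC excluded) has 1-based index n among N transformed
# samples at sampling frequency fs, then
#     f = (n - 1) * fs / N   and   T = 1 / f.

#' Period estimate from a spectral peak
#'
#' Builds the dominant-frequency/period record from a 1-based FFT bin index.
#' Useful directly when the peak bin is known; [dominant_frequency()] finds
#' the bin from a signal.
#'
#' @param n 1-based index of the maximum-power bin in the one-sided spectrum
#'   (the DC bin has index 1, so `n > 1`).
#' @param N Number of samples transformed.
#' @param fs Sampling frequency (Hz).
#' @return An object of class `"period_estimate"` with fields `n`, `N`,
#'   `fs`, `f` (Hz) and `T` (s).
#' @examples
#' period_estimate(23, 200, 20)  # f = 2.2 Hz, T ~ 0.45 s
#' @export
period_estimate <- function(n, N, fs) {
  stopifnot(N >= 4, fs > 0, n == round(n))
  if (n <= 1 || n > floor(N / 2) + 1) {
    stop("bin index n must satisfy 1 < n <= N/2 + 1 (DC excluded)", call. = FALSE)
  }
  f <- (n - 1) * fs / N
  structure(list(n = as.integer(n), N = as.integer(N), fs = fs,
                 f = f, T = 1 / f),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("Dominant frequency: bin n = %d of N = %d at fs = %g Hz -> f = %g Hz, T = %.3g s\n",
              x$n, x$N, x$fs, x$f, x$T))
  invisible(x)
}

#' Dominant frequency of a signal
#'
#' Transforms the channel with the FFT and reports the non-DC bin of highest
#' one-sided power. The DC bin is excluded because static orientation
#' offsets would otherwise always dominate; ties break toward the lower bin.
#' No taper is applied.
#'
#' @param x Numeric signal, length >= 4, not constant.
#' @param fs Sampling frequency (Hz).
#' @return A [period_estimate()].
#' @examples
#' x <- sin(2 * pi * 2.3 * seq_len(200) / 20)  # 2.3 Hz at 20 Hz for 10 s
#' dominant_frequency(x, 20)$f                 # 2.3
#' @export
dominant_frequency <- function(x, fs) {
  stopifnot(is.numeric(x), fs > 0)
  N <- length(x)
  if (N < 4) stop("need at least 4 samples", call. = FALSE)
  if (max(x) == min(x)) {
    stop("constant channel has no non-DC spectral peak", call. = FALSE)
  }
  amp <- Mod(stats::fft(x))[seq_len(floor(N / 2) + 1)]
  n <- which.max(amp[-1]) + 1L  # which.max takes the first (lower) bin on ties
  period_estimate(n, N, fs)
}

#' Recommend a classification time window from movement periods
#'
#' The classification window must span at least one full movement period of
#' the slowest behavior, so the base recommendation is the maximum observed
#' period rounded up to a whole second. A candidate ladder of the maximum
#' period rounded up 1x, 2x and 5x is also returned for window-size
#' comparisons (2.15 s -> 3, 5, 11 s).
#'
#' @param periods A list of [period_estimate()] objects and/or numeric
#'   periods in seconds (e.g. video-observed bite intervals).
#' @param multipliers Multipliers for the candidate ladder.
#' @return List with `max_period` (s), `window` (s, `ceiling(max_period)`)
#'   and `ladder` (integer seconds, `ceiling(multipliers * max_period)`).
#' @examples
#' recommend_window(list(2.15))$ladder  # 3 5 11
#' @export
recommend_window <- function(periods, multipliers = c(1, 2, 5)) {
  if (!is.list(periods)) periods <- as.list(periods)
  if (length(periods) == 0) stop("no periods supplied", call. = FALSE)
  ts <- vapply(periods, function(p) {
    if (inherits(p, "period_estimate")) p$T else as.numeric(p)
  }, numeric(1))
  if (any(!is.finite(ts)) || any(ts <= 0)) {
    stop("periods must be positive and finite", call. = FALSE)
  }
  max_period <- max(ts)
  list(max_period = max_period,
       window = as.integer(ceiling(max_period)),
       ladder = as.integer(ceiling(multipliers * max_period)))
}
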