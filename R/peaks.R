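#' Detect oscillation peaks in an intensity trace
#'
#' Finds strict local maxima whose topographic prominence is at least
#' `min_prominence_fraction` of the trace's intensity range (computed after
#' optional linear detrending), then greedily enforces a minimum peak
#' separation, keeping the more prominent peak of any conflicting pair.
#' Prominence of a peak is its height above the higher of the two minima
#' separating it from taller terrain on either side -- robust against
#' counting noise wiggles riding on a pulse.
#'
#' The defaults (relative prominence 0.2; minimum separation 30 s for
#' traces in seconds, 0.5 time units for model traces) suit reporter pulse
#' trains with periods of roughly 60-200 s sampled every few seconds.
#'
#' @param trace an [intensity_trace()].
#' @param min_prominence_fraction required prominence as a fraction of the
#'   (detrended) trace range, in (0, 1).
#' @param min_distance minimum separation between accepted peaks, in trace
#'   time units.  Default 30 (s) or 0.5 (model units).
#' @param detrend subtract a least-squares line before detection.
#' @param min_prominence_abs optional absolute prominence floor (same units
#'   as the intensity); used by depletion scenarios to reference a common
#'   amplitude scale across conditions.
#' @return Object of class `peak_series`: list with `peak_times`,
#'   `prominences`, `heights`, `n` and the options used.  Traces shorter
#'   than 3 samples or with zero range yield an empty series (with a
#'   warning for the former).
#' @export
#' @examples
#' tr <- intensity_trace(0:350, sin(2 * pi * (0:350) / 100), time_unit = "s")
#' detect_peaks(tr, min_prominence_fraction = 0.2, min_distance = 30)$peak_times
detect_peaks <- function(trace, min_prominence_fraction = 0.2,
                         min_distance = NULL, detrend = TRUE,
                         min_prominence_abs = 0) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (min_prominence_fraction <= 0 || min_prominence_fraction >= 1)
    stop("min_prominence_fraction must be in (0, 1)")
  if (is.null(min_distance))
    min_distance <- if (trace$time_unit == "s") 30 else 0.5
  if (min_distance < sampling_interval(trace))
    stop("min_distance must be at least the sampling interval")
  opts <- list(min_prominence_fraction = min_prominence_fraction,
               min_distance = min_distance, detrend = detrend,
               min_prominence_abs = min_prominence_abs)
  empty <- structure(list(peak_times = numeric(0), prominences = numeric(0),
                          heights = numeric(0), n = 0L, options = opts),
                     class = "peak_series")
  x <- trace$values
  if (length(x) < 3) {
    warning("trace shorter than 3 samples; no peaks detected")
    return(empty)
  }
  if (detrend) {
    fit <- stats::lm.fit(cbind(1, trace$times), x)
    x <- fit$residuals
  }
  rng <- diff(range(x))
  if (rng == 0) return(empty)

  idx <- local_maxima(x)
  if (length(idx) == 0) return(empty)
  prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
  thr <- max(min_prominence_fraction * rng, min_prominence_abs)
  keep <- prom >= thr
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) == 0) return(empty)

  # greedy min-distance: accept in order of decreasing prominence
  ord <- order(prom, decreasing = TRUE)
  accepted <- logical(length(idx))
  acc_t <- numeric(0)
  for (j in ord) {
    tj <- trace$times[idx[j]]
    if (all(abs(acc_t - tj) >= min_distance)) {
      accepted[j] <- TRUE
      acc_t <- c(acc_t, tj)
    }
  }
  o <- order(trace$times[idx[accepted]])
  sel <- which(accepted)[o]
  structure(list(peak_times = trace$times[idx[sel]],
                 prominences = prom[sel],
                 heights = trace$values[idx[sel]],
                 n = length(sel), options = opts),
            class = "peak_series")
}

# indices of strict local maxima; plateaus are represented by their midpoint
local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) out <- c(out, as.integer((i + j) %/% 2))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# topographic prominence of the local maximum at index i
peak_prominence <- function(x, i) {
  h <- x[i]
  lmin <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
  if (j < 1L) lmin <- min(x[1:i])
  rmin <- h
  j <- i + 1L
  n <- length(x)
  while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
  if (j > n) rmin <- min(x[i:n])
  h - max(lmin, rmin)
}

#' @export
print.peak_series <- function(x, ...) {
  cat("Peak series: ", x$n, " peaks", sep = "")
  if (x$n > 1)
    cat(", mean interval ", signif(mean(diff(x$peak_times)), 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Inter-peak interval statistics
#'
#' Summarizes the successive differences of detected peak times the way
#' oscillation periods are reported from microscopy: mean +/- sample SD
#' with the number of intervals n.  With fewer than 2 peaks the statistics
#' are marked undefined (`NA`) rather than silently zero.
#'
#' @param peaks a `peak_series` (or a numeric vector of peak times).
#' @return Object of class `interval_statistics`: list with `intervals`,
#'   `mean`, `sd` (n-1 denominator; `NA` when n < 2) and `n`.
#' @export
#' @examples
#' interval_statistics(c(10, 120, 230, 340))
interval_statistics <- function(peaks) {
  pt <- if (inherits(peaks, "peak_series")) peaks$peak_times
        else as.numeric(peaks)
  if (is.unsorted(pt, strictly = TRUE) && length(pt) > 1)
    stop("peak times must be strictly increasing")
  iv <- diff(pt)
  n <- length(iv)
  structure(list(intervals = iv,
                 mean = if (n >= 1) mean(iv) else NA_real_,
                 sd = if (n >= 2) stats::sd(iv) else NA_real_,
                 n = n),
            class = "interval_statistics")
}

#' @export
print.interval_statistics <- function(x, ...) {
  if (x$n == 0) {
    cat("Interval statistics: undefined (fewer than 2 peaks)\n")
  } else {
    cat(sprintf("Interval statistics: mean %.4g +/- %s (SD), n = %d\n",
                x$mean, if (is.na(x$sd)) "NA" else sprintf("%.4g", x$sd),
                x$n))
  }
  invisible(x)
}

#' Relative-frequency histogram of inter-peak intervals
#'
#' Bins the intervals into left-closed, right-open bins anchored at
#' `origin`; frequencies are normalized to sum to 1.
#'
#' @param stats an `interval_statistics` object (or numeric intervals).
#' @param bin_width bin width, default 20 (s).
#' @param origin left edge of the first conceptual bin.
#' @return List of class `interval_histogram` with `bin_edges` and
#'   `relative_frequencies` (empty when there are no intervals).
#' @export
relative_frequency_histogram <- function(stats, bin_width = 20, origin = 0) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  iv <- if (inherits(stats, "interval_statistics")) stats$intervals
        else as.numeric(stats)
  if (length(iv) == 0)
    return(structure(list(bin_edges = numeric(0),
                          relative_frequencies = numeric(0)),
                     class = "interval_histogram"))
  lo <- origin + floor((min(iv) - origin) / bin_width) * bin_width
  hi <- origin + (floor((max(iv) - origin) / bin_width) + 1) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- vapply(seq_len(length(edges) - 1), function(i)
    sum(iv >= edges[i] & iv < edges[i + 1]), numeric(1))
  structure(list(bin_edges = edges,
                 relative_frequencies = counts / sum(counts)),
            class = "interval_histogram")
}

#' Detect activity episodes by hysteresis thresholding
#'
#' The model's activator switches between a quiescent and an excited
#' plateau; local-maximum detection over-counts noise riding on a plateau.
#' This detector normalizes the trace by its 5-95% quantile range and
#' records an episode onset whenever the signal rises above `up` after
#' having fallen below `down` (a Schmitt trigger).  Onset-to-onset
#' intervals measure the episode rhythm.
#'
#' @param trace an [intensity_trace()].
#' @param up,down hysteresis thresholds on the normalized trace
#'   (`0 < down < up < 1`).
#' @return Numeric vector of episode onset times.
#' @export
detect_episodes <- function(trace, up = 0.6, down = 0.35) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (!(0 < down && down < up && up < 1))
    stop("need 0 < down < up < 1")
  q <- stats::quantile(trace$values, c(0.05, 0.95), names = FALSE)
  if (q[2] <= q[1]) return(numeric(0))
  xn <- (trace$values - q[1]) / (q[2] - q[1])
  hi <- xn[1] > up
  on <- logical(length(xn))
  for (i in seq_along(xn)) {
    if (!hi && xn[i] > up) { hi <- TRUE; on[i] <- TRUE }
    else if (hi && xn[i] < down) hi <- FALSE
  }
  trace$times[on]
}
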