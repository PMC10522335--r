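#' Pearson correlation of two traces
#'
#' Standard Pearson coefficient over the samples falling in `window`
#' (default: the whole overlap).  The traces must share the same sampling
#' grid on the window.  Zero variance in either trace yields `NA`
#' (undefined), never 0.
#'
#' @param a,b [intensity_trace()] objects on identical grids.
#' @param window optional `c(start, end)` in trace time units.
#' @return A single correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_correlation <- function(a, b, window = NULL) {
  g <- common_grid(a, b, window)
  if (length(g$x) < 2) return(NA_real_)
  if (stats::sd(g$x) == 0 || stats::sd(g$y) == 0) return(NA_real_)
  stats::cor(g$x, g$y)
}

common_grid <- function(a, b, window = NULL) {
  stopifnot(inherits(a, "intensity_trace"), inherits(b, "intensity_trace"))
  n <- min(length(a$times), length(b$times))
  if (max(abs(a$times[seq_len(n)] - b$times[seq_len(n)])) >
      1e-9 * max(abs(a$times[n]), 1))
    stop("traces are not on a common sampling grid")
  tt <- a$times[seq_len(n)]
  x <- a$values[seq_len(n)]; y <- b$values[seq_len(n)]
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    tt <- tt[keep]; x <- x[keep]; y <- y[keep]
  }
  list(t = tt, x = x, y = y)
}

#' Sliding-window Pearson correlation
#'
#' Correlation of two traces over a sliding window, used to localize when
#' two oscillators lock into anti-phase.  A window length of at least two
#' dominant periods is recommended.
#'
#' @inheritParams pearson_correlation
#' @param window_length window width in trace time units.
#' @param step displacement between successive windows (default
#'   `window_length / 2`).
#' @return Data frame with columns `center` and `correlation`.
#' @export
windowed_correlation <- function(a, b, window_length, step = window_length / 2) {
  g <- common_grid(a, b)
  if (window_length <= 0 || step <= 0)
    stop("window_length and step must be > 0")
  t0 <- g$t[1]
  t1 <- g$t[length(g$t)]
  centers <- seq(t0 + window_length / 2, t1 - window_length / 2 + 1e-12,
                 by = step)
  if (length(centers) == 0)
    return(data.frame(center = numeric(0), correlation = numeric(0)))
  corr <- vapply(centers, function(cc) {
    i <- g$t >= cc - window_length / 2 & g$t < cc + window_length / 2
    x <- g$x[i]; y <- g$y[i]
    if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }, numeric(1))
  data.frame(center = centers, correlation = corr)
}

#' Phase relation of two oscillatory traces
#'
#' Classifies the phase relation of two traces on a common grid as
#' in-phase, anti-phase or uncoordinated.  The dominant period is the mean
#' inter-peak interval of `a`.  With `method = "ccf"` (default), the lag
#' fraction is the argmax of the circular cross-correlation within one
#' period, as a fraction of the period.  With `method = "hilbert"`, it is
#' the circular mean of the instantaneous analytic-signal phase difference
#' -- more robust for irregular relaxation-type waveforms whose dwell
#' times wander.
#'
#' Labels: in-phase when the lag fraction is in \[0, 0.15\] or \[0.85, 1)
#' and the Pearson correlation is >= 0.3; anti-phase when the lag fraction
#' is in \[0.35, 0.65\] and the correlation is <= -0.3; otherwise
#' uncoordinated.
#'
#' @inheritParams pearson_correlation
#' @param method `"ccf"` or `"hilbert"`.
#' @param min_peaks minimum number of detected peaks per trace for the
#'   input to count as oscillatory.
#' @param ... passed to [detect_peaks()].
#' @return Object of class `phase_classification`: list with `label`,
#'   `lag_fraction`, `correlation`, `period` and `diagnostic`.
#' @export
#' @examples
#' t <- seq(0, 1000, 2)
#' a <- intensity_trace(t, sin(2 * pi * t / 100), time_unit = "s")
#' b <- intensity_trace(t, sin(2 * pi * t / 100 + pi), time_unit = "s")
#' phase_relation(a, b)$label  # "anti-phase"
phase_relation <- function(a, b, method = c("ccf", "hilbert"),
                           min_peaks = 3, ...) {
  method <- match.arg(method)
  g <- common_grid(a, b)
  pa <- detect_peaks(a, ...)
  pb <- detect_peaks(b, ...)
  uncoordinated <- function(msg, corr = NA_real_, lag = NA_real_,
                            period = NA_real_) {
    structure(list(label = "uncoordinated", lag_fraction = lag,
                   correlation = corr, period = period, diagnostic = msg),
              class = "phase_classification")
  }
  if (pa$n < min_peaks || pb$n < min_peaks)
    return(uncoordinated(sprintf(
      "non-oscillatory input (%d and %d peaks; need >= %d each)",
      pa$n, pb$n, min_peaks)))
  period <- mean(diff(pa$peak_times))
  corr <- pearson_correlation(a, b)
  dt <- sampling_interval(a)
  lag <- if (method == "ccf") {
    nlag <- max(1L, as.integer(round(period / dt)))
    x <- g$x - mean(g$x); y <- g$y - mean(g$y)
    cc <- vapply(0:(nlag - 1), function(L) {
      yy <- if (L == 0) y else c(y[-seq_len(L)], y[seq_len(L)])
      sum(x * yy)
    }, numeric(1))
    ((which.max(cc) - 1) * dt / period) %% 1
  } else {
    hilbert_phase_lag(a, b)
  }
  label <- if ((lag <= 0.15 || lag >= 0.85) && !is.na(corr) && corr >= 0.3) {
    "in-phase"
  } else if (lag >= 0.35 && lag <= 0.65 && !is.na(corr) && corr <= -0.3) {
    "anti-phase"
  } else "uncoordinated"
  structure(list(label = label, lag_fraction = lag, correlation = corr,
                 period = period, diagnostic = NULL),
            class = "phase_classification")
}

#' @export
print.phase_classification <- function(x, ...) {
  cat("Phase relation: ", x$label, sep = "")
  if (!is.na(x$lag_fraction))
    cat(sprintf(" (lag %.3f of period, r = %.3f)", x$lag_fraction,
                x$correlation))
  if (!is.null(x$diagnostic)) cat(" [", x$diagnostic, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Analytic-signal phase lag between two traces
#'
#' Computes instantaneous phases via the FFT-based analytic signal
#' (Hilbert transform) of the mean-removed traces and returns the circular
#' mean of the phase difference as a fraction of a cycle in `[0, 1)`.
#' Two oscillators locked in anti-phase give 0.5 regardless of how
#' irregular their common rhythm is.
#'
#' @inheritParams pearson_correlation
#' @return Lag fraction in `[0, 1)`.
#' @export
hilbert_phase_lag <- function(a, b) {
  g <- common_grid(a, b)
  pha <- analytic_phase(g$x)
  phb <- analytic_phase(g$y)
  dph <- pha - phb
  (atan2(mean(sin(dph)), mean(cos(dph))) / (2 * pi)) %% 1
}

analytic_phase <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE))
}

#' Transition slowing statistic
#'
#' Quantifies transient slowing of an oscillation pair around a dynamical
#' transition: the pooled mean inter-peak interval inside the transition
#' window divided by the mean of the pooled means of the two flanking
#' windows.  A ratio above 1 indicates slowing during the transition.
#'
#' @param peaks_a,peaks_b `peak_series` objects (or numeric peak times) of
#'   the two cells.
#' @param pre_window,transition_window,post_window `c(start, end)` windows
#'   in the same time units as the peak times.
#' @param min_peaks_per_series minimum peaks required from each series in
#'   each window; windows with fewer yield `NA` with a warning.
#' @return List of class `slowdown_report` with `ratio` and the
#'   per-window pooled mean intervals.
#' @export
#' @examples
#' # pre mean 100, transition mean 150, post mean 110 -> 150/105
#' a <- cumsum(c(0, rep(100, 5), rep(150, 5), rep(110, 5)))
#' slowdown_statistic(a, a + 50, c(0, 500), c(500, 1250), c(1250, 1800))
slowdown_statistic <- function(peaks_a, peaks_b, pre_window,
                               transition_window, post_window,
                               min_peaks_per_series = 2) {
  pta <- if (inherits(peaks_a, "peak_series")) peaks_a$peak_times
         else as.numeric(peaks_a)
  ptb <- if (inherits(peaks_b, "peak_series")) peaks_b$peak_times
         else as.numeric(peaks_b)
  win_mean <- function(w, what) {
    ia <- pta[pta >= w[1] & pta <= w[2]]
    ib <- ptb[ptb >= w[1] & ptb <= w[2]]
    if (length(ia) < min_peaks_per_series ||
        length(ib) < min_peaks_per_series) {
      warning("insufficient peaks in ", what, " window [", w[1], ", ",
              w[2], "]")
      return(NA_real_)
    }
    mean(c(diff(ia), diff(ib)))
  }
  pre <- win_mean(pre_window, "pre")
  tra <- win_mean(transition_window, "transition")
  post <- win_mean(post_window, "post")
  ratio <- tra / mean(c(pre, post))
  structure(list(ratio = ratio, pre_mean = pre, transition_mean = tra,
                 post_mean = post),
            class = "slowdown_report")
}

#' @export
print.slowdown_report <- function(x, ...) {
  cat(sprintf(
    "Slowdown report: ratio %.4g (pre %.4g, transition %.4g, post %.4g)\n",
    x$ratio, x$pre_mean, x$transition_mean, x$post_mean))
  invisible(x)
}
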