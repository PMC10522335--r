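#' Distance schedules
#'
#' A distance schedule describes the inter-cell distance d as a function of
#' simulation time (time 0 = end of burn-in; during burn-in the schedule's
#' value at time 0 is used).  Three kinds are supported: a constant
#' distance, a linear ramp that is constant outside `[ramp_start,
#' ramp_end]`, and a piecewise-linear curve through `(times, values)`
#' breakpoints with constant extrapolation.
#'
#' @param d constant distance (`constant_schedule`).
#' @param d_start,d_end ramp endpoints.
#' @param ramp_start,ramp_end start and end times of the ramp.
#' @param times,values piecewise breakpoints (equal length, times increasing).
#' @return An object of class `distance_schedule` with an `evaluate(t)`
#'   closure and the defining fields.
#' @export
#' @examples
#' s <- ramp_schedule(10, 0, ramp_start = 0, ramp_end = 30)
#' s$evaluate(15)  # 5
constant_schedule <- function(d) {
  if (d < 0) stop("distance must be >= 0")
  structure(list(kind = "constant", d_start = d, d_end = d,
                 ramp_start = 0, ramp_end = 0,
                 evaluate = function(t) rep(d, length(t))),
            class = "distance_schedule")
}

#' @rdname constant_schedule
#' @export
ramp_schedule <- function(d_start, d_end, ramp_start, ramp_end) {
  if (d_start < 0 || d_end < 0) stop("distances must be >= 0")
  if (ramp_end <= ramp_start) stop("ramp_end must exceed ramp_start")
  ev <- function(t) {
    w <- pmin(pmax((t - ramp_start) / (ramp_end - ramp_start), 0), 1)
    d_start + (d_end - d_start) * w
  }
  structure(list(kind = "linear_ramp", d_start = d_start, d_end = d_end,
                 ramp_start = ramp_start, ramp_end = ramp_end, evaluate = ev),
            class = "distance_schedule")
}

#' @rdname constant_schedule
#' @export
piecewise_schedule <- function(times, values) {
  if (length(times) != length(values) || length(times) < 1)
    stop("times and values must be nonempty and of equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("breakpoint times must be strictly increasing")
  if (any(values < 0)) stop("distances must be >= 0")
  ev <- function(t) {
    stats::approx(times, values, xout = pmin(pmax(t, times[1]),
                                             times[length(times)]),
                  rule = 2)$y
  }
  structure(list(kind = "piecewise", times = times, values = values,
                 d_start = values[1], d_end = values[length(values)],
                 evaluate = ev),
            class = "distance_schedule")
}

as_schedule <- function(x) {
  if (inherits(x, "distance_schedule")) return(x)
  if (is.numeric(x) && length(x) == 1) return(constant_schedule(x))
  stop("expected a distance_schedule or a single distance value")
}

schedule_core_args <- function(s) {
  switch(s$kind,
    constant = list(kind = 0L, d_start = s$d_start, d_end = s$d_start,
                    ramp_start = 0, ramp_end = 0,
                    break_times = numeric(0), break_values = numeric(0)),
    linear_ramp = list(kind = 1L, d_start = s$d_start, d_end = s$d_end,
                       ramp_start = s$ramp_start, ramp_end = s$ramp_end,
                       break_times = numeric(0), break_values = numeric(0)),
    piecewise = list(kind = 2L, d_start = s$d_start, d_end = s$d_end,
                     ramp_start = 0, ramp_end = 0,
                     break_times = as.numeric(s$times),
                     break_values = as.numeric(s$values)))
}

schedule_meta <- function(s) {
  s[setdiff(names(s), "evaluate")]
}

#' @export
print.distance_schedule <- function(x, ...) {
  cat("Distance schedule (", x$kind, "): d ", x$d_start,
      if (x$kind != "constant") paste0(" -> ", x$d_end), "\n", sep = "")
  invisible(x)
}
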