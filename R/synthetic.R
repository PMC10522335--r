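#' Specification of a synthetic fluorescence pulse train
#'
#' Describes a surrogate tip-fluorescence trace: Gaussian-shaped pulses
#' whose inter-pulse intervals are drawn from a truncated normal
#' distribution (truncated below at twice the pulse width so pulses cannot
#' overlap), on a baseline with optional linear drift (photobleaching) and
#' additive white measurement noise.  The default period statistics
#' (104 +/- 28 s) match reporter oscillations measured during the
#' cell-to-cell dialogue; single-hypha reporters show 103-137 s means with
#' SDs of 17-37 s.
#'
#' @param period_mean,period_sd inter-pulse interval mean and SD (s).
#' @param n_pulses number of pulses.
#' @param pulse_width Gaussian kernel SD of a single pulse (s).
#' @param amplitude pulse height (intensity units).
#' @param baseline constant background intensity.
#' @param drift_slope linear drift (intensity per second).
#' @param noise_sd additive white-noise SD.
#' @param sample_interval sampling cadence (s); must resolve the period
#'   (at most `period_mean / 10`).
#' @param seed RNG seed.
#' @return List of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(period_mean = 104, period_sd = 28,
                             n_pulses = 20, pulse_width = 10,
                             amplitude = 100, baseline = 10,
                             drift_slope = 0, noise_sd = 0,
                             sample_interval = 5, seed = NULL) {
  if (period_mean <= 2 * pulse_width)
    stop("period_mean must exceed 2 * pulse_width")
  if (sample_interval > period_mean / 10)
    stop("sample_interval must be at most period_mean / 10")
  for (f in c("period_sd", "pulse_width", "amplitude", "baseline",
              "noise_sd")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stop("field '", f, "' must be a nonnegative number")
  }
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  structure(list(period_mean = period_mean, period_sd = period_sd,
                 n_pulses = as.integer(n_pulses), pulse_width = pulse_width,
                 amplitude = amplitude, baseline = baseline,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 sample_interval = sample_interval, seed = seed),
            class = "pulse_train_spec")
}

# truncated-normal intervals, lower bound 2 * pulse_width
draw_intervals <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  filled <- 0
  while (filled < n) {
    cand <- stats::rnorm(n - filled, mean, sd)
    cand <- cand[cand > lower]
    if (length(cand) > 0) {
      out[(filled + 1):(filled + length(cand))] <- cand
      filled <- filled + length(cand)
    }
  }
  out
}

render_pulses <- function(times, centers, spec) {
  v <- spec$baseline + spec$drift_slope * times
  for (cc in centers)
    v <- v + spec$amplitude * exp(-(times - cc)^2 / (2 * spec$pulse_width^2))
  if (spec$noise_sd > 0)
    v <- v + stats::rnorm(length(times), 0, spec$noise_sd)
  v
}

#' Generate a synthetic pulse-train trace
#'
#' Realizes a [pulse_train_spec()] as an intensity trace plus the
#' ground-truth pulse center times, reproducibly from the spec's seed.
#'
#' @param spec a `pulse_train_spec`.
#' @return List with `trace` (an [intensity_trace()]) and `ground_truth`
#'   (pulse center times, s).
#' @export
#' @examples
#' g <- generate_pulse_trace(pulse_train_spec(n_pulses = 5, period_sd = 0,
#'                                            seed = 1))
#' diff(g$ground_truth)  # all exactly 104
generate_pulse_trace <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  gaps <- draw_intervals(spec$n_pulses - 1, spec$period_mean,
                         spec$period_sd, 2 * spec$pulse_width)
  centers <- spec$period_mean + c(0, cumsum(gaps))
  t_end <- centers[length(centers)] + spec$period_mean
  times <- seq(0, t_end, by = spec$sample_interval)
  tr <- intensity_trace(times, render_pulses(times, centers, spec),
                        label = "synthetic pulse train", time_unit = "s")
  list(trace = tr, ground_truth = centers)
}

#' Generate a pair of synthetic traces with a fixed phase relation
#'
#' Builds two pulse trains on a common grid.  With `shared_jitter` the
#' second train reuses the first train's interval realization, its pulse
#' centers displaced by `phase_offset_fraction` of the local cycle
#' (0.5 makes train 2 bisect train 1's intervals: anti-phase; 0 makes the
#' trains coincide: in-phase).  Without `shared_jitter` the second train
#' draws its own independent intervals, so the pair drifts apart
#' (uncoordinated), whatever the nominal offset.
#'
#' @param spec base [pulse_train_spec()] (its `seed` drives everything).
#' @param phase_offset_fraction offset of train 2 in units of the cycle,
#'   in `[0, 1)`.
#' @param shared_jitter share one interval realization between the trains.
#' @return List with `trace1`, `trace2`, `ground_truth1`, `ground_truth2`.
#' @export
generate_pair <- function(spec, phase_offset_fraction = 0.5,
                          shared_jitter = TRUE) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  if (phase_offset_fraction < 0 || phase_offset_fraction >= 1)
    stop("phase_offset_fraction must be in [0, 1)")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  gaps1 <- draw_intervals(spec$n_pulses - 1, spec$period_mean,
                          spec$period_sd, 2 * spec$pulse_width)
  c1 <- spec$period_mean + c(0, cumsum(gaps1))
  c2 <- if (shared_jitter) {
    steps <- c(gaps1, spec$period_mean)
    c1 + phase_offset_fraction * steps
  } else {
    gaps2 <- draw_intervals(spec$n_pulses - 1, spec$period_mean,
                            spec$period_sd, 2 * spec$pulse_width)
    spec$period_mean + phase_offset_fraction * spec$period_mean +
      c(0, cumsum(gaps2))
  }
  t_end <- max(c1[length(c1)], c2[length(c2)]) + spec$period_mean
  times <- seq(0, t_end, by = spec$sample_interval)
  tr1 <- intensity_trace(times, render_pulses(times, c1, spec),
                         label = "tip 1", time_unit = "s")
  tr2 <- intensity_trace(times, render_pulses(times, c2, spec),
                         label = "tip 2", time_unit = "s")
  list(trace1 = tr1, trace2 = tr2, ground_truth1 = c1, ground_truth2 = c2)
}

#' Generate a synthetic entrainment sequence
#'
#' Emulates the transition from two independent monologues to an
#' anti-phasic dialogue as a three-segment pair of traces: (1) independent
#' pulse trains, (2) independent trains slowed by
#' `transition_slowdown_factor`, (3) anti-phasic trains sharing one
#' interval realization.  The recorded change points delimit the segments,
#' providing ground truth for windowed-correlation and slowing analyses.
#'
#' @param spec base [pulse_train_spec()]; `n_pulses` is ignored (segment
#'   durations govern the pulse counts).
#' @param transition_slowdown_factor period multiplier of the middle
#'   segment, >= 1.
#' @param segment_durations durations (s) of the three segments.
#' @return List with `trace1`, `trace2`, `ground_truth1`, `ground_truth2`
#'   and `change_points` (length 2).
#' @export
generate_entrainment_sequence <- function(spec,
                                          transition_slowdown_factor = 1.5,
                                          segment_durations = c(600, 600,
                                                                600)) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  if (transition_slowdown_factor < 1)
    stop("transition_slowdown_factor must be >= 1")
  if (length(segment_durations) != 3 || any(segment_durations <= 0))
    stop("segment_durations must be 3 positive durations")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  cp <- cumsum(segment_durations)[1:2]
  t_end <- sum(segment_durations)
  lower <- 2 * spec$pulse_width
  grow <- function(start, until, mean) {
    cc <- numeric(0)
    t <- start
    repeat {
      t <- t + draw_intervals(1, mean, spec$period_sd, lower)
      if (t >= until) break
      cc <- c(cc, t)
    }
    cc
  }
  m <- spec$period_mean
  slow_m <- m * transition_slowdown_factor
  # segments 1 + 2: independent per cell
  c1 <- c(grow(0, cp[1], m), grow(cp[1], cp[2], slow_m))
  c2 <- c(grow(0, cp[1], m), grow(cp[1], cp[2], slow_m))
  # segment 3: shared realization, cell 2 bisects cell 1
  base <- grow(cp[2], t_end, m)
  if (length(base) >= 2) {
    mid <- base[-length(base)] + diff(base) / 2
  } else mid <- numeric(0)
  c1 <- c(c1, base)
  c2 <- c(c2, mid)
  times <- seq(0, t_end, by = spec$sample_interval)
  tr1 <- intensity_trace(times, render_pulses(times, c1, spec),
                         label = "tip 1", time_unit = "s")
  tr2 <- intensity_trace(times, render_pulses(times, c2, spec),
                         label = "tip 2", time_unit = "s")
  list(trace1 = tr1, trace2 = tr2, ground_truth1 = c1, ground_truth2 = c2,
       change_points = cp)
}
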