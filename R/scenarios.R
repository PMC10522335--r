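#' Single-cell monologue simulation
#'
#' Runs the model with the tip-to-tip coupling forced to zero, so that
#' cell 1 behaves as an isolated hypha exchanging signaling component only
#' with the bulk medium.  At the published noise level (omega = 1000) the
#' excitable circuit fires recurrent pulses in all five variables -- the
#' "cell monologue".
#'
#' @param params a `dialog_params` object.
#' @param settings a `simulation_settings` object.
#' @return A `dialog_trajectory` (analyze cell 1).
#' @export
run_single_cell <- function(params = default_parameters(),
                            settings = simulation_settings()) {
  simulate_dialog(params, settings, schedule = constant_schedule(params$d),
                  single_cell = TRUE)
}

#' Fixed-distance two-cell simulation
#'
#' Simulates the pair at a constant distance and reports the post-burn-in
#' Pearson correlation of the two activators together with a phase
#' classification.  At long distance (d = 10) the cells pulse as
#' independent units (correlation near 0); at contact (d = 0) they lock
#' into anti-phase alternation (strongly negative correlation, phase lag
#' close to half a cycle).
#'
#' @param d constant inter-cell distance.
#' @inheritParams run_single_cell
#' @param method phase-lag estimator handed to [phase_relation()];
#'   `"hilbert"` (default) is robust to the irregular dwell times of the
#'   model's relaxation pulses.
#' @return List with `trajectory`, `correlation` and `phase`
#'   (a `phase_classification`).
#' @export
run_fixed_distance <- function(d, params = default_parameters(),
                               settings = simulation_settings(),
                               method = "hilbert") {
  traj <- simulate_dialog(params, settings, schedule = constant_schedule(d))
  a1 <- trajectory_to_trace(traj, 1, "A")
  a2 <- trajectory_to_trace(traj, 2, "A")
  list(trajectory = traj,
       correlation = pearson_correlation(a1, a2),
       phase = phase_relation(a1, a2, method = method))
}

#' Distance sweep of activator anti-correlation
#'
#' For each distance on the grid and each seed, simulates the pair and
#' records the Pearson correlation of A1 vs A2 -- the in-silico analogue
#' of moving two hyphae progressively closer.  The anti-correlation
#' magnitude grows as the distance shrinks.
#'
#' @param d_grid nonempty sorted distance grid.
#' @param n_seeds replicate seeds per distance.
#' @param base_seed seed of the first replicate; replicate j uses
#'   `base_seed + j - 1`.
#' @inheritParams run_single_cell
#' @return Object of class `sweep_result`: list with `results`
#'   (data frame `d`, `seed`, `correlation`) and `summary` (per-d mean and
#'   SD across seeds).
#' @export
run_distance_sweep <- function(d_grid, n_seeds = 10,
                               params = default_parameters(),
                               settings = simulation_settings(),
                               base_seed = 1) {
  if (length(d_grid) == 0) stop("d_grid must be nonempty")
  if (is.unsorted(d_grid)) stop("d_grid must be sorted increasing")
  rows <- list()
  for (d in d_grid) {
    for (j in seq_len(n_seeds)) {
      s <- settings
      s$seed <- base_seed + j - 1
      r <- run_fixed_distance(d, params, s)
      rows[[length(rows) + 1]] <- data.frame(d = d, seed = s$seed,
                                             correlation = r$correlation)
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$d), function(g) {
    data.frame(d = g$d[1], mean_correlation = mean(g$correlation),
               sd_correlation = stats::sd(g$correlation),
               n = nrow(g))
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Distance sweep (", nrow(x$results), " runs):\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Default approach-ramp schedule
#'
#' Holds the pair at long distance (d = 10) for 20 time units, ramps
#' linearly to contact (d = 0) over the following 30 units -- emulating two
#' hyphae growing toward each other -- then holds at contact.  The flat
#' segments on both sides give the transition analysis proper pre- and
#' post-windows.
#'
#' @param d_start,d_end ramp endpoints.
#' @param ramp_start,ramp_end ramp timing (after burn-in).
#' @return A `distance_schedule`.
#' @export
default_ramp <- function(d_start = 10, d_end = 0, ramp_start = 20,
                         ramp_end = 50) {
  ramp_schedule(d_start, d_end, ramp_start, ramp_end)
}

#' Approach-ramp (entrainment) simulation
#'
#' Simulates the pair under a decreasing distance ramp, computes the
#' sliding-window correlation of the two activators, and summarizes
#' inter-peak intervals in the pre-ramp, ramp, and post-ramp windows via
#' [slowdown_statistic()].  As the cells come within coupling range the
#' windowed correlation drops from around 0 to strongly negative
#' (anti-synchrony).
#'
#' @param schedule a decreasing `distance_schedule` (default
#'   [default_ramp()]).
#' @inheritParams run_single_cell
#' @param window_length,step sliding-window parameters (time units).
#' @return List with `trajectory`, `windowed` (data frame of window
#'   centers and correlations), `slowdown` (a `slowdown_report`), and the
#'   window definitions used.
#' @export
run_approach_ramp <- function(schedule = default_ramp(),
                              params = default_parameters(),
                              settings = simulation_settings(),
                              window_length = 10, step = 1) {
  schedule <- as_schedule(schedule)
  traj <- simulate_dialog(params, settings, schedule = schedule)
  a1 <- trajectory_to_trace(traj, 1, "A")
  a2 <- trajectory_to_trace(traj, 2, "A")
  wc <- windowed_correlation(a1, a2, window_length, step)
  t_end <- max(traj$times)
  rs <- if (schedule$kind == "linear_ramp") schedule$ramp_start else 0
  re <- if (schedule$kind == "linear_ramp") schedule$ramp_end else 0
  windows <- list(pre = c(0, rs), transition = c(rs, re),
                  post = c(re, t_end))
  p1 <- detect_peaks(a1)
  p2 <- detect_peaks(a2)
  slow <- withCallingHandlers(
    slowdown_statistic(p1, p2, windows$pre, windows$transition,
                       windows$post),
    warning = function(w) invokeRestart("muffleWarning"))
  list(trajectory = traj, windowed = wc, slowdown = slow,
       windows = windows, peaks = list(cell1 = p1, cell2 = p2))
}

#' Oscillation report for one trace
#'
#' Counts peaks over the trace and flags the condition as oscillating when
#' the peak rate reaches `threshold_rate` peaks per 100 time units.
#' An absolute prominence floor can anchor detection to a common amplitude
#' scale when several conditions are compared.
#'
#' @param trace an [intensity_trace()].
#' @param condition free-text condition label.
#' @param threshold_rate peaks per 100 time units required to call the
#'   trace oscillating.
#' @param min_prominence_abs absolute prominence floor (see
#'   [detect_peaks()]).
#' @return Object of class `oscillation_report`: list with `condition`,
#'   `peak_count`, `mean_amplitude` (mean peak prominence), `duration`,
#'   `oscillating`.
#' @export
oscillation_report <- function(trace, condition = trace$label,
                               threshold_rate = 5, min_prominence_abs = 0) {
  pk <- detect_peaks(trace, min_prominence_abs = min_prominence_abs)
  duration <- diff(range(trace$times))
  thr <- threshold_rate * duration / 100
  structure(list(condition = condition, peak_count = pk$n,
                 mean_amplitude = if (pk$n > 0) mean(pk$prominences)
                                  else NA_real_,
                 duration = duration,
                 oscillating = pk$n >= thr),
            class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat(sprintf("Condition '%s': %d peaks in %g time units -> %s\n",
              x$condition, x$peak_count, x$duration,
              if (x$oscillating) "oscillating" else "not oscillating"))
  invisible(x)
}

#' Media-depletion scenario
#'
#' Runs the single-cell model at each bulk-media signaling concentration
#' and reports whether the activator still pulses.  Peak prominence is
#' referenced to 20% of the largest activator range across the condition
#' list, so that small stochastic ripples around the quiescent state in
#' depleted media are not mistaken for oscillation.  Removing the
#' signaling component from the medium (cmedia = 0) silences the circuit;
#' the control concentration (cmedia = 1) sustains it.
#'
#' @param cmedia_values nonnegative media concentrations.
#' @inheritParams run_single_cell
#' @param threshold_rate peaks per 100 time units required for the
#'   oscillating flag.
#' @return List of `oscillation_report`s, one per value.
#' @export
run_media_depletion <- function(cmedia_values,
                                params = default_parameters(),
                                settings = simulation_settings(),
                                threshold_rate = 5) {
  if (any(cmedia_values < 0)) stop("cmedia values must be >= 0")
  traces <- lapply(cmedia_values, function(cm) {
    p <- params
    p$cmedia <- cm
    traj <- run_single_cell(p, settings)
    trajectory_to_trace(traj, 1, "A")
  })
  scale <- max(vapply(traces, function(tr) diff(range(tr$values)),
                      numeric(1)))
  mapply(function(tr, cm) {
    oscillation_report(tr, condition = sprintf("cmedia = %g", cm),
                       threshold_rate = threshold_rate,
                       min_prominence_abs = 0.2 * scale)
  }, traces, cmedia_values, SIMPLIFY = FALSE)
}
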