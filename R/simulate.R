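#' Simulation settings
#'
#' Bundles the numerical settings of the Euler-Maruyama integration.
#' Defaults follow the published protocol: integration step `dt = 0.001`
#' time units, a burn-in of 200 time units discarded before analysis, and
#' 100 time units of recorded dynamics.  One record is kept every
#' `record_stride` steps (default 100, i.e. every 0.1 time unit, about 17
#' samples per typical oscillation cycle).
#'
#' @param dt integration step, in model time units (one unit = one minute).
#' @param total_time recorded duration after burn-in.
#' @param burn_in discarded initial duration.
#' @param record_stride steps between recorded samples.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param noise_mode `"as-printed"` (per-channel propensity increments,
#'   amplitude `tau / omega`), `"chemical-langevin"` (square-root
#'   propensities, amplitude `tau / sqrt(omega)`), or `"off"`
#'   (deterministic Euler).
#' @param clamp_nonnegative clamp all state variables at 0 after each step
#'   (concentrations are physical quantities).
#' @param per_channel draw all 38 per-channel increments individually
#'   instead of one aggregated draw per variable (audit mode; the two are
#'   distributionally identical).
#' @param mirror_noise force cell 2 to reuse cell 1's noise draws
#'   (diagnostic mode: identically forced cells stay perfectly correlated).
#' @return A list of class `simulation_settings`.
#' @export
simulation_settings <- function(dt = 0.001, total_time = 100, burn_in = 200,
                                record_stride = 100, seed = NULL,
                                noise_mode = c("as-printed",
                                               "chemical-langevin", "off"),
                                clamp_nonnegative = TRUE,
                                per_channel = FALSE, mirror_noise = FALSE) {
  noise_mode <- match.arg(noise_mode)
  if (dt <= 0) stop("dt must be > 0")
  if (total_time <= 0) stop("total_time must be > 0")
  if (burn_in < 0) stop("burn_in must be >= 0")
  if (record_stride < 1) stop("record_stride must be >= 1")
  structure(list(dt = dt, total_time = total_time, burn_in = burn_in,
                 record_stride = as.integer(record_stride), seed = seed,
                 noise_mode = noise_mode,
                 clamp_nonnegative = isTRUE(clamp_nonnegative),
                 per_channel = isTRUE(per_channel),
                 mirror_noise = isTRUE(mirror_noise)),
            class = "simulation_settings")
}

noise_mode_code <- function(mode) {
  switch(mode, "off" = 0L, "as-printed" = 1L, "chemical-langevin" = 2L)
}

#' Single Euler-Maruyama step
#'
#' Advances the state by one step:
#' `state + tau * F(state) * dt + noise`, where the per-variable noise is
#' the aggregated Gaussian increment of the 19 per-cell channels under the
#' chosen mode (`sd = sqrt(sum g^2)` for `"as-printed"`,
#' `sqrt(sum g)` for `"chemical-langevin"`), scaled by `tau / omega`
#' resp. `tau / sqrt(omega)` and `sqrt(dt)`.  With `noise_mode = "off"`
#' this is the deterministic Euler update.
#'
#' @inheritParams drift
#' @param dt integration step.
#' @param noise_mode see [simulation_settings()].
#' @param clamp_nonnegative clamp the result at 0.
#' @return The new state (named numeric vector of length 10).
#' @export
em_step <- function(state, params, d = params$d, dt = 0.001,
                    noise_mode = c("as-printed", "chemical-langevin", "off"),
                    clamp_nonnegative = TRUE) {
  noise_mode <- match.arg(noise_mode)
  if (dt < 0) stop("dt must be >= 0")
  f <- drift(state, params, d)
  out <- state + params$tau * f * dt
  if (noise_mode != "off" && dt > 0) {
    g <- noise_propensities(state, params, d)
    agg <- if (noise_mode == "as-printed") {
      tapply(g$propensity^2, list(g$cell, g$target_variable), sum)
    } else {
      tapply(g$propensity, list(g$cell, g$target_variable), sum)
    }
    amp <- if (noise_mode == "as-printed") params$tau / params$omega
           else params$tau / sqrt(params$omega)
    # fixed draw order A1 I1 X1 Y1 Z1 A2 I2 X2 Y2 Z2
    ord <- c("A", "I", "X", "Y", "Z")
    sds <- c(sqrt(agg["1", ord]), sqrt(agg["2", ord]))
    out <- out + amp * sds * sqrt(dt) * stats::rnorm(10)
  }
  if (clamp_nonnegative) out <- pmax(out, 0)
  bad <- which(!is.finite(out))
  if (length(bad) > 0)
    stop("integration failure: non-finite ",
         paste(STATE_NAMES[bad], collapse = ", "))
  stats::setNames(out, STATE_NAMES)
}

#' Simulate the two-cell dialogue model
#'
#' Integrates the model with the Euler-Maruyama method from the canonical
#' initial state, discarding `burn_in` time units (run at the schedule's
#' value at its start) and recording `total_time` units thereafter.  The
#' schedule clock starts at the end of the burn-in.  The run is fully
#' reproducible from `(seed, params, settings, schedule)`.
#'
#' @param params a `dialog_params` object.
#' @param settings a `simulation_settings` object.
#' @param schedule a `distance_schedule`, or a single number for a constant
#'   distance; defaults to `params$d`.
#' @param init initial state (default [initial_state()]).
#' @param single_cell logical; force the coupling rate to 0 so each cell
#'   evolves independently (cell 1 is then a single-cell "monologue" run).
#' @return An object of class `dialog_trajectory`: list with `times`
#'   (recorded grid), `states` (matrix, one column per variable), and
#'   provenance fields `params`, `settings`, `schedule`, `seed`.
#' @export
#' @examples
#' traj <- simulate_dialog(default_parameters(),
#'                         simulation_settings(total_time = 5, burn_in = 0,
#'                                             seed = 1))
#' head(traj$states)
simulate_dialog <- function(params = default_parameters(),
                            settings = simulation_settings(),
                            schedule = NULL, init = initial_state(),
                            single_cell = FALSE) {
  validate_parameters(params)
  stopifnot(inherits(settings, "simulation_settings"))
  if (is.null(schedule)) schedule <- params$d
  schedule <- as_schedule(schedule)
  check_state(init)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  sa <- schedule_core_args(schedule)
  res <- .em_core(as.numeric(init), param_vector(params),
                  sa$kind, sa$d_start, sa$d_end, sa$ramp_start, sa$ramp_end,
                  sa$break_times, sa$break_values,
                  settings$dt, settings$burn_in, settings$total_time,
                  settings$record_stride,
                  noise_mode_code(settings$noise_mode),
                  settings$per_channel, settings$mirror_noise,
                  settings$clamp_nonnegative, isTRUE(single_cell))
  colnames(res$states) <- STATE_NAMES
  structure(list(times = res$times, states = res$states, params = params,
                 settings = settings, schedule = schedule,
                 seed = settings$seed, single_cell = isTRUE(single_cell)),
            class = "dialog_trajectory")
}

#' @export
print.dialog_trajectory <- function(x, ...) {
  cat("Two-cell dialogue trajectory: ", length(x$times), " records over ",
      max(x$times), " time units (dt = ", x$settings$dt, ", noise = ",
      x$settings$noise_mode, ", burn-in = ", x$settings$burn_in, ")\n",
      sep = "")
  invisible(x)
}

#' Extract one variable of one cell from a trajectory
#'
#' @param traj a `dialog_trajectory`.
#' @param cell 1 or 2.
#' @param variable one of `"A", "I", "X", "Y", "Z"`.
#' @return Numeric vector aligned with `traj$times`.
#' @export
trajectory_variable <- function(traj, cell = 1, variable = "A") {
  stopifnot(inherits(traj, "dialog_trajectory"))
  variable <- match.arg(variable, c("A", "I", "X", "Y", "Z"))
  if (!cell %in% c(1, 2)) stop("cell must be 1 or 2")
  traj$states[, paste0(variable, cell)]
}

#' Step-halving convergence check for the deterministic integrator
#'
#' Runs the noise-free model at `dt` and `dt / 2` over the same horizon and
#' reports the maximum absolute state discrepancy on the common grid --
#' a standard sanity check that the fixed Euler step resolves the dynamics.
#'
#' @param params a `dialog_params` object.
#' @param schedule distance schedule or constant distance.
#' @param total_time horizon (no burn-in).
#' @param dt the coarse step; the comparison run uses `dt / 2`.
#' @return List with `max_discrepancy`, the per-variable maxima
#'   `by_variable`, and the two step sizes.
#' @export
deterministic_convergence_check <- function(params = default_parameters(),
                                            schedule = NULL,
                                            total_time = 20, dt = 0.001) {
  mk <- function(step) {
    simulation_settings(dt = step, total_time = total_time, burn_in = 0,
                        record_stride = max(1L, as.integer(round(0.1 / step))),
                        noise_mode = "off")
  }
  t1 <- simulate_dialog(params, mk(dt), schedule)
  t2 <- simulate_dialog(params, mk(dt / 2), schedule)
  n <- min(nrow(t1$states), nrow(t2$states))
  dif <- abs(t1$states[seq_len(n), , drop = FALSE] -
             t2$states[seq_len(n), , drop = FALSE])
  by_var <- apply(dif, 2, max)
  list(max_discrepancy = max(by_var), by_variable = by_var,
       dt = dt, dt_half = dt / 2)
}
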