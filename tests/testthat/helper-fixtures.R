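# Shared fixtures: analytic test traces and a deSolve reference integrator.

sine_trace <- function(period = 100, duration = 1000, dt = 2, phase = 0,
                       unit = "s") {
  t <- seq(0, duration, dt)
  intensity_trace(t, sin(2 * pi * t / period + phase), time_unit = unit)
}

# Independent deterministic oracle: classical fixed-step Runge-Kutta at a
# finer step than the package's Euler scheme, via deSolve.
rk_oracle <- function(params, d, times, hini = 1e-4) {
  rhs <- function(t, u, parms) {
    list(params$tau * as.numeric(drift(u, params, d = d)))
  }
  out <- deSolve::ode(as.numeric(initial_state()), times, rhs, NULL,
                      method = "rk4", hini = hini)
  unname(out[, -1])
}

random_nonneg_state <- function() {
  stats::runif(10, 0, 6)
}
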