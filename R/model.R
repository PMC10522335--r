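#' Drift of the two-cell dialogue model
#'
#' Evaluates the deterministic part F(U) of the model, un-scaled by the
#' time constant `tau` (the integrator applies `tau`).  Per cell c with
#' partner o:
#' \deqn{dA_c = a_0 - \alpha A_c + \beta A_c^2 - A_c^3 - A_c I_c + A_c Z_c}
#' \deqn{dI_c = \epsilon (i_0 + \gamma A_c^2 / (A_c^2 + k) - I_c)}
#' \deqn{dX_c = x_0 - k_1 A_c^2 X_c}
#' \deqn{dY_c = k_1 A_c^2 X_c - k_2 Y_c / (A_c^3 + 1)}
#' \deqn{dZ_c = -k_{cext}(Z_c - C_{media}) + k_2 Y_c / (A_c^3 + 1) - A_c Z_c
#'   + k_z e^{-d} Z_o - k_z e^{-d} Z_c}
#'
#' @param state numeric vector of length 10
#'   (`A1, I1, X1, Y1, Z1, A2, I2, X2, Y2, Z2`).
#' @param params a `dialog_params` object.
#' @param d inter-cell distance; defaults to `params$d`.
#' @return Named numeric vector of length 10 with the drift components.
#' @export
#' @examples
#' drift(initial_state(), default_parameters())
drift <- function(state, params, d = params$d) {
  check_state(state)
  if (d < 0) stop("distance d must be >= 0")
  kd <- params$kz * exp(-d)
  out <- numeric(10)
  for (c in 0:1) {
    A <- state[5 * c + 1]; I <- state[5 * c + 2]; X <- state[5 * c + 3]
    Y <- state[5 * c + 4]; Z <- state[5 * c + 5]
    Zo <- state[5 * (1 - c) + 5]
    rel <- params$k2 * Y / (A^3 + 1)
    hill <- params$gamma * A^2 / (A^2 + params$k)
    out[5 * c + 1] <- params$a0 - params$alpha * A + params$beta * A^2 -
      A^3 - A * I + A * Z
    out[5 * c + 2] <- params$epsilon * (params$i0 + hill - I)
    out[5 * c + 3] <- params$x0 - params$k1 * A^2 * X
    out[5 * c + 4] <- params$k1 * A^2 * X - rel
    out[5 * c + 5] <- -params$kcext * (Z - params$cmedia) + rel - A * Z +
      kd * Zo - kd * Z
  }
  stats::setNames(out, STATE_NAMES)
}

check_state <- function(state) {
  if (length(state) != 10)
    stop("state must have 10 entries (A1, I1, X1, Y1, Z1, A2, I2, X2, Y2, Z2)")
  bad <- which(!is.finite(state))
  if (length(bad) > 0)
    stop("non-finite state variable: ", paste(STATE_NAMES[bad], collapse = ", "))
  invisible(state)
}

#' Per-channel noise propensities
#'
#' Evaluates the 38 independent Wiener-channel magnitudes of the noise
#' function G(U), 19 per cell, grouped per target variable as
#' A: 6, I: 3, X: 2, Y: 2, Z: 6.  Channels that share a formula across
#' variables (the vesicle-release term appears in both the Y and Z rows)
#' carry distinct channel indices and therefore independent processes.
#' Propensities are evaluated on the state clamped at zero, so they are
#' nonnegative for any input.
#'
#' @inheritParams drift
#' @return A data frame with one row per channel and columns `cell`,
#'   `channel_index` (1-19 within a cell), `target_variable`
#'   (one of `"A", "I", "X", "Y", "Z"`) and `propensity`.
#' @export
noise_propensities <- function(state, params, d = params$d) {
  check_state(state)
  if (d < 0) stop("distance d must be >= 0")
  kd <- params$kz * exp(-d)
  s <- pmax(state, 0)
  rows <- list()
  for (c in 0:1) {
    A <- s[5 * c + 1]; I <- s[5 * c + 2]; X <- s[5 * c + 3]
    Y <- s[5 * c + 4]; Z <- s[5 * c + 5]
    Zo <- s[5 * (1 - c) + 5]
    rel <- params$k2 * Y / (A^3 + 1)
    hill <- params$gamma * A^2 / (A^2 + params$k)
    g <- c(params$a0, params$alpha * A, params$beta * A^2, A^3, A * I, A * Z,
           params$epsilon * params$i0, params$epsilon * hill,
           params$epsilon * I,
           params$x0, params$k1 * A^2 * X,
           params$k1 * A^2 * X, rel,
           params$kcext * Z, params$kcext * params$cmedia, rel, A * Z,
           kd * Zo, kd * Z)
    rows[[c + 1]] <- data.frame(
      cell = c + 1L,
      channel_index = 1:19,
      target_variable = c(rep("A", 6), rep("I", 3), rep("X", 2),
                          rep("Y", 2), rep("Z", 6)),
      propensity = g,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Distance-dependent coupling rate
#'
#' The tip-to-tip exchange rate of extracellular signaling component,
#' `kz * exp(-d)`.  It decays exponentially with the inter-cell distance,
#' so that two distant cells are effectively uncoupled.
#'
#' @inheritParams drift
#' @return A single nonnegative number.
#' @export
#' @examples
#' coupling_rate(default_parameters(), d = 0)   # kz
#' coupling_rate(default_parameters(), d = 10)  # ~4.5e-4
coupling_rate <- function(params, d = params$d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d))
    stop("distance d must be a single number")
  if (d < 0) stop("distance d must be >= 0")
  params$kz * exp(-d)
}
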