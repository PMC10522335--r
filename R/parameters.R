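#' Model parameters for the two-cell dialogue model
#'
#' Constructs the full parameter set of the stochastic two-cell
#' excitable-oscillator model.  Each hyphal cell carries an activator
#' (`A`), an inhibitor (`I`), free vesicles (`X`), docked vesicles (`Y`)
#' and the extracellular signaling concentration at its tip (`Z`); the
#' two tips exchange signaling component at rate `kz * exp(-d)` where `d`
#' is the (dimensionless) inter-cell distance.
#'
#' The defaults are the published constants of the model:
#' tau = 8.48, epsilon = 0.55, alpha = 12.4, beta = 8.05, gamma = 8,
#' k = 6, a0 = 5.6, i0 = 0.1, x0 = 1.0, k1 = 0.1, k2 = 1.0, kz = 10.0,
#' kcext = 5, cmedia = 1, omega = 1000, with d defaulting to 10
#' ("long distance").  One model time unit corresponds to one minute.
#'
#' @param tau time-scaling constant multiplying both drift and noise.
#' @param epsilon inhibitor time-scale separation.
#' @param alpha,beta activator linear and quadratic coefficients.
#' @param gamma inhibitor production gain.
#' @param k inhibitor-production half-saturation constant.
#' @param a0,i0,x0 basal production of activator, inhibitor and free vesicles.
#' @param k1 vesicle-docking rate coefficient.
#' @param k2 vesicle-release rate coefficient.
#' @param kz extracellular tip-to-tip exchange rate coefficient.
#' @param kcext media-exchange rate.
#' @param cmedia bulk-media signaling concentration (the depletion scenarios
#'   lower this toward 0).
#' @param d inter-cell distance (dimensionless); coupling is `kz * exp(-d)`.
#' @param omega system size controlling the noise magnitude (fluctuations
#'   shrink as omega grows).
#' @param ... overrides passed as named values, checked against the field set.
#'
#' @return An object of class `dialog_params`: a named list of the 16 fields.
#' @seealso [drift()], [simulate_dialog()], [coupling_rate()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$kz
#' default_parameters(cmedia = 0)$cmedia
default_parameters <- function(tau = 8.48, epsilon = 0.55, alpha = 12.4,
                               beta = 8.05, gamma = 8, k = 6, a0 = 5.6,
                               i0 = 0.1, x0 = 1.0, k1 = 0.1, k2 = 1.0,
                               kz = 10.0, kcext = 5, cmedia = 1, d = 10,
                               omega = 1000, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    stop("unknown parameter field(s): ", paste(names(extra), collapse = ", "))
  p <- list(tau = tau, epsilon = epsilon, alpha = alpha, beta = beta,
            gamma = gamma, k = k, a0 = a0, i0 = i0, x0 = x0, k1 = k1,
            k2 = k2, kz = kz, kcext = kcext, cmedia = cmedia, d = d,
            omega = omega)
  validate_parameters(p)
  structure(p, class = "dialog_params")
}

PARAM_FIELDS <- c("tau", "epsilon", "alpha", "beta", "gamma", "k", "a0",
                  "i0", "x0", "k1", "k2", "kz", "kcext", "cmedia", "d",
                  "omega")

validate_parameters <- function(p) {
  missing <- setdiff(PARAM_FIELDS, names(p))
  if (length(missing) > 0)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  for (f in PARAM_FIELDS) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  strict_pos <- setdiff(PARAM_FIELDS, c("cmedia", "d"))
  for (f in strict_pos)
    if (p[[f]] <= 0) stop("parameter '", f, "' must be strictly positive")
  if (p$cmedia < 0) stop("parameter 'cmedia' must be >= 0")
  if (p$d < 0) stop("parameter 'd' must be >= 0")
  invisible(p)
}

# Order expected by the C++ core (d excluded; distance enters via schedule).
param_vector <- function(p) {
  c(p$tau, p$epsilon, p$alpha, p$beta, p$gamma, p$k, p$a0, p$i0, p$x0,
    p$k1, p$k2, p$kz, p$kcext, p$cmedia, p$omega)
}

#' @export
print.dialog_params <- function(x, ...) {
  cat("Two-cell dialogue model parameters:\n")
  for (f in PARAM_FIELDS) cat(sprintf("  %-7s = %g\n", f, x[[f]]))
  invisible(x)
}

#' Canonical initial state of the simulations
#'
#' Both cells start from the same sub-threshold rest values
#' (A = 0.7065, I = 0.7145, X = Y = 0, Z = 1) so that all dynamics after
#' the burn-in are attributable to the model, not to the initialization.
#'
#' @return Named numeric vector of length 10
#'   (`A1, I1, X1, Y1, Z1, A2, I2, X2, Y2, Z2`).
#' @export
initial_state <- function() {
  stats::setNames(c(0.7065, 0.7145, 0, 0, 1.0, 0.7065, 0.7145, 0, 0, 1.0),
                  STATE_NAMES)
}

STATE_NAMES <- c("A1", "I1", "X1", "Y1", "Z1", "A2", "I2", "X2", "Y2", "Z2")

#' Serialize and restore model parameters
#'
#' Writes the 16 parameter fields to a YAML or JSON file (chosen from the
#' file extension) and reads them back; field names are exactly those of
#' [default_parameters()].  Unknown keys on read are rejected.
#'
#' @param p a `dialog_params` object.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a `dialog_params` object.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "dialog_params"))
  fields <- unclass(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(fields, path)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), PARAM_FIELDS)
  if (length(unknown) > 0)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  do.call(default_parameters, raw)
}
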