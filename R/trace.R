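#' Uniformly sampled intensity trace
#'
#' The common container of the analysis stage: a uniformly sampled
#' intensity time series, e.g. tip fluorescence of a reporter, or one model
#' variable converted to a pseudo-fluorescence signal.
#'
#' @param times sample times, strictly increasing and uniformly spaced
#'   (relative tolerance 1e-9).
#' @param values intensities (arbitrary units), finite, same length.
#' @param label free-text label (e.g. `"SofT-GFP tip 1"`).
#' @param time_unit `"s"` for seconds or `"model"` for model time units
#'   (one model unit = one minute).
#' @return Object of class `intensity_trace`.
#' @export
intensity_trace <- function(times, values, label = "",
                            time_unit = c("s", "model")) {
  time_unit <- match.arg(time_unit)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 2) stop("a trace needs at least 2 samples")
  if (any(!is.finite(times))) stop("non-finite sample times")
  if (any(!is.finite(values))) stop("non-finite intensity values")
  dtv <- diff(times)
  if (any(dtv <= 0)) stop("sample times must be strictly increasing")
  step <- stats::median(dtv)
  if (any(abs(dtv - step) > 1e-9 * max(abs(times), 1)))
    stop("sample times must be uniformly spaced (first offending index: ",
         which(abs(dtv - step) > 1e-9 * max(abs(times), 1))[1] + 1, ")")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label, time_unit = time_unit, step = step),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat("Intensity trace", if (nzchar(x$label)) paste0(" '", x$label, "'"),
      ": ", length(x$times), " samples, step ", signif(x$step, 4), " ",
      x$time_unit, "\n", sep = "")
  invisible(x)
}

sampling_interval <- function(trace) trace$step

#' Convert a model trajectory into a pseudo-fluorescence trace
#'
#' Maps one variable of one cell through an affine gain/offset, optionally
#' adds white measurement noise, and downsamples to a coarser interval --
#' mimicking how a fluorescent reporter renders a model variable.  Model
#' time units are converted to seconds (1 unit = 60 s) when
#' `time_unit = "s"`.
#'
#' @param traj a `dialog_trajectory`.
#' @param cell 1 or 2.
#' @param variable one of `"A", "I", "X", "Y", "Z"`.
#' @param gain,offset affine map `gain * value + offset`.
#' @param noise_sd additive white-noise SD (post-gain intensity units).
#' @param sample_interval desired sampling interval in trajectory time
#'   units; must be a multiple of the recording spacing.
#' @param seed RNG seed for the measurement noise.
#' @param time_unit unit of the output trace.
#' @return An [intensity_trace()].
#' @export
trajectory_to_trace <- function(traj, cell = 1, variable = "A", gain = 1,
                                offset = 0, noise_sd = 0,
                                sample_interval = NULL, seed = NULL,
                                time_unit = c("model", "s")) {
  stopifnot(inherits(traj, "dialog_trajectory"))
  time_unit <- match.arg(time_unit)
  v <- trajectory_variable(traj, cell, variable)
  step <- traj$settings$dt * traj$settings$record_stride
  if (is.null(sample_interval)) sample_interval <- step
  ratio <- sample_interval / step
  if (abs(ratio - round(ratio)) > 1e-8 || round(ratio) < 1)
    stop("sample_interval must be a positive multiple of the recording ",
         "spacing (", step, ")")
  idx <- seq(1, length(v), by = round(ratio))
  tt <- traj$times[idx]
  vv <- gain * v[idx] + offset
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vv <- vv + stats::rnorm(length(vv), 0, noise_sd)
  }
  if (time_unit == "s") tt <- tt * 60
  intensity_trace(tt, vv, label = paste0(variable, cell), time_unit = time_unit)
}
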