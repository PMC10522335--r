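#' Load a run configuration
#'
#' Reads a structured config file (YAML or JSON, decided by extension)
#' with up to four sections -- `parameters`, `settings`, `schedule`,
#' `analysis` -- plus `output_dir` and `log_level`.  Unknown keys anywhere
#' are rejected with a named-field diagnostic; missing values are filled
#' with the package defaults (the published parameter set, dt = 0.001,
#' burn-in 200).  An empty file therefore yields the full default
#' configuration.
#'
#' @param path config file path.
#' @return Object of class `run_config`: list with `parameters`
#'   (`dialog_params`), `settings` (`simulation_settings`), `schedule`
#'   (`distance_schedule`), `analysis` (list of analysis options),
#'   `output_dir`, `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  build_config(raw)
}

CONFIG_SECTIONS <- c("parameters", "settings", "schedule", "analysis",
                     "output_dir", "log_level")
SETTINGS_FIELDS <- c("dt", "total_time", "burn_in", "record_stride", "seed",
                     "noise_mode", "clamp_nonnegative", "per_channel",
                     "mirror_noise")
SCHEDULE_FIELDS <- c("kind", "d_start", "d_end", "ramp_start", "ramp_end",
                     "times", "values")
ANALYSIS_FIELDS <- c("min_prominence_fraction", "min_distance", "bin_width",
                     "window_length")

build_config <- function(raw) {
  unknown <- setdiff(names(raw), CONFIG_SECTIONS)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  reject_unknown <- function(x, allowed, section) {
    u <- setdiff(names(x), allowed)
    if (length(u) > 0)
      stop("unknown key(s) in '", section, "': ", paste(u, collapse = ", "))
    x
  }
  pars <- reject_unknown(raw$parameters %||% list(), PARAM_FIELDS,
                         "parameters")
  params <- do.call(default_parameters, pars)
  sets <- reject_unknown(raw$settings %||% list(), SETTINGS_FIELDS,
                         "settings")
  settings <- do.call(simulation_settings, sets)
  sch_raw <- reject_unknown(raw$schedule %||% list(), SCHEDULE_FIELDS,
                            "schedule")
  schedule <- if (length(sch_raw) == 0) {
    constant_schedule(params$d)
  } else {
    kind <- sch_raw$kind %||% "constant"
    switch(kind,
      constant = constant_schedule(sch_raw$d_start %||% params$d),
      linear_ramp = ramp_schedule(sch_raw$d_start %||% 10,
                                  sch_raw$d_end %||% 0,
                                  sch_raw$ramp_start %||% 0,
                                  sch_raw$ramp_end %||% 30),
      piecewise = piecewise_schedule(unlist(sch_raw$times),
                                     unlist(sch_raw$values)),
      stop("unknown schedule kind: ", kind))
  }
  ana_raw <- reject_unknown(raw$analysis %||% list(), ANALYSIS_FIELDS,
                            "analysis")
  analysis <- utils::modifyList(
    list(min_prominence_fraction = 0.2, min_distance = NULL,
         bin_width = 20, window_length = 10),
    ana_raw)
  if (analysis$min_prominence_fraction <= 0 ||
      analysis$min_prominence_fraction >= 1)
    stop("config field 'min_prominence_fraction' must be in (0, 1)")
  structure(list(parameters = params, settings = settings,
                 schedule = schedule, analysis = analysis,
                 output_dir = raw$output_dir %||% ".",
                 log_level = raw$log_level %||% "INFO"),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes a `run_config` back to YAML or JSON so that a run directory
#' carries its fully resolved configuration; `load_config` of the result
#' reproduces the configuration exactly.
#'
#' @param config a `run_config`.
#' @param path destination path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  sch <- schedule_meta(config$schedule)
  out <- list(parameters = unclass(config$parameters),
              settings = unclass(config$settings)[SETTINGS_FIELDS],
              schedule = sch,
              analysis = config$analysis,
              output_dir = config$output_dir,
              log_level = config$log_level)
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  out <- lapply(out, function(x) if (is.list(x)) drop_null(x) else x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Trajectory and trace CSV input/output
#'
#' `write_trajectory_csv` writes a simulated trajectory in long format
#' (columns `time`, `cell`, `variable`, `value`; 10 data rows per record)
#' with full floating-point precision, plus a JSON metadata sidecar
#' (`<path>.meta.json`) holding parameters, settings, schedule and seed so
#' the run can be reproduced exactly.  `write_trace_csv` and
#' `read_trace_csv` round-trip a single intensity trace (columns `time`,
#' `value`); the header row is mandatory and the time grid must be
#' uniform.
#'
#' @param traj a `dialog_trajectory`.
#' @param trace an [intensity_trace()].
#' @param path CSV file path.
#' @param time_unit declared unit of the trace times on read.
#' @return The written path (writers, invisibly); an `intensity_trace`
#'   (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "dialog_trajectory"))
  n <- length(traj$times)
  long <- data.frame(
    time = rep(traj$times, each = 10),
    cell = rep(rep(1:2, each = 5), n),
    variable = rep(rep(c("A", "I", "X", "Y", "Z"), 2), n),
    value = as.vector(t(traj$states)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,cell,variable,value", con)
  writeLines(sprintf("%.17g,%d,%s,%.17g", long$time, long$cell,
                     long$variable, long$value), con)
  meta <- list(parameters = unclass(traj$params),
               settings = unclass(traj$settings)[SETTINGS_FIELDS],
               schedule = schedule_meta(traj$schedule),
               seed = traj$seed, single_cell = traj$single_cell)
  meta <- lapply(meta, function(x)
    if (is.list(x)) x[!vapply(x, is.null, logical(1))] else x)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,value", con)
  writeLines(sprintf("%.17g,%.17g", trace$times, trace$values), con)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trace_csv <- function(path, time_unit = c("s", "model")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1)
  cols <- strsplit(header, ",")[[1]]
  if (!all(c("time", "value") %in% cols))
    stop("trace CSV must have a header row with columns 'time' and 'value'")
  df <- utils::read.csv(path)
  dtv <- diff(df$time)
  # reference step: the most frequent spacing (robust to a few bad rows)
  tab <- table(signif(dtv, 9))
  step <- as.numeric(names(tab)[which.max(tab)])
  bad <- which(abs(dtv - step) > 1e-9 * max(abs(df$time), 1))
  if (length(bad) > 0)
    stop("non-uniform time grid at row ", bad[1] + 2) # 1-based incl. header
  lbl <- if ("label" %in% cols) as.character(df$label[1]) else ""
  intensity_trace(df$time, df$value, label = lbl, time_unit = time_unit)
}
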