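## CSV readers/writers for the instrument-trace dialects, and YAML
## manifests recording ground-truth parameters and seeds next to the
## generated files. One series per file, header row mandatory.

read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop_io("cannot read %s: %s", path,
                                             conditionMessage(e)))
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_io("%s lacks required column(s): %s", path,
            paste(missing, collapse = ", "))
  df
}

#' Read / write flow-curve CSV files
#'
#' Dialect: columns `shear_rate_per_s,viscosity_pa_s,replicate`.
#'
#' @param path CSV file path.
#' @param curves a list of [flow_curve()] objects (for writing).
#' @return `read_flow_curve_csv` returns a list of [flow_curve()]
#'   objects, one per replicate; `write_flow_curve_csv` returns `path`
#'   invisibly.
#' @export
read_flow_curve_csv <- function(path) {
  df <- read_checked_csv(path, c("shear_rate_per_s", "viscosity_pa_s",
                                 "replicate"))
  lapply(split(df, df$replicate), function(s) {
    s <- s[order(s$shear_rate_per_s), ]
    flow_curve(s$shear_rate_per_s, s$viscosity_pa_s,
               replicate_id = as.character(s$replicate[1L]))
  })
}

#' @rdname read_flow_curve_csv
#' @export
write_flow_curve_csv <- function(curves, path) {
  if (inherits(curves, "flow_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(shear_rate_per_s = cv$shear_rate,
               viscosity_pa_s = cv$viscosity,
               replicate = cv$replicate_id)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write thinning-trace CSV files
#'
#' Dialect: columns `time_s,diameter_m`.
#'
#' @param path CSV file path.
#' @param trace a [thinning_trace()] (for writing).
#' @param ... geometry arguments passed to [thinning_trace()] when
#'   reading.
#' @return `read_thinning_csv` returns a [thinning_trace()];
#'   `write_thinning_csv` returns `path` invisibly.
#' @export
read_thinning_csv <- function(path, ...) {
  df <- read_checked_csv(path, c("time_s", "diameter_m"))
  thinning_trace(df$time_s, df$diameter_m, ...)
}

#' @rdname read_thinning_csv
#' @export
write_thinning_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time, diameter_m = trace$diameter),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write friction-curve CSV files
#'
#' Dialects: `speed_m_per_s,mu` for ready-made Stribeck data, or
#' `omega_per_s,torque_n_m` for raw plate-on-plate sweeps, which are
#' converted with \eqn{U = \Omega R} and \eqn{\mu = M/(R F_N)}.
#'
#' @param path CSV file path.
#' @param surface,plate_radius,normal_force conversion/metadata
#'   arguments.
#' @param curve a [friction_curve()] (for writing).
#' @return `read_friction_csv` returns a [friction_curve()];
#'   `write_friction_csv` returns `path` invisibly.
#' @export
read_friction_csv <- function(path, surface = "smooth_pdms",
                              plate_radius = 0.025, normal_force = 1.0) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  if (all(c("speed_m_per_s", "mu") %in% names(df))) {
    df <- df[order(df$speed_m_per_s), ]
    friction_curve(df$speed_m_per_s, df$mu, surface = surface)
  } else if (all(c("omega_per_s", "torque_n_m") %in% names(df))) {
    df <- df[order(df$omega_per_s), ]
    friction_curve(entrainment_from_angular(df$omega_per_s, plate_radius),
                   friction_from_torque(df$torque_n_m, plate_radius,
                                        normal_force),
                   surface = surface)
  } else {
    stop_io("%s matches neither friction dialect (speed_m_per_s,mu or omega_per_s,torque_n_m)",
            path)
  }
}

#' @rdname read_friction_csv
#' @export
write_friction_csv <- function(curve, path) {
  write.csv(data.frame(speed_m_per_s = curve$speed, mu = curve$mu),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write QCM-D trace CSV files
#'
#' Dialect: columns `time_s,delta_f_hz`; injection/rinse markers are
#' given separately (they come from the run log, not the trace).
#'
#' @param path CSV file path.
#' @param injection_time,rinse_time s, phase markers.
#' @param trace a [qcmd_trace()] (for writing).
#' @return `read_qcmd_csv` returns a [qcmd_trace()]; `write_qcmd_csv`
#'   returns `path` invisibly.
#' @export
read_qcmd_csv <- function(path, injection_time, rinse_time) {
  df <- read_checked_csv(path, c("time_s", "delta_f_hz"))
  qcmd_trace(df$time_s, df$delta_f_hz, injection_time, rinse_time)
}

#' @rdname read_qcmd_csv
#' @export
write_qcmd_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time, delta_f_hz = trace$delta_f),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic data set with its ground-truth manifest
#'
#' Writes the four CSV series of one [generate_preset_sample()] result
#' into a directory plus a YAML manifest recording the preset name, seed
#' and every ground-truth generator parameter.
#'
#' @param sample a [generate_preset_sample()] result.
#' @param dir output directory (created if needed).
#' @param seed the seed the sample was generated with (recorded in the
#'   manifest).
#' @return the manifest path, invisibly.
#' @export
write_synthetic_sample <- function(sample, dir, seed) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io("cannot create directory %s", dir)
  write_flow_curve_csv(sample$flow, file.path(dir, "flow_curve.csv"))
  write_thinning_csv(sample$thinning, file.path(dir, "thinning.csv"))
  write_friction_csv(sample$friction, file.path(dir, "friction.csv"))
  write_qcmd_csv(sample$qcmd, file.path(dir, "qcmd.csv"))
  strip <- function(p) unclass(p)[!vapply(unclass(p), is.null, logical(1L))]
  manifest <- list(preset = sample$preset, seed = seed,
                   sigma_n_per_m = sample$sigma,
                   ground_truth = list(
                     flow = strip(sample$params$flow),
                     thinning = strip(sample$params$thinning),
                     stribeck = strip(sample$params$stribeck),
                     qcmd = strip(sample$params$qcmd)),
                   files = list(flow = "flow_curve.csv",
                                thinning = "thinning.csv",
                                friction = "friction.csv",
                                qcmd = "qcmd.csv"))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
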