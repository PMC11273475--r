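#' Write a 3-D array as a legacy-ASCII VTK structured-points file
#'
#' Writes scalar cell data on the phantom's regular grid in the legacy VTK
#' text format, readable by ParaView/VisIt. Used for phantom labels and
#' temperature snapshots.
#'
#' @param arr numeric or integer 3-D array (cell data; `NA` written as
#'   -9999).
#' @param path output file path.
#' @param spacing cell edge length, m.
#' @param origin grid corner coordinates, m.
#' @param name data array name.
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(arr, path, spacing, origin = c(0, 0, 0),
                                 name = "value") {
  d <- dim(arr)
  v <- as.vector(arr)
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    name,
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1] + 1L, d[2] + 1L, d[3] + 1L),
    sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
    sprintf("SPACING %g %g %g", spacing, spacing, spacing),
    sprintf("CELL_DATA %d", length(v)),
    sprintf("SCALARS %s float 1", name),
    "LOOKUP_TABLE default"), con)
  writeLines(formatC(v, format = "g", digits = 7), con)
  invisible(path)
}

#' Write a phantom to VTK
#'
#' @param phantom a `voxel_phantom`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phantom_vtk <- function(phantom, path) {
  h <- phantom$voxel_size
  origin <- c(phantom$x[1], phantom$y[1], phantom$z[1]) - h / 2
  write_vtk_structured(phantom$labels, path, h, origin, name = "tissue_label")
}

#' Write a thermal snapshot to VTK
#'
#' @param state a `thermal_state`.
#' @param phantom the `voxel_phantom` the state lives on.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_state_vtk <- function(state, phantom, path) {
  h <- phantom$voxel_size
  origin <- c(phantom$x[1], phantom$y[1], phantom$z[1]) - h / 2
  write_vtk_structured(state$temperature, path, h, origin,
                       name = "temperature_C")
}

#' Write and read a run configuration as YAML
#'
#' Round-trips a [mih_config()] configuration losslessly through a YAML
#' file.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `write_run_config()` returns `path`; `read_run_config()` the
#'   configuration.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# recursive merge that, unlike modifyList, preserves explicit NULL entries
# (they mean "unset" in the configuration, e.g. an uncalibrated tau_eff)
merge_config <- function(base, upd) {
  for (i in seq_along(upd)) {
    nm <- names(upd)[i]
    v <- upd[[i]]
    if (is.list(v) && !is.null(names(v)) && is.list(base[[nm]])) {
      base[nm] <- list(merge_config(base[[nm]], v))
    } else {
      base[nm] <- list(v)
    }
  }
  base
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- merge_config(mih_config(), yaml::read_yaml(path))
  # yaml reads named numeric vectors back as lists; restore the ones used
  for (key in c("brain_semiaxes_m", "stub_halfwidth_m")) {
    cfg$phantom[[key]] <- as.numeric(unlist(cfg$phantom[[key]]))
  }
  cfg$coil$layout <- unlist(cfg$coil$layout)
  cfg$report$snapshot_times_s <-
    as.numeric(unlist(cfg$report$snapshot_times_s))
  structure(cfg, class = class(mih_config()))
}

#' Write the artifacts of a pipeline run
#'
#' Writes the JSON dose report, probe-curve CSV, exposure CSV, coil
#' axis-profile CSV, the phantom VTK and one VTK snapshot per configured
#' snapshot time into `dir`.
#'
#' @param run a `mih_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(dose_report(run), file.path(dir, "dose_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(run$probes, file.path(dir, "probes.csv"),
                   row.names = FALSE)
  utils::write.csv(run$exposure, file.path(dir, "exposure.csv"),
                   row.names = FALSE)
  utils::write.csv(run$axis_profile[, c("x", "B_T")],
                   file.path(dir, "axis_profile.csv"), row.names = FALSE)
  write_phantom_vtk(run$phantom, file.path(dir, "phantom.vtk"))
  for (nm in names(run$snapshots)) {
    write_state_vtk(run$snapshots[[nm]], run$phantom,
                    file.path(dir, paste0("temperature_", nm, ".vtk")))
  }
  invisible(dir)
}
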