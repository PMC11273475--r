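#' Default run configuration
#'
#' The nested configuration driving [run_pipeline()]. Every entry has a
#' documented default reproducing the reference scenario: the 180-turn
#' Helmholtz pair driven at 8 A / 100 kHz with the center-plane separation
#' calibrated to a center flux density of 8.5621 mT, magnetite-like
#' particles at volume fraction 0.003 with the relaxation time calibrated
#' to a loss power of 673,920 W/m^3 at the reference field strength, source
#' correction factor 0.55, and a 300 s implicit bioheat solve at 0.5 mm
#' voxels from a uniform 37 degC start. Configurations round-trip
#' losslessly through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param ... named overrides, merged recursively into the defaults (e.g.
#'   `thermal = list(duration_s = 60)`).
#' @return A nested list of class `run_config`.
#' @export
#' @examples
#' cfg <- mih_config(thermal = list(duration_s = 10))
#' cfg$thermal$duration_s
mih_config <- function(...) {
  cfg <- list(
    phantom = list(
      voxel_size_m = 0.5e-3,
      tumor_area_m2 = 451.52e-6,
      tumor_thickness_m = 2e-3,
      scalp_thickness_m = 1e-3,
      skull_thickness_m = 1e-3,
      brain_semiaxes_m = c(8e-3, 6e-3, 6e-3),
      tumor_embed_m = 0.5e-3,
      stub_halfwidth_m = c(8e-3, 7e-3),
      stub_length_m = 8e-3,
      margin_m = 2e-3
    ),
    coil = list(
      turns = 180,
      inner_radius_m = 0.14,
      outer_radius_m = 0.15,
      width_m = 0.05,
      separation_m = NULL,          # NULL: Helmholtz condition (mean radius)
      layout = c(radial = 12, axial = 15),
      calibrate_to_B_T = 8.5621e-3  # NULL to keep separation_m as given
    ),
    drive = list(current_A = 8, frequency_Hz = 1e5),
    particles = list(
      Md_A_per_m = 446e3,
      diameter_m = 19e-9,
      phi = 0.003,
      temperature_K = 310.15,
      tau_eff_s = NULL,             # NULL: calibrate to the target below
      calibrate_to_P0_W_m3 = 673920,
      calibration_H_A_per_m = 6814.2
    ),
    source = list(alpha = 0.55, per_voxel_field = FALSE),
    thermal = list(
      duration_s = 300, dt_s = 1, scheme = "implicit",
      blood_rho = 1060, blood_c = 3650, blood_T_C = 37, T_init_C = 37,
      bc_air = list(type = "insulated", h = 10, T_ambient_C = 25),
      bc_far = list(type = "fixed", T_C = 37),
      output_every_s = 5
    ),
    report = list(
      tumor_threshold_C = 42, brain_threshold_C = 38.5,
      snapshot_times_s = c(0, 100, 300)
    ),
    outdir = NULL
  )
  structure(utils::modifyList(cfg, list(...)), class = "run_config")
}

config_phantom <- function(cfg) {
  p <- cfg$phantom
  build_head_phantom(
    voxel_size = p$voxel_size_m,
    geometry = head_geometry(
      tumor_area = p$tumor_area_m2, tumor_thickness = p$tumor_thickness_m,
      scalp_thickness = p$scalp_thickness_m,
      skull_thickness = p$skull_thickness_m,
      brain_semiaxes = p$brain_semiaxes_m, tumor_embed = p$tumor_embed_m,
      stub_halfwidth = p$stub_halfwidth_m, stub_length = p$stub_length_m,
      margin = p$margin_m))
}

config_coil <- function(cfg) {
  co <- cfg$coil
  coil <- coil_spec(turns = co$turns, inner_radius = co$inner_radius_m,
                    outer_radius = co$outer_radius_m, width = co$width_m,
                    separation = co$separation_m, layout = co$layout)
  drive <- drive_current(cfg$drive$current_A, cfg$drive$frequency_Hz)
  if (!is.null(co$calibrate_to_B_T)) {
    coil <- calibrate_separation(coil, drive, co$calibrate_to_B_T)
  }
  list(coil = coil, drive = drive)
}

config_particles <- function(cfg, H_center) {
  pa <- cfg$particles
  spec <- nanoparticle_spec(Md = pa$Md_A_per_m, diameter = pa$diameter_m,
                            phi = pa$phi, temperature = pa$temperature_K,
                            tau_eff = pa$tau_eff_s)
  if (is.null(spec$tau_eff)) {
    H_ref <- if (is.null(pa$calibration_H_A_per_m)) H_center else
      pa$calibration_H_A_per_m
    spec <- calibrate_relaxation_time(spec, pa$calibrate_to_P0_W_m3, H_ref,
                                      f = cfg$drive$frequency_Hz)
  }
  spec
}

#' Run the full hyperthermia pipeline
#'
#' Executes the stages in order — phantom, coil field (with separation
#' calibration), field-to-source conversion via the relaxation-loss model,
#' the Pennes bioheat solve, exposure estimates and the dose report — and
#' returns everything as a `mih_run` object. The run is fully deterministic
#' given the configuration. If `config$outdir` is set, artifacts (JSON dose
#' report, probe CSV, exposure CSV, axis-profile CSV, VTK snapshots) are
#' written there.
#'
#' @param config a [mih_config()] configuration.
#' @param quiet suppress stage progress messages.
#' @return An object of class `mih_run`: the dose report (field summary,
#'   per-region temperature statistics, coverage fractions, probe curves)
#'   plus the `phantom`, final `state`, `snapshots`, `exposure` table and
#'   the resolved `coil`/`particles` stages.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(mih_config(
#'   phantom = list(voxel_size_m = 1e-3),
#'   thermal = list(duration_s = 30)))
#' res
#' }
run_pipeline <- function(config = mih_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("stage phantom: voxelizing head phantom")
  phantom <- stage("phantom", config_phantom(config))

  say("stage coil_field: Biot-Savart winding superposition")
  cd <- stage("coil_field", config_coil(config))
  v0 <- voxel_at(phantom, c(0, 0, 0))
  tumor_center <- c(phantom$x[v0[1]], phantom$y[v0[2]], phantom$z[v0[3]])
  fm_center <- stage("coil_field",
                     field_map_3d(cd$coil, cd$drive, rbind(tumor_center)))
  B_center <- fm_center$B_T
  H_center <- fm_center$H_A_per_m
  axis_profile <- stage("coil_field", helmholtz_axis_profile(
    cd$coil, cd$drive, x = seq(-0.05, 0.05, length.out = 101)))

  say("stage mnp_power: relaxation-loss source")
  particles <- stage("mnp_power", config_particles(config, H_center))
  power <- stage("mnp_power", relaxation_loss_power(
    particles, H_center, config$drive$frequency_Hz))
  q_src <- heat_source_density(power, config$source$alpha)

  tumor_mask <- region_mask(phantom, "mixed tissue")
  src <- array(0, dim(phantom$labels))
  if (isTRUE(config$source$per_voxel_field)) {
    say("stage mnp_power: per-voxel field evaluation over the tumor")
    idx <- which(tumor_mask, arr.ind = TRUE)
    pts <- cbind(phantom$x[idx[, 1]], phantom$y[idx[, 2]],
                 phantom$z[idx[, 3]])
    Hv <- field_map_3d(cd$coil, cd$drive, pts)$H_A_per_m
    Pv <- vapply(Hv, function(h) relaxation_loss_power(
      particles, h, config$drive$frequency_Hz)$P0, numeric(1))
    src[tumor_mask] <- config$source$alpha * Pv
  } else {
    src[tumor_mask] <- q_src
  }

  say("stage bioheat: Pennes solve (", config$thermal$duration_s, " s at ",
      phantom$voxel_size * 1e3, " mm)")
  th <- config$thermal
  params <- bioheat_params(
    duration = th$duration_s, dt = th$dt_s, scheme = th$scheme,
    blood_rho = th$blood_rho, blood_c = th$blood_c, blood_T = th$blood_T_C,
    T_init = th$T_init_C,
    bc_air = list(type = th$bc_air$type, h = th$bc_air$h,
                  T_ambient = th$bc_air$T_ambient_C),
    bc_far = list(type = th$bc_far$type, T = th$bc_far$T_C),
    output_every = th$output_every_s)
  probes <- default_probes(phantom)
  bh <- stage("bioheat", simulate_bioheat(
    phantom, params, src, probes,
    snapshot_times = config$report$snapshot_times_s))

  say("stage induced_field: quasi-static exposure estimates")
  exposure <- stage("induced_field", exposure_report(
    phantom, B_center, f = config$drive$frequency_Hz))

  say("stage report: dose statistics")
  Tf <- bh$state$temperature
  masks <- list(`mixed tissue` = tumor_mask,
                scalp = region_mask(phantom, "scalp"),
                skull = region_mask(phantom, "skull"),
                `brain tissue` = region_mask(phantom, "brain tissue"),
                muscle = region_mask(phantom, "muscle"))
  extrema <- region_extrema(bh$state, masks)
  dose <- list(
    B_center_T = B_center, H_center_A_per_m = H_center,
    P0_W_m3 = power$P0, source_W_m3 = q_src,
    chi_i = power$chi_i, chi_0 = power$chi_0, xi = power$xi,
    tau_eff_s = power$tau_eff,
    coil_separation_m = cd$coil$separation,
    tumor_fraction_above = fraction_above(
      bh$state, tumor_mask, config$report$tumor_threshold_C),
    brain_fraction_above = fraction_above(
      bh$state, masks$`brain tissue`, config$report$brain_threshold_C),
    tumor_threshold_C = config$report$tumor_threshold_C,
    brain_threshold_C = config$report$brain_threshold_C)

  res <- structure(
    list(config = config, phantom = phantom, coil = cd$coil,
         drive = cd$drive, particles = particles, power = power,
         axis_profile = axis_profile, state = bh$state,
         probes = bh$probes, snapshots = bh$snapshots,
         exposure = exposure, extrema = extrema, dose = dose),
    class = "mih_run")

  if (!is.null(config$outdir)) {
    say("writing artifacts to ", config$outdir)
    write_run_artifacts(res, config$outdir)
  }
  res
}

# standard probe set: tumor center/top, first scalp voxel straight below
# the tumor center, brain center
default_probes <- function(phantom) {
  v <- voxel_at(phantom, c(0, 0, 0))
  dzh <- phantom$geometry$tumor_thickness / 2 - phantom$voxel_size / 2
  scalp_id <- match("scalp", phantom$tissues)
  col <- phantom$labels[v[1], v[2], ]
  ks <- which(col == scalp_id & phantom$z < 0)
  if (!length(ks)) stop("no scalp voxel beneath the tumor center",
                        call. = FALSE)
  list(
    tumor_center = c(phantom$x[v[1]], phantom$y[v[2]], phantom$z[v[3]]),
    tumor_top = c(phantom$x[v[1]], phantom$y[v[2]], dzh),
    scalp_below = c(phantom$x[v[1]], phantom$y[v[2]], phantom$z[max(ks)]),
    brain_center = c(0, 0, phantom$head_center[3]))
}

#' Fraction of a region at or above a temperature threshold
#'
#' @param state a `thermal_state`.
#' @param mask logical region mask on the state's grid (non-empty).
#' @param threshold temperature threshold, degC.
#' @return Volume fraction in `[0, 1]` of region voxels with
#'   `T >= threshold`.
#' @export
fraction_above <- function(state, mask, threshold) {
  if (!any(mask)) stop("empty region", call. = FALSE)
  Tv <- state$temperature[mask]
  if (anyNA(Tv)) stop("region mask covers air voxels", call. = FALSE)
  mean(Tv >= threshold)
}

#' Per-region temperature extrema and means
#'
#' @param state a `thermal_state`.
#' @param masks named list of logical region masks.
#' @return A `data.frame` with `region`, `min_C`, `mean_C`, `max_C` at the
#'   state's time.
#' @export
region_extrema <- function(state, masks) {
  out <- lapply(names(masks), function(nm) {
    Tv <- state$temperature[masks[[nm]]]
    Tv <- Tv[!is.na(Tv)]
    if (!length(Tv)) {
      return(data.frame(region = nm, min_C = NA_real_, mean_C = NA_real_,
                        max_C = NA_real_))
    }
    data.frame(region = nm, min_C = min(Tv), mean_C = mean(Tv),
               max_C = max(Tv))
  })
  out <- do.call(rbind, out)
  out$time_s <- state$time
  out
}

#' Heating-curve summary of a probe time series
#'
#' Reports, for one monotone-in-time probe series, the first crossing time
#' of each threshold (linear interpolation between samples; `NA` if never
#' crossed), the final value, and a plateau estimate by Aitken
#' delta-squared extrapolation of the last three samples (exact for an
#' exponential approach, the form the perfused-tissue kinetics take).
#'
#' @param time sample times, s (increasing).
#' @param temperature probe temperatures, degC.
#' @param thresholds thresholds to report crossing times for, degC.
#' @return A list with `final_C`, `plateau_C` and `crossing_s` (named
#'   vector, `NA` where not crossed).
#' @export
#' @examples
#' t <- seq(0, 300, by = 5)
#' y <- perfused_block_temperature(t, Q = 370656, Qm = 5790,
#'                                 rho_c = 1072.4 * 3651.1,
#'                                 omega_b = 0.01392)
#' heating_curve(t, y, thresholds = 42)
heating_curve <- function(time, temperature, thresholds = 42) {
  stopifnot(length(time) == length(temperature), !is.unsorted(time))
  cross <- vapply(thresholds, function(th) {
    i <- which(temperature >= th)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(time[1])
    t0 <- time[i - 1]; t1 <- time[i]
    y0 <- temperature[i - 1]; y1 <- temperature[i]
    t0 + (th - y0) / (y1 - y0) * (t1 - t0)
  }, numeric(1))
  names(cross) <- paste0("T", thresholds)
  n <- length(temperature)
  plateau <- if (n >= 3) {
    y1 <- temperature[n - 2]; y2 <- temperature[n - 1]; y3 <- temperature[n]
    den <- y1 + y3 - 2 * y2
    if (abs(den) < 1e-12) y3 else (y1 * y3 - y2^2) / den
  } else {
    temperature[n]
  }
  list(final_C = temperature[n], plateau_C = plateau, crossing_s = cross)
}

#' @export
print.mih_run <- function(x, ...) {
  d <- x$dose
  cat("Magnetic induction hyperthermia run\n")
  cat(sprintf("  B center      : %.4f mT  (H = %.1f A/m)\n",
              d$B_center_T * 1e3, d$H_center_A_per_m))
  cat(sprintf("  loss power P0 : %.0f W/m^3  (source alpha*P0 = %.0f W/m^3)\n",
              d$P0_W_m3, d$source_W_m3))
  pc <- x$probes[x$probes$probe == "tumor_center", ]
  cat(sprintf("  tumor center  : %.2f degC at %g s\n",
              pc$T_C[nrow(pc)], pc$time_s[nrow(pc)]))
  tum <- x$extrema[x$extrema$region == "mixed tissue", ]
  cat(sprintf("  tumor region  : min %.2f / mean %.2f / max %.2f degC; %.1f%% >= %g degC\n",
              tum$min_C, tum$mean_C, tum$max_C,
              100 * d$tumor_fraction_above, d$tumor_threshold_C))
  br <- x$extrema[x$extrema$region == "brain tissue", ]
  cat(sprintf("  brain region  : max %.2f degC; %.1f%% >= %g degC\n",
              br$max_C, 100 * d$brain_fraction_above, d$brain_threshold_C))
  invisible(x)
}

#' @export
summary.mih_run <- function(object, ...) {
  print(object)
  cat("\nPer-region temperatures at t =", object$state$time, "s:\n")
  print(object$extrema, row.names = FALSE, digits = 4)
  cat("\n")
  print(object$exposure)
  invisible(object)
}

#' Plot probe heating curves of a run
#'
#' @param x a `mih_run`.
#' @param thresholds horizontal reference temperatures, degC.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mih_run <- function(x, thresholds = c(42, 46), ...) {
  pr <- x$probes
  probes <- unique(pr$probe)
  tt <- sort(unique(pr$time_s))
  Y <- sapply(probes, function(p) pr$T_C[pr$probe == p][order(
    pr$time_s[pr$probe == p])])
  graphics::matplot(tt, Y, type = "l", lty = 1, lwd = 2,
                    xlab = "time (s)", ylab = "temperature (degC)",
                    main = "Probe heating curves", ...)
  graphics::abline(h = thresholds, lty = 3, col = "grey40")
  graphics::legend("bottomright", legend = probes, lty = 1, lwd = 2,
                   col = seq_along(probes), bty = "n")
  invisible(x)
}

#' Flat dose-report list of a run
#'
#' The JSON-serializable dose report: field summary, source chain, probe
#' endpoints, per-region statistics and coverage fractions.
#'
#' @param x a `mih_run`.
#' @return A nested list (no S4/array members).
#' @export
dose_report <- function(x) {
  stopifnot(inherits(x, "mih_run"))
  pc <- function(p) {
    s <- x$probes[x$probes$probe == p, ]
    stats::setNames(s$T_C, paste0("t", s$time_s, "s"))
  }
  ext <- split(x$extrema[, c("min_C", "mean_C", "max_C")],
               x$extrema$region)
  list(
    field = list(B_center_mT = x$dose$B_center_T * 1e3,
                 H_center_A_per_m = x$dose$H_center_A_per_m,
                 coil_separation_m = x$dose$coil_separation_m),
    power = list(P0_W_m3 = x$dose$P0_W_m3,
                 source_W_m3 = x$dose$source_W_m3,
                 xi = x$dose$xi, chi_i = x$dose$chi_i,
                 chi_0 = x$dose$chi_0, tau_eff_s = x$dose$tau_eff_s),
    coverage = list(
      tumor_fraction_above = x$dose$tumor_fraction_above,
      tumor_threshold_C = x$dose$tumor_threshold_C,
      brain_fraction_above = x$dose$brain_fraction_above,
      brain_threshold_C = x$dose$brain_threshold_C),
    regions = lapply(ext, function(d) as.list(d[1, ])),
    probes_final = lapply(unique(x$probes$probe), function(p) {
      s <- pc(p); s[[length(s)]]
    }) |> stats::setNames(unique(x$probes$probe)),
    time_s = x$state$time)
}
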