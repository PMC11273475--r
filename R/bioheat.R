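#' Bioheat solver parameters
#'
#' Parameters of the Pennes bioheat solve
#' \deqn{\rho c \frac{\partial T}{\partial t} = \nabla\!\cdot\!(k \nabla T)
#'   + \rho_b C_b \omega_b (T_b - T) + Q_m + \alpha P_0,}
#' with per-voxel tissue properties from the registry, the blood perfusion
#' term acting as a distributed sink toward the arterial temperature `T_b`,
#' and the nanoparticle source applied over the tumor. Air voxels are
#' excluded from the solve. The tissue-air surface is insulated by default
#' (`bc_air$type = "convective"` enables a Robin condition with film
#' coefficient `h` and ambient temperature `T_ambient`); tissue faces lying
#' on the grid boundary (the far end of the body stub) are held at the body
#' temperature `bc_far$T`.
#'
#' @param duration total heating time, s.
#' @param dt time step, s.
#' @param scheme `"implicit"` (backward Euler, default) or `"explicit"`
#'   (forward Euler, subject to the stability bound).
#' @param blood_rho,blood_c blood density (kg/m^3) and specific heat
#'   (J/(kg K)).
#' @param blood_T arterial blood temperature, degC.
#' @param T_init uniform initial temperature, degC.
#' @param bc_air list: `type` `"insulated"` or `"convective"`, with `h`
#'   (W/(m^2 K)) and `T_ambient` (degC) for the convective case.
#' @param bc_far list: `type` `"fixed"` (with `T`, degC) or `"insulated"`.
#' @param output_every probe recording interval, s.
#' @return A list of class `bioheat_params`.
#' @export
bioheat_params <- function(duration = 300, dt = 1,
                           scheme = c("implicit", "explicit"),
                           blood_rho = 1060, blood_c = 3650, blood_T = 37,
                           T_init = 37,
                           bc_air = list(type = "insulated", h = 10,
                                         T_ambient = 25),
                           bc_far = list(type = "fixed", T = 37),
                           output_every = 5) {
  scheme <- match.arg(scheme)
  stopifnot(duration >= 0, dt > 0, blood_rho > 0, blood_c > 0,
            output_every > 0)
  structure(
    list(duration = duration, dt = dt, scheme = scheme,
         blood_rho = blood_rho, blood_c = blood_c, blood_T = blood_T,
         T_init = T_init, bc_air = bc_air, bc_far = bc_far,
         output_every = output_every),
    class = "bioheat_params")
}

#' Assemble the discrete bioheat operator
#'
#' Builds the finite-volume operator on the phantom's active (non-air)
#' voxels: per-voxel heat capacity `rho c V`, the conduction stiffness with
#' harmonic-mean face conductivities across tissue interfaces, the
#' perfusion sink coefficient `rho_b C_b omega_b V`, and the constant load
#' `(Q_m + source) V` plus boundary contributions.
#'
#' @param phantom a [build_head_phantom()] phantom.
#' @param params a [bioheat_params()].
#' @param source volumetric source array (W/m^3) on the full grid (zero
#'   outside the tumor), or `NULL` for no source.
#' @param registry a [tissue_table()] registry.
#' @return A list of class `bioheat_operator` holding the sparse stiffness
#'   `K`, capacity `M`, perfusion and boundary diagonals, constant
#'   right-hand side `b0`, and index bookkeeping.
#' @export
assemble_bioheat <- function(phantom, params, source = NULL,
                             registry = tissue_table()) {
  lab <- phantom$labels
  dims <- dim(lab)
  h <- phantom$voxel_size
  act <- lab != 1L                       # label 1 is air
  n <- sum(act)
  if (n == 0) stop("phantom has no tissue voxels", call. = FALSE)
  idx <- array(0L, dims)
  idx[act] <- seq_len(n)

  if (is.null(source)) source <- array(0, dims)
  if (any(source < 0)) stop("source must be nonnegative", call. = FALSE)
  if (any(source[!act] != 0)) {
    stop("source must be zero on air voxels", call. = FALSE)
  }

  # per-label property vectors (NA for air and for any unlabeled tissue)
  prop <- function(col) {
    v <- rep(NA_real_, length(phantom$tissues))
    m <- match(phantom$tissues, registry$tissue)
    v[!is.na(m)] <- registry[[col]][m[!is.na(m)]]
    v
  }
  labv <- lab[act]
  k_v <- prop("k_W_mK")[labv]
  rc_v <- (prop("rho_kg_m3") * prop("c_J_kgK"))[labv]
  om_v <- prop("omega_b_per_s")[labv]
  qm_v <- prop("Qm_W_m3")[labv]
  if (anyNA(k_v) || anyNA(rc_v)) {
    bad <- unique(phantom$tissues[labv[is.na(k_v) | is.na(rc_v)]])
    stop("no thermal properties for label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  om_v[is.na(om_v)] <- 0
  qm_v[is.na(qm_v)] <- 0

  V <- h^3
  karr <- array(0, dims)
  karr[act] <- k_v

  # interior faces between active voxels, per axis: harmonic-mean
  # conductance g = 2 k1 k2 / (k1 + k2) * h  (area h^2 / distance h)
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  slice <- function(d, drop_last) {
    ix <- lapply(dims, seq_len)
    ix[[d]] <- if (drop_last) seq_len(dims[d] - 1L) else
      seq_len(dims[d] - 1L) + 1L
    c(ix, list(drop = FALSE))
  }
  for (d in 1:3) {
    a1 <- do.call(`[`, c(list(idx), slice(d, TRUE)))
    a2 <- do.call(`[`, c(list(idx), slice(d, FALSE)))
    k1 <- do.call(`[`, c(list(karr), slice(d, TRUE)))
    k2 <- do.call(`[`, c(list(karr), slice(d, FALSE)))
    keep <- a1 > 0L & a2 > 0L
    g <- 2 * k1[keep] * k2[keep] / (k1[keep] + k2[keep]) * h
    ii <- c(ii, a1[keep]); jj <- c(jj, a2[keep]); gg <- c(gg, g)
  }
  K <- Matrix::sparseMatrix(i = c(ii, jj, ii, jj), j = c(jj, ii, ii, jj),
                            x = c(-gg, -gg, gg, gg), dims = c(n, n))

  # exposed faces: adjacent to air (air BC) or on the grid boundary (far BC)
  air_faces <- numeric(n)
  far_faces <- numeric(n)
  for (d in 1:3) {
    a1 <- do.call(`[`, c(list(idx), slice(d, TRUE)))
    a2 <- do.call(`[`, c(list(idx), slice(d, FALSE)))
    w <- a1 > 0L & a2 == 0L
    air_faces[a1[w]] <- air_faces[a1[w]] + 1
    w <- a2 > 0L & a1 == 0L
    air_faces[a2[w]] <- air_faces[a2[w]] + 1
    # grid-boundary faces of active voxels
    lo <- lapply(dims, seq_len); lo[[d]] <- 1L
    hi <- lapply(dims, seq_len); hi[[d]] <- dims[d]
    b1 <- do.call(`[`, c(list(idx), lo))
    b2 <- do.call(`[`, c(list(idx), hi))
    far_faces[b1[b1 > 0L]] <- far_faces[b1[b1 > 0L]] + 1
    far_faces[b2[b2 > 0L]] <- far_faces[b2[b2 > 0L]] + 1
  }

  diag_bc <- numeric(n)
  b_bc <- numeric(n)
  if (identical(params$bc_air$type, "convective")) {
    g_air <- params$bc_air$h * h^2 * air_faces
    diag_bc <- diag_bc + g_air
    b_bc <- b_bc + g_air * params$bc_air$T_ambient
  }
  if (identical(params$bc_far$type, "fixed")) {
    g_far <- 2 * k_v * h * far_faces     # half-cell conductance k A/(h/2)
    diag_bc <- diag_bc + g_far
    b_bc <- b_bc + g_far * params$bc_far$T
  }

  Mcap <- rc_v * V
  P <- params$blood_rho * params$blood_c * om_v * V
  load <- (qm_v + source[act]) * V
  b0 <- load + P * params$blood_T + b_bc

  structure(
    list(K = K, M = Mcap, P = P, diag_bc = diag_bc, b0 = b0,
         n = n, idx = idx, active = act, dims = dims, voxel_size = h,
         k = k_v, rho_c = rc_v, labels_active = labv,
         tissues = phantom$tissues, params = params),
    class = "bioheat_operator")
}

#' Maximum stable explicit time step
#'
#' The forward-Euler conduction stability bound
#' \eqn{\Delta t \le \min_v \rho c \,\Delta x^2 / (6 k)} over the active
#' voxels.
#'
#' @param op a [assemble_bioheat()] operator (or a `voxel_phantom`, in
#'   which case `registry` is used to assemble one with default
#'   parameters).
#' @param registry a [tissue_table()] registry.
#' @return The limiting time step in seconds, with the limiting tissue as
#'   attribute `"tissue"`.
#' @export
stability_limit <- function(op, registry = tissue_table()) {
  if (inherits(op, "voxel_phantom")) {
    op <- assemble_bioheat(op, bioheat_params(), registry = registry)
  }
  dt_v <- op$rho_c * op$voxel_size^2 / (6 * op$k)
  i <- which.min(dt_v)
  structure(dt_v[i], tissue = op$tissues[op$labels_active[i]])
}

# one time step on the active-voxel temperature vector
bioheat_step_vec <- function(Tv, op, dt, scheme, factor = NULL) {
  if (scheme == "explicit") {
    lim <- op$rho_c * op$voxel_size^2 / (6 * op$k)
    if (dt > min(lim) * (1 + 1e-12)) {
      i <- which.min(lim)
      stop(sprintf(
        "explicit step dt = %g s violates the stability bound %.4g s (limiting tissue: %s)",
        dt, min(lim), op$tissues[op$labels_active[i]]), call. = FALSE)
    }
    rhs <- op$b0 - as.numeric(op$K %*% Tv) -
      (op$P + op$diag_bc) * Tv
    Tv + dt / op$M * rhs
  } else {
    if (is.null(factor)) factor <- bioheat_factor(op, dt)
    rhs <- op$M / dt * Tv + op$b0
    as.numeric(Matrix::solve(factor, rhs))
  }
}

# Cholesky factor of (M/dt + K + P + bc) for the implicit scheme
bioheat_factor <- function(op, dt) {
  A <- op$K + Matrix::Diagonal(op$n, op$M / dt + op$P + op$diag_bc)
  Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
}

#' Advance a thermal state by one time step
#'
#' Single step of the bioheat integration, mainly for scheme testing; use
#' [simulate_bioheat()] for full runs (it factorizes the implicit operator
#' once).
#'
#' @param state a `thermal_state` (from [thermal_state()] or a previous
#'   step).
#' @param op a [assemble_bioheat()] operator.
#' @param dt time step, s.
#' @param scheme `"implicit"` or `"explicit"` (default from the operator's
#'   parameters).
#' @return The advanced `thermal_state`.
#' @export
bioheat_step <- function(state, op, dt = op$params$dt,
                         scheme = op$params$scheme) {
  Tv <- state$temperature[op$active]
  Tv <- bioheat_step_vec(Tv, op, dt, scheme)
  Tarr <- state$temperature
  Tarr[op$active] <- Tv
  thermal_state(Tarr, state$time + dt)
}

#' Construct a thermal state
#'
#' @param temperature temperature array, degC (NA on air voxels).
#' @param time simulation time, s.
#' @return An object of class `thermal_state`.
#' @export
thermal_state <- function(temperature, time = 0) {
  structure(list(temperature = temperature, time = time),
            class = "thermal_state")
}

#' @export
print.thermal_state <- function(x, ...) {
  Tv <- x$temperature[!is.na(x$temperature)]
  cat("Thermal state at t = ", x$time, " s: T in [",
      signif(min(Tv), 5), ", ", signif(max(Tv), 5), "] degC over ",
      length(Tv), " tissue voxels\n", sep = "")
  invisible(x)
}

#' Run the bioheat simulation
#'
#' Integrates the Pennes equation from the uniform initial temperature for
#' the configured duration, recording probe temperatures at every output
#' interval and full-grid snapshots at the requested times. The implicit
#' operator is factorized once (the coefficients are constant in time).
#'
#' @param phantom a [build_head_phantom()] phantom.
#' @param params a [bioheat_params()].
#' @param source volumetric source array (W/m^3; zero outside the tumor) or
#'   `NULL`.
#' @param probes named list of probe locations, each a physical point (m,
#'   length-3); probes must fall on tissue voxels.
#' @param snapshot_times times (s) at which to keep full temperature
#'   snapshots; they are rounded to the nearest step.
#' @param registry a [tissue_table()] registry.
#' @return A list of class `bioheat_run`: final `state` (`thermal_state`),
#'   `probes` (`data.frame` time_s, probe, T_C), `snapshots` (named list of
#'   `thermal_state`), and the `operator`.
#' @export
simulate_bioheat <- function(phantom, params = bioheat_params(),
                             source = NULL, probes = list(),
                             snapshot_times = numeric(0),
                             registry = tissue_table()) {
  op <- assemble_bioheat(phantom, params, source, registry)
  dt <- params$dt
  nstep <- max(0L, as.integer(round(params$duration / dt)))
  rec_every <- max(1L, as.integer(round(params$output_every / dt)))
  snap_steps <- unique(pmin(nstep, pmax(0L, as.integer(round(
    snapshot_times / dt)))))

  pidx <- vapply(probes, function(p) {
    v <- voxel_at(phantom, p)
    a <- op$idx[v[1], v[2], v[3]]
    if (a == 0L) {
      stop("probe at (", paste(signif(p * 1e3, 4), collapse = ", "),
           ") mm falls on an air voxel", call. = FALSE)
    }
    a
  }, integer(1))

  Tv <- rep(params$T_init, op$n)
  factor <- if (params$scheme == "implicit" && nstep > 0) {
    bioheat_factor(op, dt)
  }

  rec_t <- numeric(0)
  rec_T <- matrix(numeric(0), nrow = 0, ncol = length(pidx))
  snaps <- list()
  record <- function(step, Tv) {
    t <- step * dt
    if (length(pidx) && (step %% rec_every == 0L || step == nstep)) {
      rec_t <<- c(rec_t, t)
      rec_T <<- rbind(rec_T, Tv[pidx])
    }
    if (step %in% snap_steps) {
      arr <- array(NA_real_, op$dims)
      arr[op$active] <- Tv
      snaps[[sprintf("t%gs", t)]] <<- thermal_state(arr, t)
    }
  }
  record(0L, Tv)
  if (nstep > 0) {
    for (s in seq_len(nstep)) {
      Tv <- bioheat_step_vec(Tv, op, dt, params$scheme, factor)
      record(s, Tv)
    }
  }

  arr <- array(NA_real_, op$dims)
  arr[op$active] <- Tv
  probe_df <- if (length(pidx)) {
    data.frame(time_s = rep(rec_t, times = length(pidx)),
               probe = rep(names(probes), each = length(rec_t)),
               T_C = as.vector(rec_T))
  } else {
    data.frame(time_s = numeric(0), probe = character(0),
               T_C = numeric(0))
  }
  structure(
    list(state = thermal_state(arr, nstep * dt), probes = probe_df,
         snapshots = snaps, operator = op),
    class = "bioheat_run")
}

#' @export
print.bioheat_run <- function(x, ...) {
  print(x$state)
  if (nrow(x$probes)) {
    last <- x$probes[x$probes$time_s == max(x$probes$time_s), ]
    cat("Final probe temperatures (degC):\n")
    print(last[, c("probe", "T_C")], row.names = FALSE, digits = 5)
  }
  invisible(x)
}

#' Closed-form perfused-block temperature
#'
#' Exact solution of the lumped (gradient-free) Pennes balance for a
#' uniformly heated, uniformly perfused block:
#' \deqn{T(t) = T_b + (T_{init} - T_b)\,e^{-t/\tau}
#'   + \Delta T_{ss}\,(1 - e^{-t/\tau}),}
#' with \eqn{\Delta T_{ss} = (Q + Q_m)/(\rho_b C_b \omega_b)} and
#' \eqn{\tau = \rho c / (\rho_b C_b \omega_b)}. This is the independent
#' oracle for the solver on homogeneous perfused problems and the
#' reference kinetics for the tumor center.
#'
#' @param t time(s), s.
#' @param Q applied source density, W/m^3.
#' @param Qm metabolic heat, W/m^3.
#' @param rho_c tissue volumetric heat capacity rho*c, J/(m^3 K).
#' @param omega_b perfusion rate, 1/s.
#' @param blood_rho,blood_c blood density and specific heat.
#' @param Tb blood temperature, degC.
#' @param T_init initial temperature, degC.
#' @return Temperature(s) at `t`, degC.
#' @export
#' @examples
#' # tumor-center reference with the tabulated mixed-tissue properties
#' perfused_block_temperature(300, Q = 370656, Qm = 5790,
#'                            rho_c = 1072.4 * 3651.1, omega_b = 0.01392)
perfused_block_temperature <- function(t, Q, Qm = 0,
                                       rho_c, omega_b,
                                       blood_rho = 1060, blood_c = 3650,
                                       Tb = 37, T_init = Tb) {
  w <- blood_rho * blood_c * omega_b
  dTss <- (Q + Qm) / w
  tau <- rho_c / w
  Tb + (T_init - Tb) * exp(-t / tau) + dTss * (1 - exp(-t / tau))
}
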