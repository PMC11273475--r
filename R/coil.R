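#' Helmholtz coil pair specification
#'
#' Describes a pair of identical coaxial multi-turn coils. Each coil's
#' winding is distributed over a radial band `[inner_radius, outer_radius]`
#' and an axial band of width `width`, as a uniform `layout["radial"] x
#' layout["axial"]` grid of circular loops; the product must equal `turns`.
#' `separation` is the distance between the two coils' center planes; the
#' classical Helmholtz condition sets it equal to the mean winding radius,
#' which is the default. The coil axis is x, with the origin midway between
#' the coils.
#'
#' @param turns loops per coil.
#' @param inner_radius,outer_radius radial extent of the winding band, m.
#' @param width axial extent of the winding band, m.
#' @param separation center-plane to center-plane distance, m; `NULL` for
#'   the Helmholtz condition (mean winding radius).
#' @param layout integer `c(radial =, axial =)` winding subdivision.
#' @param conductivity winding material conductivity, S/m (metadata only; no
#'   loss model).
#' @return An object of class `coil_spec`.
#' @export
#' @examples
#' coil_spec()  # the default 180-turn pair
coil_spec <- function(turns = 180,
                      inner_radius = 0.14, outer_radius = 0.15,
                      width = 0.05, separation = NULL,
                      layout = c(radial = 12, axial = 15),
                      conductivity = 5.998e7) {
  stopifnot(turns >= 1, inner_radius > 0, outer_radius > inner_radius,
            width > 0)
  if (prod(layout) != turns) {
    stop("winding layout (", layout[1], " x ", layout[2],
         ") must place exactly ", turns, " loops per coil", call. = FALSE)
  }
  if (is.null(separation)) {
    separation <- (inner_radius + outer_radius) / 2
  }
  stopifnot(separation > 0)
  structure(
    list(turns = turns, inner_radius = inner_radius,
         outer_radius = outer_radius, width = width,
         separation = separation, layout = layout,
         conductivity = conductivity),
    class = "coil_spec")
}

#' @export
print.coil_spec <- function(x, ...) {
  cat("Helmholtz coil pair: ", x$turns, " turns/coil, radii ",
      x$inner_radius, "-", x$outer_radius, " m, width ", x$width,
      " m, separation ", signif(x$separation, 5), " m (",
      x$layout[1], " x ", x$layout[2], " winding grid)\n", sep = "")
  invisible(x)
}

#' Sinusoidal drive current
#'
#' @param current peak current amplitude, A.
#' @param frequency drive frequency, Hz.
#' @return An object of class `drive_current`.
#' @export
drive_current <- function(current = 8, frequency = 1e5) {
  stopifnot(current > 0, frequency > 0)
  structure(list(current = current, frequency = frequency),
            class = "drive_current")
}

#' @export
print.drive_current <- function(x, ...) {
  cat("Drive: ", x$current, " A (peak) at ", x$frequency / 1e3, " kHz\n",
      sep = "")
  invisible(x)
}

# positions (axial offset) and radii of every winding loop of the pair
coil_loops <- function(coil) {
  nr <- coil$layout[[1]]
  na <- coil$layout[[2]]
  dr <- (coil$outer_radius - coil$inner_radius) / nr
  radii <- coil$inner_radius + (seq_len(nr) - 0.5) * dr
  du <- coil$width / na
  offs <- (seq_len(na) - 0.5) * du - coil$width / 2
  one <- expand.grid(R = radii, u = offs)
  rbind(data.frame(R = one$R, x0 = -coil$separation / 2 + one$u),
        data.frame(R = one$R, x0 = +coil$separation / 2 + one$u))
}

#' On-axis flux density of a single circular loop
#'
#' Axial flux density of one circular current loop at axial distance `x`
#' from the loop plane:
#' \deqn{B(x) = \frac{\mu_0 I R^2}{2 (R^2 + x^2)^{3/2}}.}
#'
#' @param loop_radius loop radius R, m.
#' @param I current, A (sign gives orientation).
#' @param x axial distance(s) from the loop plane, m.
#' @return Axial flux density in T, same length as `x`.
#' @export
#' @examples
#' loop_axial_field(0.145, 8, 0)  # mu0 * I / (2 R)
loop_axial_field <- function(loop_radius, I, x) {
  stopifnot(loop_radius > 0)
  mu0 * I * loop_radius^2 / (2 * (loop_radius^2 + x^2)^1.5)
}

#' Off-axis field of a single circular loop
#'
#' Magnetic flux density of a circular loop of radius `loop_radius` centered
#' on the x axis at `x0`, evaluated at arbitrary points, via the standard
#' complete-elliptic-integral solution (axial and radial components). On the
#' axis it reduces to [loop_axial_field()] with zero radial component.
#'
#' @param loop_radius loop radius, m.
#' @param I current, A.
#' @param points numeric matrix `n x 3` of (x, y, z) in m (a length-3 vector
#'   is accepted for a single point).
#' @param x0 axial position of the loop plane, m.
#' @param singular_tol distance from the wire, m, below which evaluation is
#'   refused.
#' @return `n x 3` matrix of B components in T.
#' @export
loop_field_offaxis <- function(loop_radius, I, points, x0 = 0,
                               singular_tol = 1e-6) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  a <- loop_radius
  xr <- points[, 1] - x0
  rho <- sqrt(points[, 2]^2 + points[, 3]^2)
  dw <- sqrt((rho - a)^2 + xr^2)        # distance to the wire circle
  if (any(dw < singular_tol)) {
    stop("evaluation point within ", singular_tol,
         " m of the wire: field is singular", call. = FALSE)
  }
  den <- (a + rho)^2 + xr^2
  m <- 4 * a * rho / den
  ke <- pracma::ellipke(pmin(m, 1 - 1e-15))
  K <- ke$k
  E <- ke$e
  pref <- mu0 * I / (2 * pi * sqrt(den))
  d2 <- (a - rho)^2 + xr^2
  Bx <- pref * (K + (a^2 - rho^2 - xr^2) / d2 * E)
  Brho <- ifelse(rho > 0,
                 pref * xr / rho * (-K + (a^2 + rho^2 + xr^2) / d2 * E),
                 0)
  cy <- ifelse(rho > 0, points[, 2] / rho, 0)
  cz <- ifelse(rho > 0, points[, 3] / rho, 0)
  cbind(Bx = Bx, By = Brho * cy, Bz = Brho * cz)
}

#' Axial field profile of the Helmholtz pair
#'
#' Superposes the on-axis fields of every winding loop of both coils at the
#' requested axis positions. Reported magnitudes are peak (amplitude)
#' values of the sinusoidal drive; pass `rms = TRUE` for RMS reporting.
#'
#' @param coil a [coil_spec()].
#' @param drive a [drive_current()].
#' @param x axis sample positions, m (default a dense profile across the
#'   pair).
#' @param rms report RMS instead of peak amplitudes.
#' @return A `data.frame` of class `field_map` with columns `x`, `B_T`
#'   (axial flux density) and `H_A_per_m` (`B / mu0`).
#' @export
#' @examples
#' prof <- helmholtz_axis_profile(coil_spec(), drive_current(),
#'                                x = seq(-0.05, 0.05, by = 0.01))
#' prof[prof$x == 0, ]
helmholtz_axis_profile <- function(coil, drive,
                                   x = seq(-0.2, 0.2, length.out = 201),
                                   rms = FALSE) {
  loops <- coil_loops(coil)
  B <- vapply(x, function(xi) {
    sum(loop_axial_field(loops$R, drive$current, xi - loops$x0))
  }, numeric(1))
  if (rms) B <- B / sqrt(2)
  structure(data.frame(x = x, B_T = B, H_A_per_m = B / mu0),
            class = c("field_map", "data.frame"))
}

#' Center flux density of the pair
#'
#' @inheritParams helmholtz_axis_profile
#' @return Peak flux density at the geometric center, T.
#' @export
helmholtz_center_field <- function(coil, drive) {
  helmholtz_axis_profile(coil, drive, x = 0)$B_T
}

#' Flux density map on arbitrary 3-D points
#'
#' Superposes the off-axis elliptic-integral loop fields of all winding
#' loops at arbitrary points. Biological tissue has relative permeability 1
#' and does not perturb B, so the same map applies with or without the
#' phantom present; `H = B / mu0` everywhere.
#'
#' @inheritParams helmholtz_axis_profile
#' @param points `n x 3` matrix of (x, y, z) positions, m.
#' @return A `data.frame` of class `field_map` with the point coordinates,
#'   components `Bx_T`, `By_T`, `Bz_T`, magnitude `B_T` and `H_A_per_m`.
#' @export
field_map_3d <- function(coil, drive, points, rms = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  loops <- coil_loops(coil)
  Bacc <- matrix(0, nrow(points), 3)
  for (i in seq_len(nrow(loops))) {
    Bacc <- Bacc + loop_field_offaxis(loops$R[i], drive$current, points,
                                      x0 = loops$x0[i])
  }
  if (rms) Bacc <- Bacc / sqrt(2)
  Bmag <- sqrt(rowSums(Bacc^2))
  structure(
    data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
               Bx_T = Bacc[, 1], By_T = Bacc[, 2], Bz_T = Bacc[, 3],
               B_T = Bmag, H_A_per_m = Bmag / mu0),
    class = c("field_map", "data.frame"))
}

#' Field uniformity over a region of a map
#'
#' @param map a `field_map` (from [helmholtz_axis_profile()] or
#'   [field_map_3d()]).
#' @param region logical vector selecting the rows of `map` to summarise
#'   (default all rows).
#' @return A list with `min`, `max`, `center` (value nearest the origin)
#'   and relative `ripple` `(max - min) / center` of the flux-density
#'   magnitude.
#' @export
uniformity_report <- function(map, region = rep(TRUE, nrow(map))) {
  if (length(region) != nrow(map)) {
    stop("region selector longer than the map", call. = FALSE)
  }
  if (!any(region)) stop("empty region", call. = FALSE)
  B <- map$B_T[region]
  if (!is.null(map$x)) {
    d <- map$x[region]^2
    if (!is.null(map$y)) d <- d + map$y[region]^2 + map$z[region]^2
    center <- B[which.min(d)]
  } else {
    center <- B[1]
  }
  list(min = min(B), max = max(B), center = center,
       ripple = (max(B) - min(B)) / center)
}

#' Calibrate the coil separation to a target center field
#'
#' The coil tables fix the winding envelope but not the center-plane
#' separation. This helper solves for the separation at which the
#' distributed-winding center flux density equals a requested value (e.g.
#' a measured or reported field), searching within reasonable bounds.
#'
#' @param coil a [coil_spec()]; its separation is replaced.
#' @param drive a [drive_current()].
#' @param target_B requested peak center flux density, T.
#' @param interval search interval for the separation, m.
#' @return The input `coil_spec` with calibrated `separation`.
#' @export
#' @examples
#' cal <- calibrate_separation(coil_spec(), drive_current(), 8.5621e-3)
#' helmholtz_center_field(cal, drive_current()) * 1e3  # mT
calibrate_separation <- function(coil, drive, target_B,
                                 interval = c(0.05, 0.5)) {
  f <- function(s) {
    coil$separation <- s
    helmholtz_center_field(coil, drive) - target_B
  }
  if (f(interval[1]) < 0 || f(interval[2]) > 0) {
    stop("target center field not bracketed by the separation interval",
         call. = FALSE)
  }
  s <- stats::uniroot(f, interval, tol = 1e-10)$root
  coil$separation <- s
  coil
}
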