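#' Induced electric field on a circular path (quasi-static)
#'
#' At 100 kHz displacement currents are negligible and the induced electric
#' field follows Faraday's law applied to a circular path of radius `r`
#' coaxial with the coil in a uniform axial flux density of amplitude `B`:
#' `E * 2 pi r = 2 pi f * B * pi r^2`, i.e.
#' \deqn{E = \pi f B r.}
#' This is the closed-form interior solution for a homogeneous conducting
#' cylinder in a uniform axial AC field in the negligible-skin-depth limit;
#' it is an order-of-magnitude exposure bound, not a solution of the
#' heterogeneous-anatomy eddy-current problem.
#'
#' @param f frequency, Hz.
#' @param B axial flux density amplitude, T.
#' @param r path radius, m.
#' @return E amplitude, V/m.
#' @export
#' @examples
#' induced_e_circular_path(1e5, 8.5629e-3, 11.99e-3)  # ~32 V/m
induced_e_circular_path <- function(f, B, r) {
  if (any(f < 0) || any(B < 0) || any(r < 0)) {
    stop("f, B and r must be nonnegative", call. = FALSE)
  }
  pi * f * B * r
}

#' Conduction current density in tissue
#'
#' Ohmic current density `J = sigma * E` with the tissue's tabulated
#' conductivity.
#'
#' @param E electric field amplitude, V/m.
#' @param tissue tissue name, looked up in `registry`, or a one-row
#'   registry entry.
#' @param registry a [tissue_table()] registry.
#' @return J in A/m^2.
#' @export
current_density <- function(E, tissue, registry = tissue_table()) {
  stopifnot(all(E >= 0))
  row <- if (is.data.frame(tissue)) tissue else tissue_lookup(registry, tissue)
  row$sigma_S_per_m * E
}

#' Per-tissue quasi-static exposure estimates
#'
#' For every tissue region of the phantom, estimates the induced electric
#' field amplitude on the region's widest circular path about the coil axis
#' (its maximal in-plane radius) under the uniform center flux density, and
#' the resulting conduction current density. These are quasi-static
#' analytic bounds intended for safety screening; they do not resolve the
#' field redistribution of heterogeneous anatomy (see the methods
#' vignette).
#'
#' @param phantom a [build_head_phantom()] phantom.
#' @param B center flux density amplitude, T (or a `field_map` whose value
#'   nearest the origin is used).
#' @param f frequency, Hz.
#' @param registry a [tissue_table()] registry.
#' @param tissues tissue labels to report (default every non-air label
#'   present in the phantom).
#' @return A `data.frame` (class `exposure_report`) with columns `tissue`,
#'   `r_eff_m`, `E_V_per_m`, `J_A_per_m2`.
#' @export
exposure_report <- function(phantom, B, f = 1e5, registry = tissue_table(),
                            tissues = NULL) {
  if (inherits(B, "field_map")) {
    B <- uniformity_report(B)$center
  }
  present <- phantom$tissues[sort(unique(as.integer(phantom$labels)))]
  present <- setdiff(present, "air")
  if (is.null(tissues)) tissues <- present
  # dielectric lookup name for the mixed tumor label
  sigma_name <- function(tt) if (tt == "mixed tissue") "mixed tissue" else tt
  rho2 <- outer(phantom$y^2, phantom$z^2, `+`)   # in-plane radius^2 (y-z)
  out <- lapply(tissues, function(tt) {
    mask <- region_mask(phantom, tt)
    if (!any(mask)) {
      return(data.frame(tissue = tt, r_eff_m = NA_real_,
                        E_V_per_m = NA_real_, J_A_per_m2 = NA_real_))
    }
    any_yz <- apply(mask, c(2, 3), any)
    r_eff <- sqrt(max(rho2[any_yz]))
    E <- induced_e_circular_path(f, B, r_eff)
    J <- current_density(E, sigma_name(tt), registry)
    data.frame(tissue = tt, r_eff_m = r_eff, E_V_per_m = E, J_A_per_m2 = J)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("exposure_report", "data.frame")
  out
}

#' @export
print.exposure_report <- function(x, ...) {
  cat("Quasi-static exposure estimates (analytic bounds,",
      "not an eddy-current field solution):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
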