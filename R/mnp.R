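#' Langevin function
#'
#' \eqn{L(\xi) = \coth\xi - 1/\xi}, the equilibrium magnetization curve of a
#' classical paramagnet. Below a small-argument crossover the series
#' \eqn{\xi/3 - \xi^3/45} is used to avoid cancellation at the removable
#' singularity.
#'
#' @param xi Langevin parameter(s), dimensionless, `>= 0`.
#' @return `L(xi)`, in `[0, 1)`.
#' @export
#' @examples
#' langevin(1)  # coth(1) - 1 = 0.3130353
langevin <- function(xi) {
  if (any(xi < 0)) stop("Langevin parameter must be >= 0", call. = FALSE)
  out <- numeric(length(xi))
  small <- xi < 1e-4
  out[small] <- xi[small] / 3 - xi[small]^3 / 45
  xl <- xi[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Magnetic nanoparticle specification
#'
#' Physical description of the single-domain particle population suspended
#' in the tumor: domain magnetization `Md` (A/m), single-particle volume
#' (via `diameter` of an equivalent sphere or `volume` directly, m^3),
#' suspension volume fraction `phi`, absolute temperature (K) and the
#' effective relaxation time `tau_eff` (s). `tau_eff` may be given directly,
#' derived from Neel and Brownian times via
#' [effective_relaxation_time()], or left `NULL` to be calibrated later
#' ([calibrate_relaxation_time()]).
#'
#' @param Md domain magnetization, A/m (default magnetite, 446 kA/m).
#' @param diameter particle diameter, m (default 19 nm).
#' @param volume particle volume, m^3; overrides `diameter`.
#' @param phi volume fraction in `[0, 1]` (default 0.003).
#' @param temperature absolute temperature, K (default body temperature).
#' @param tau_eff effective relaxation time, s, or `NULL`.
#' @param tau_N,tau_B Neel and Brownian relaxation times, s; used when
#'   `tau_eff` is `NULL` and both are given.
#' @return An object of class `nanoparticle_spec`.
#' @export
nanoparticle_spec <- function(Md = 446e3, diameter = 19e-9, volume = NULL,
                              phi = 0.003, temperature = 310.15,
                              tau_eff = NULL, tau_N = NULL, tau_B = NULL) {
  if (is.null(volume)) {
    stopifnot(diameter > 0)
    volume <- pi * diameter^3 / 6
  }
  stopifnot(Md > 0, volume > 0, phi >= 0, phi <= 1, temperature > 0)
  if (is.null(tau_eff) && !is.null(tau_N) && !is.null(tau_B)) {
    tau_eff <- effective_relaxation_time(tau_N, tau_B)
  }
  if (!is.null(tau_eff)) stopifnot(tau_eff > 0)
  structure(
    list(Md = Md, volume = volume, phi = phi, temperature = temperature,
         tau_eff = tau_eff),
    class = "nanoparticle_spec")
}

#' @export
print.nanoparticle_spec <- function(x, ...) {
  d_nm <- (6 * x$volume / pi)^(1 / 3) * 1e9
  cat("Nanoparticle spec: Md = ", x$Md / 1e3, " kA/m, d = ",
      signif(d_nm, 4), " nm, phi = ", x$phi, ", T = ", x$temperature,
      " K, tau_eff = ",
      if (is.null(x$tau_eff)) "(uncalibrated)" else
        paste0(signif(x$tau_eff, 5), " s"),
      "\n", sep = "")
  invisible(x)
}

#' Langevin parameter of a spec in a given field
#'
#' \eqn{\xi = \mu_0 M_d H_0 V / (k_B T)}, the ratio of magnetic to thermal
#' energy of one particle.
#'
#' @param spec a [nanoparticle_spec()].
#' @param H0 applied field strength amplitude, A/m.
#' @return Dimensionless `xi`.
#' @export
langevin_parameter <- function(spec, H0) {
  mu0 * spec$Md * H0 * spec$volume / (k_B * spec$temperature)
}

#' Initial (zero-field) susceptibility
#'
#' \eqn{\chi_i = \mu_0 \varphi M_d^2 V / (3 k_B T)}.
#'
#' @inheritParams langevin_parameter
#' @return Dimensionless `chi_i`.
#' @export
initial_susceptibility <- function(spec) {
  mu0 * spec$phi * spec$Md^2 * spec$volume / (3 * k_B * spec$temperature)
}

#' Equilibrium susceptibility in a finite field
#'
#' \eqn{\chi_0 = \chi_i \, (3/\xi) L(\xi)}; at zero field
#' \eqn{\chi_0 = \chi_i} and it decreases monotonically with the field
#' amplitude (Langevin saturation).
#'
#' @inheritParams langevin_parameter
#' @return Dimensionless `chi_0 <= chi_i`.
#' @export
equilibrium_susceptibility <- function(spec, H0) {
  stopifnot(all(H0 >= 0))
  chi_i <- initial_susceptibility(spec)
  xi <- langevin_parameter(spec, H0)
  ifelse(xi == 0, chi_i, chi_i * 3 / xi * langevin(xi))
}

#' Relaxation loss power of the suspension
#'
#' Volumetric heating power of the superparamagnetic suspension in an
#' alternating field of amplitude `H0` and frequency `f` (Rosensweig
#' relaxation-loss form):
#' \deqn{P_0 = \pi \mu_0 \chi_0 H_0^2 f \,
#'   \frac{2\pi f \tau_{eff}}{1 + (2\pi f \tau_{eff})^2}.}
#'
#' @inheritParams langevin_parameter
#' @param f drive frequency, Hz.
#' @return A list of class `power_result` with `xi`, `chi_i`, `chi_0`,
#'   `tau_eff`, `H0`, `f` and the loss power `P0` (W/m^3).
#' @export
#' @examples
#' sp <- calibrate_relaxation_time(nanoparticle_spec(), 673920, H0 = 6814.2)
#' relaxation_loss_power(sp, 6814.2, 1e5)$P0
relaxation_loss_power <- function(spec, H0, f) {
  stopifnot(H0 >= 0, f >= 0)
  if (is.null(spec$tau_eff)) {
    stop("spec has no tau_eff: set it or calibrate it first", call. = FALSE)
  }
  chi0 <- equilibrium_susceptibility(spec, H0)
  x <- 2 * pi * f * spec$tau_eff
  P0 <- pi * mu0 * chi0 * H0^2 * f * x / (1 + x^2)
  structure(
    list(xi = langevin_parameter(spec, H0),
         chi_i = initial_susceptibility(spec),
         chi_0 = chi0, tau_eff = spec$tau_eff, H0 = H0, f = f, P0 = P0),
    class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("Relaxation loss: P0 = ", signif(x$P0, 6), " W/m^3 at H0 = ",
      x$H0, " A/m, f = ", x$f / 1e3, " kHz\n", sep = "")
  cat("  xi = ", signif(x$xi, 5), ", chi_i = ", signif(x$chi_i, 5),
      ", chi_0 = ", signif(x$chi_0, 5), ", tau_eff = ",
      signif(x$tau_eff, 5), " s\n", sep = "")
  invisible(x)
}

#' Effective relaxation time from Neel and Brownian times
#'
#' The two relaxation channels act in parallel:
#' \eqn{1/\tau_{eff} = 1/\tau_N + 1/\tau_B}.
#'
#' @param tau_N Neel (internal moment flip) time, s.
#' @param tau_B Brownian (particle rotation) time, s.
#' @return Effective relaxation time, s.
#' @export
effective_relaxation_time <- function(tau_N, tau_B) {
  if (any(tau_N <= 0) || any(tau_B <= 0)) {
    stop("relaxation times must be positive", call. = FALSE)
  }
  1 / (1 / tau_N + 1 / tau_B)
}

#' Calibrate the relaxation time to a target loss power
#'
#' Solves for the `tau_eff` at which [relaxation_loss_power()] equals a
#' requested `P0` at the given field and frequency. The frequency response
#' `x/(1+x^2)` (with `x = 2 pi f tau_eff`) is unimodal with its maximum at
#' `x = 1`, so an attainable target has two roots; the sub-peak branch
#' (`x < 1`, the faster relaxation) is returned by default, matching the
#' short Neel times of small superparamagnetic particles.
#'
#' @inheritParams relaxation_loss_power
#' @param target_P0 requested loss power, W/m^3.
#' @param branch `"sub_peak"` (`2 pi f tau < 1`) or `"super_peak"`.
#' @param f drive frequency, Hz.
#' @return The spec with `tau_eff` set.
#' @export
calibrate_relaxation_time <- function(spec, target_P0, H0, f = 1e5,
                                      branch = c("sub_peak", "super_peak")) {
  branch <- match.arg(branch)
  chi0 <- equilibrium_susceptibility(spec, H0)
  pmax_ <- pi * mu0 * chi0 * H0^2 * f * 0.5
  if (target_P0 > pmax_) {
    stop("target P0 exceeds the attainable maximum ", signif(pmax_, 6),
         " W/m^3 at these conditions", call. = FALSE)
  }
  y <- target_P0 / (2 * pmax_)          # solve x/(1+x^2) = y
  disc <- sqrt(1 - 4 * y^2)
  x <- if (branch == "sub_peak") (1 - disc) / (2 * y) else (1 + disc) / (2 * y)
  spec$tau_eff <- x / (2 * pi * f)
  spec
}

#' Tumor heat-source density
#'
#' The volumetric heat source applied to the tumor is the relaxation loss
#' power scaled by the empirical correction factor `alpha` (default 0.55):
#' `alpha * P0`.
#'
#' @param P0 relaxation loss power, W/m^3 (a `power_result` is accepted).
#' @param alpha correction factor in `[0, 1]`.
#' @return Source density, W/m^3.
#' @export
heat_source_density <- function(P0, alpha = 0.55) {
  if (inherits(P0, "power_result")) P0 <- P0$P0
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * P0
}
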