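#' Physical constants used throughout the package
#'
#' `mu0` is the vacuum permeability in H/m, `k_B` the Boltzmann constant in
#' J/K.
#'
#' @name constants
#' @keywords internal
NULL

#' @rdname constants
#' @export
mu0 <- 4e-7 * pi

#' @rdname constants
#' @export
k_B <- 1.380649e-23
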