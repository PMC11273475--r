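#' Tissue property registry
#'
#' Returns the registry of dielectric and thermophysical tissue properties
#' used by the phantom, induced-field and bioheat stages: electrical
#' conductivity (S/m), relative permittivity, density (kg/m^3), specific heat
#' (J/(kg K)), thermal conductivity (W/(m K)), blood perfusion rate (1/s) and
#' metabolic heat production (W/m^3), for scalp, torso, limbs, skull, brain
#' tissue, muscle, the magnetic nanofluid, tumor tissue and the
#' tumor/nanofluid mixed tissue.
#'
#' The registry ships as a plain CSV under `inst/extdata` and is loaded
#' verbatim. Dielectric values are not tabulated for tumor and mixed tissue;
#' with `fill_missing = TRUE` (the default) those two rows take the muscle
#' dielectric values, the closest tabulated soft-tissue surrogate, and the
#' mixed-tissue row inherits tumor perfusion and metabolic heat (the mixing
#' affects density and heat capacity; perfusion and metabolism are those of
#' the host tumor tissue).
#'
#' @param fill_missing fill untabulated dielectric entries for tumor/mixed
#'   tissue from muscle, and untabulated mixed-tissue perfusion/metabolism
#'   from tumor tissue.
#' @return A `data.frame` of class `tissue_registry`, one row per tissue.
#' @export
#' @examples
#' reg <- tissue_table()
#' tissue_lookup(reg, "skull")$k_W_mK
tissue_table <- function(fill_missing = TRUE) {
  path <- system.file("extdata", "tissue_properties.csv", package = "mihsim",
                      mustWork = TRUE)
  reg <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (fill_missing) {
    mus <- reg[reg$tissue == "muscle", ]
    tum <- reg[reg$tissue == "tumor tissue", ]
    for (tt in c("tumor tissue", "mixed tissue")) {
      i <- which(reg$tissue == tt)
      reg$sigma_S_per_m[i] <- mus$sigma_S_per_m
      reg$eps_r[i] <- mus$eps_r
    }
    i <- which(reg$tissue == "mixed tissue")
    reg$omega_b_per_s[i] <- tum$omega_b_per_s
    reg$Qm_W_m3[i] <- tum$Qm_W_m3
  }
  class(reg) <- c("tissue_registry", "data.frame")
  reg
}

#' Look up one tissue in the registry
#'
#' @param registry a `tissue_registry` from [tissue_table()].
#' @param tissue tissue name (exact match).
#' @return A one-row `data.frame` with the tissue's properties.
#' @export
tissue_lookup <- function(registry, tissue) {
  i <- match(tissue, registry$tissue)
  if (is.na(i)) {
    stop("unknown tissue: '", tissue, "'", call. = FALSE)
  }
  registry[i, , drop = FALSE]
}

#' @export
print.tissue_registry <- function(x, ...) {
  cat("Tissue property registry (", nrow(x), " tissues)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Properties of a tumor/nanofluid mixture
#'
#' Computes the effective properties of tumor tissue uniformly loaded with
#' magnetic nanofluid at volume fraction `phi`. Density and specific heat
#' follow the volume-fraction mixing rule
#' \deqn{\rho_{mix} = (1-\varphi)\,\rho_{base} + \varphi\,\rho_{particle}}
#' (and likewise for c). Thermal conductivity is taken from the tabulated
#' mixed-tissue value when the base/particle pair is the tabulated
#' tumor/nanofluid pair (no simple mixing rule reproduces the tabulated
#' value; see the methods vignette), otherwise it is volume-weighted.
#' Perfusion and metabolic heat are inherited from the base tissue: the
#' particles are not perfused and produce no metabolic heat.
#'
#' @param phi nanoparticle volume fraction in `[0, 1]`.
#' @param registry a `tissue_registry`.
#' @param base_tissue host tissue name (default `"tumor tissue"`).
#' @param particle_material particle phase name (default
#'   `"magnetic nanofluids"`).
#' @return A one-row `data.frame` with the mixture's properties, named
#'   `"mixture"` (or the base/particle row unchanged at `phi = 0` / `phi = 1`).
#' @export
#' @examples
#' reg <- tissue_table()
#' mixture_properties(0.003, reg)$rho_kg_m3  # 1072.36 -> tabulated 1072.4
mixture_properties <- function(phi, registry,
                               base_tissue = "tumor tissue",
                               particle_material = "magnetic nanofluids") {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) ||
      phi < 0 || phi > 1) {
    stop("volume fraction 'phi' must be a single number in [0, 1]",
         call. = FALSE)
  }
  base <- tissue_lookup(registry, base_tissue)
  part <- tissue_lookup(registry, particle_material)
  if (phi == 0) return(base)
  if (phi == 1) return(part)

  out <- base
  out$tissue <- "mixture"
  out$rho_kg_m3 <- (1 - phi) * base$rho_kg_m3 + phi * part$rho_kg_m3
  out$c_J_kgK <- (1 - phi) * base$c_J_kgK + phi * part$c_J_kgK
  tabulated <- base_tissue == "tumor tissue" &&
    particle_material == "magnetic nanofluids" &&
    "mixed tissue" %in% registry$tissue
  if (tabulated) {
    out$k_W_mK <- tissue_lookup(registry, "mixed tissue")$k_W_mK
  } else {
    out$k_W_mK <- (1 - phi) * base$k_W_mK + phi * part$k_W_mK
  }
  # omega_b, Qm, dielectric entries stay those of the host tissue
  rownames(out) <- NULL
  out
}

#' Round to decimal places, halves away from zero
#'
#' Decimal rounding as used when comparing against tabulated values printed
#' to a fixed number of decimals (ties round away from zero, the convention
#' of the tables this package mirrors). A magnitude-scaled epsilon guards
#' against binary representation error in values that are exact decimals.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return `x` rounded.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + abs(x) * p * 1e-12) / p
}
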