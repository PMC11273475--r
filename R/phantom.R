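#' Default head-phantom geometry
#'
#' Geometry of the layered mouse-head phantom, all lengths in meters. The
#' head is a concentric triple ellipsoid (brain core, skull shell, scalp
#' shell); the tumor is a right circular disk of fixed face area and
#' thickness sitting on top of the scalp with its center at the origin (the
#' coil geometric center); a muscle stub below the head provides a far-field
#' path to the body heat sink. Shell thicknesses are not tabulated anywhere
#' and default to typical murine-scale values; every entry can be
#' overridden.
#'
#' @param tumor_area tumor face area, m^2 (default 451.52 mm^2).
#' @param tumor_thickness tumor disk thickness, m (default 2 mm).
#' @param scalp_thickness,skull_thickness shell thicknesses, m.
#' @param brain_semiaxes brain ellipsoid semi-axes (x, y, z), m; x is the
#'   coil axis.
#' @param tumor_embed depth to which the scalp apex reaches into the tumor
#'   base, m. A cutaneous melanoma arises within the skin, so the tumor
#'   base is seated in the scalp rather than resting tangentially on it
#'   (a tangent disk would leave an air gap under almost its whole base);
#'   the default seats the base half a scalp thickness deep.
#' @param stub_halfwidth muscle stub half-extent (x, y), m.
#' @param stub_length muscle stub length below the head, m.
#' @param margin air margin around the tissue, m.
#' @return A named list of geometry parameters.
#' @export
head_geometry <- function(tumor_area = 451.52e-6,
                          tumor_thickness = 2e-3,
                          scalp_thickness = 1e-3,
                          skull_thickness = 1e-3,
                          brain_semiaxes = c(8e-3, 6e-3, 6e-3),
                          tumor_embed = scalp_thickness / 2,
                          stub_halfwidth = c(8e-3, 7e-3),
                          stub_length = 8e-3,
                          margin = 2e-3) {
  list(tumor_area = tumor_area,
       tumor_thickness = tumor_thickness,
       scalp_thickness = scalp_thickness,
       skull_thickness = skull_thickness,
       brain_semiaxes = brain_semiaxes,
       tumor_embed = tumor_embed,
       stub_halfwidth = stub_halfwidth,
       stub_length = stub_length,
       margin = margin)
}

#' Build the voxelized layered head phantom
#'
#' Voxelizes the [head_geometry()] scene on an isotropic grid. Each voxel
#' carries exactly one tissue label (air included); membership is decided at
#' the voxel center, with the tumor z-extent half-open so the disk spans
#' exactly `round(thickness / voxel_size)` layers. The physical origin (the
#' coil geometric center) lies on a voxel corner and coincides with the
#' tumor disk center. The tumor carries the `"mixed tissue"` label (tumor
#' uniformly loaded with magnetic nanofluid).
#'
#' @param voxel_size isotropic voxel edge, m; must be positive and at most
#'   1 mm so the 2 mm tumor is at least two voxels thick.
#' @param geometry a list from [head_geometry()].
#' @return An object of class `voxel_phantom`: a list with integer `labels`
#'   (3-D array), the `tissues` label set, `voxel_size`, voxel-center
#'   coordinate vectors `x`, `y`, `z` (m, relative to the coil center) and
#'   the generating `geometry`.
#' @export
#' @examples
#' ph <- build_head_phantom(voxel_size = 1e-3)
#' ph
build_head_phantom <- function(voxel_size = 0.5e-3, geometry = head_geometry()) {
  g <- geometry
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("voxel_size must be a positive scalar (m)", call. = FALSE)
  }
  if (voxel_size > 1e-3 + 1e-12) {
    stop("voxel_size too coarse: must be <= 1 mm", call. = FALSE)
  }
  if (g$tumor_thickness / voxel_size < 2 - 1e-9) {
    stop("voxel_size too coarse to resolve the tumor thickness ",
         "(need >= 2 voxels across ", g$tumor_thickness * 1e3, " mm)",
         call. = FALSE)
  }

  r_t <- sqrt(g$tumor_area / pi)
  shell <- g$scalp_thickness + g$skull_thickness
  a_out <- g$brain_semiaxes + shell            # scalp outer semi-axes
  # head center: scalp apex reaches tumor_embed above the tumor bottom face
  zc <- -(g$tumor_thickness / 2 + a_out[3]) + g$tumor_embed

  half_x <- max(r_t, a_out[1], g$stub_halfwidth[1]) + g$margin
  half_y <- max(r_t, a_out[2], g$stub_halfwidth[2]) + g$margin
  z_top <- g$tumor_thickness / 2 + g$margin
  z_bot <- zc - a_out[3] - g$stub_length

  # voxel corners on multiples of voxel_size so the origin is a corner
  nxp <- ceiling(half_x / voxel_size - 1e-9)
  nyp <- ceiling(half_y / voxel_size - 1e-9)
  nzt <- ceiling(z_top / voxel_size - 1e-9)
  nzb <- ceiling(-z_bot / voxel_size - 1e-9)
  x <- (seq_len(2 * nxp) - nxp - 0.5) * voxel_size
  y <- (seq_len(2 * nyp) - nyp - 0.5) * voxel_size
  z <- (seq_len(nzb + nzt) - nzb - 0.5) * voxel_size

  tissues <- c("air", "mixed tissue", "scalp", "skull", "brain tissue",
               "muscle")
  dims <- c(length(x), length(y), length(z))
  lab <- array(1L, dim = dims)

  X <- array(x, dims)
  Y <- array(rep(y, each = dims[1]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)

  inside_ell <- function(s) {
    (X / s[1])^2 + (Y / s[2])^2 + ((Z - zc) / s[3])^2 <= 1
  }
  brain <- inside_ell(g$brain_semiaxes)
  skull <- inside_ell(g$brain_semiaxes + g$skull_thickness)
  scalp <- inside_ell(a_out)
  stub <- abs(X) <= g$stub_halfwidth[1] & abs(Y) <= g$stub_halfwidth[2] &
    Z <= zc
  tumor <- X^2 + Y^2 <= r_t^2 &
    Z >= -g$tumor_thickness / 2 & Z < g$tumor_thickness / 2

  lab[stub] <- 6L
  lab[scalp] <- 3L
  lab[skull & !brain] <- 4L
  lab[brain] <- 5L
  lab[tumor] <- 2L

  structure(
    list(labels = lab, tissues = tissues, voxel_size = voxel_size,
         x = x, y = y, z = z, geometry = g,
         tumor_radius = r_t, head_center = c(0, 0, zc)),
    class = "voxel_phantom")
}

#' Logical mask of one tissue region
#'
#' @param phantom a `voxel_phantom`.
#' @param tissue a label present in `phantom$tissues` (`"air"` included).
#' @return Logical array of the phantom's grid shape.
#' @export
region_mask <- function(phantom, tissue) {
  i <- match(tissue, phantom$tissues)
  if (is.na(i)) {
    stop("unknown tissue label: '", tissue, "'", call. = FALSE)
  }
  phantom$labels == i
}

#' Volume of one tissue region
#'
#' @inheritParams region_mask
#' @return Region volume in m^3 (voxel count times voxel volume).
#' @export
region_volume <- function(phantom, tissue) {
  sum(region_mask(phantom, tissue)) * phantom$voxel_size^3
}

#' Grid index of the voxel containing a physical point
#'
#' @param phantom a `voxel_phantom`.
#' @param point numeric length-3, m, in the coil-centered frame.
#' @return Integer `(i, j, k)` index of the nearest voxel center.
#' @export
voxel_at <- function(phantom, point) {
  stopifnot(length(point) == 3)
  c(which.min(abs(phantom$x - point[1])),
    which.min(abs(phantom$y - point[2])),
    which.min(abs(phantom$z - point[3])))
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("Voxel head phantom: ", paste(d, collapse = " x "),
      " voxels at ", x$voxel_size * 1e3, " mm\n", sep = "")
  cnt <- tabulate(x$labels, nbins = length(x$tissues))
  vol <- cnt * x$voxel_size^3 * 1e9
  df <- data.frame(tissue = x$tissues, voxels = cnt, volume_mm3 = vol)
  print(df[df$voxels > 0, ], row.names = FALSE, digits = 5)
  invisible(x)
}
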