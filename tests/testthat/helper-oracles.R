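# Brute-force Biot-Savart oracle: field of a polygonal approximation of a
# circular loop (radius R, centered on the x axis at x0, current I), summed
# over straight segments dl x r / |r|^3. Independent of the analytic
# elliptic-integral and on-axis formulas it checks.
biot_savart_segments <- function(R, I, point, x0 = 0, nseg = 1e4) {
  th <- seq(0, 2 * pi, length.out = nseg + 1)
  # segment midpoints and directed lengths on the loop (loop in y-z plane)
  ym <- R * cos((th[-1] + th[-(nseg + 1)]) / 2)
  zm <- R * sin((th[-1] + th[-(nseg + 1)]) / 2)
  dly <- R * (cos(th[-1]) - cos(th[-(nseg + 1)]))
  dlz <- R * (sin(th[-1]) - sin(th[-(nseg + 1)]))
  rx <- point[1] - x0
  ry <- point[2] - ym
  rz <- point[3] - zm
  r3 <- (rx^2 + ry^2 + rz^2)^1.5
  # dl = (0, dly, dlz); B = mu0 I/(4 pi) sum dl x r / r^3
  Bx <- sum((dly * rz - dlz * ry) / r3)
  By <- sum(dlz * rx / r3)
  Bz <- sum(-dly * rx / r3)
  mihsim::mu0 * I / (4 * pi) * c(Bx, By, Bz)
}

# single-block phantom for solver unit tests: n^3 voxels of one tissue
# drawn from a custom registry row
block_phantom <- function(n = 4, voxel_size = 1e-3, tissue = "blocktis") {
  tissues <- c("air", tissue)
  lab <- array(2L, dim = c(n, n, n))
  coords <- (seq_len(n) - (n + 1) / 2) * voxel_size
  structure(
    list(labels = lab, tissues = tissues, voxel_size = voxel_size,
         x = coords, y = coords, z = coords,
         geometry = list(tumor_thickness = 2e-3),
         tumor_radius = NA, head_center = c(0, 0, 0)),
    class = "voxel_phantom")
}

# registry for synthetic solver tests
block_registry <- function(k = 0.5, rho = 1000, c = 3600, omega = 0.01,
                           Qm = 0, tissue = "blocktis") {
  structure(
    data.frame(tissue = tissue, sigma_S_per_m = 0.1, eps_r = 100,
               rho_kg_m3 = rho, c_J_kgK = c, k_W_mK = k,
               omega_b_per_s = omega, Qm_W_m3 = Qm),
    class = c("tissue_registry", "data.frame"))
}

# two-voxel phantom with distinct tissues, for face-conductance checks
two_voxel_phantom <- function(t1, t2, voxel_size = 0.5e-3) {
  lab <- array(c(2L, 3L), dim = c(2, 1, 1))
  structure(
    list(labels = lab, tissues = c("air", t1, t2),
         voxel_size = voxel_size,
         x = c(-0.5, 0.5) * voxel_size, y = 0, z = 0,
         geometry = list(tumor_thickness = 2e-3),
         tumor_radius = NA, head_center = c(0, 0, 0)),
    class = "voxel_phantom")
}
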