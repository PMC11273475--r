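test_that("face conductivities are harmonic means across tissue interfaces", {
  reg <- tissue_table()
  ph <- two_voxel_phantom("skull", "brain tissue")
  op <- assemble_bioheat(ph, bioheat_params(bc_far = list(type = "insulated")),
                         registry = reg)
  g <- -op$K[1, 2] / ph$voxel_size
  expect_equal(g, 2 * 0.32 * 0.515 / (0.32 + 0.515), tolerance = 1e-12)
  expect_equal(g, 0.3947, tolerance = 1e-4)
  # homogeneous block: every face carries the same conductance k * h
  bp <- block_phantom(n = 3)
  bop <- assemble_bioheat(bp, bioheat_params(bc_far = list(type = "insulated")),
                          registry = block_registry(k = 0.5))
  offd <- -as.numeric(bop$K[bop$K < 0])
  expect_equal(range(offd), rep(0.5 * bp$voxel_size, 2), tolerance = 1e-12)
  # zero-perfusion tissue has a zero sink coefficient
  zop <- assemble_bioheat(bp, bioheat_params(),
                          registry = block_registry(omega = 0))
  expect_true(all(zop$P == 0))
})

test_that("assembly validates sources and labels", {
  bp <- block_phantom(n = 2)
  reg <- block_registry()
  bad <- array(-1, dim(bp$labels))
  expect_error(assemble_bioheat(bp, bioheat_params(), bad, reg),
               "nonnegative")
  expect_error(assemble_bioheat(bp, bioheat_params(),
                                registry = block_registry(tissue = "other")),
               "no thermal properties")
})

test_that("explicit stability limit follows rho c dx^2 / (6 k)", {
  ph <- build_head_phantom(0.5e-3)
  lim <- stability_limit(ph)
  # mixed tissue is the limiting class at the default resolution
  expect_equal(as.numeric(lim),
               1072.4 * 3651.1 * (0.5e-3)^2 / (6 * 0.5316),
               tolerance = 1e-12)
  expect_equal(as.numeric(lim), 0.3069, tolerance = 1e-3)
  expect_equal(attr(lim, "tissue"), "mixed tissue")
  # dx^2 scaling
  lim2 <- stability_limit(build_head_phantom(1e-3))
  expect_equal(as.numeric(lim2), 4 * as.numeric(lim), tolerance = 1e-6)
  # violating the bound raises a stability error naming the tissue
  op <- assemble_bioheat(ph, bioheat_params(scheme = "explicit"),
                         registry = tissue_table())
  st <- thermal_state(array(ifelse(ph$labels != 1L, 37, NA),
                            dim(ph$labels)))
  expect_error(bioheat_step(st, op, dt = 1, scheme = "explicit"),
               "stability bound.*mixed tissue")
})

test_that("uniform equilibrium states stay unchanged without forcing", {
  bp <- block_phantom(n = 3)
  reg <- block_registry(omega = 0, Qm = 0)
  params <- bioheat_params(bc_far = list(type = "insulated"))
  op <- assemble_bioheat(bp, params, registry = reg)
  st <- thermal_state(array(37, dim(bp$labels)))
  for (scheme in c("implicit", "explicit")) {
    st1 <- bioheat_step(st, op, dt = 0.05, scheme = scheme)
    expect_equal(st1$temperature, st$temperature, tolerance = 1e-12)
  }
})

test_that("a perfused block follows the exact exponential relaxation", {
  # homogeneous, insulated, uniformly heated: the PDE degenerates to the
  # scalar perfused-tissue ODE, solved in closed form
  rho <- 1072.4; cc <- 3651.1; omega <- 0.01392
  reg <- block_registry(k = 0.5316, rho = rho, c = cc, omega = omega,
                        Qm = 5790)
  bp <- block_phantom(n = 3, voxel_size = 0.5e-3)
  params <- bioheat_params(duration = 300, dt = 1,
                           bc_far = list(type = "insulated"))
  src <- array(370656, dim(bp$labels))
  run <- simulate_bioheat(bp, params, src,
                          probes = list(center = c(0, 0, 0)),
                          registry = reg)
  oracle <- perfused_block_temperature(
    c(100, 300), Q = 370656, Qm = 5790, rho_c = rho * cc, omega_b = omega)
  got <- run$probes$T_C[run$probes$time_s %in% c(100, 300)]
  expect_equal(got, oracle, tolerance = 5e-3)
  # every voxel identical (no gradients)
  Tf <- run$state$temperature
  expect_lt(diff(range(Tf)), 1e-9)
  # the 300 s endpoint reproduces the reference kinetics
  expect_equal(oracle[2], 43.877, tolerance = 1e-4)
  expect_gt(oracle[1], 42)
})

test_that("one implicit step converges at first order to the ODE solution", {
  rho <- 1000; cc <- 3600; omega <- 0.01
  reg <- block_registry(rho = rho, c = cc, omega = omega)
  bp <- block_phantom(n = 2)
  src <- array(2e5, dim(bp$labels))
  errs <- vapply(c(1, 0.25), function(dt) {
    params <- bioheat_params(duration = dt, dt = dt,
                             bc_far = list(type = "insulated"))
    run <- simulate_bioheat(bp, params, src, registry = reg)
    exact <- perfused_block_temperature(dt, Q = 2e5, rho_c = rho * cc,
                                        omega_b = omega)
    abs(run$state$temperature[1, 1, 1] - exact)
  }, numeric(1))
  # quartering dt cuts the one-step error by ~16x (O(dt^2) local error)
  expect_lt(errs[2], errs[1] / 8)
})

test_that("temperature elevation is linear in the source", {
  bp <- block_phantom(n = 3)
  reg <- block_registry(Qm = 0)
  params <- bioheat_params(duration = 50, dt = 1,
                           bc_far = list(type = "insulated"))
  base <- simulate_bioheat(bp, params, registry = reg)$state$temperature
  s1 <- array(1e5, dim(bp$labels))
  r1 <- simulate_bioheat(bp, params, s1, registry = reg)$state$temperature
  r2 <- simulate_bioheat(bp, params, 2 * s1,
                         registry = reg)$state$temperature
  expect_equal(r2 - base, 2 * (r1 - base), tolerance = 1e-9)
})

test_that("insulated unperfused solves conserve enthalpy exactly", {
  bp <- block_phantom(n = 4)
  reg <- block_registry(omega = 0, Qm = 0)
  params <- bioheat_params(duration = 20, dt = 1,
                           bc_far = list(type = "insulated"))
  op <- assemble_bioheat(bp, params, registry = reg)
  # uneven initial field
  arr <- array(37, dim(bp$labels))
  arr[1:2, , ] <- 40
  st <- thermal_state(arr)
  E0 <- sum(op$M * arr[op$active])
  for (i in 1:20) st <- bioheat_step(st, op, dt = 1, scheme = "implicit")
  expect_equal(sum(op$M * st$temperature[op$active]), E0,
               tolerance = 1e-12)
  # with a constant source the enthalpy grows by Q * V_r * t
  src <- array(1e5, dim(bp$labels))
  op2 <- assemble_bioheat(bp, params, src, registry = reg)
  st2 <- thermal_state(array(37, dim(bp$labels)))
  for (i in 1:20) st2 <- bioheat_step(st2, op2, dt = 1, scheme = "implicit")
  gain <- sum(op2$M * st2$temperature[op2$active]) -
    sum(op2$M * 37)
  expect_equal(gain, 1e5 * sum(op2$active) * bp$voxel_size^3 * 20,
               tolerance = 1e-10)
})

test_that("the solution obeys the discrete maximum principle", {
  bp <- block_phantom(n = 4)
  reg <- block_registry(omega = 0, Qm = 0)
  params <- bioheat_params(bc_far = list(type = "insulated"))
  op <- assemble_bioheat(bp, params, registry = reg)
  set.seed(7)
  arr <- array(runif(length(bp$labels), 36, 44), dim(bp$labels))
  st <- thermal_state(arr)
  lo <- min(arr); hi <- max(arr)
  for (scheme in c("implicit", "explicit")) {
    s <- st
    for (i in 1:15) s <- bioheat_step(s, op, dt = 0.05, scheme = scheme)
    expect_gte(min(s$temperature), lo - 1e-9)
    expect_lte(max(s$temperature), hi + 1e-9)
  }
})

test_that("explicit and implicit schemes agree on the head phantom", {
  ph <- build_head_phantom(1e-3)
  src <- array(0, dim(ph$labels))
  src[region_mask(ph, "mixed tissue")] <- 370656
  probes <- list(tumor_center = c(0, 0, 0),
                 brain = c(0, 0, ph$head_center[3]))
  dt <- 0.5   # inside the 1 mm stability bound (~1.2 s)
  runs <- lapply(c("implicit", "explicit"), function(sch) {
    simulate_bioheat(ph, bioheat_params(duration = 300, dt = dt,
                                        scheme = sch),
                     src, probes)
  })
  merged <- merge(runs[[1]]$probes, runs[[2]]$probes,
                  by = c("time_s", "probe"))
  expect_lt(max(abs(merged$T_C.x - merged$T_C.y)), 0.05)
})

test_that("tumor-center temperature is grid-converged at the default resolution", {
  # reduced head (small brain, small tumor) so the halved-voxel solve stays
  # desk-sized; the discretization, interface handling and boundary logic
  # are identical to the full scenario
  g <- head_geometry(tumor_area = 113.1e-6, brain_semiaxes = c(4e-3, 3e-3, 3e-3),
                     stub_halfwidth = c(4e-3, 3.5e-3), stub_length = 4e-3)
  Tc <- vapply(c(0.5e-3, 0.25e-3), function(h) {
    ph <- build_head_phantom(h, g)
    src <- array(0, dim(ph$labels))
    src[region_mask(ph, "mixed tissue")] <- 370656
    run <- simulate_bioheat(ph, bioheat_params(duration = 300, dt = 1),
                            src, probes = list(center = c(0, 0, 0)))
    probe_value(run, "center", 300)
  }, numeric(1))
  expect_lt(abs(diff(Tc)), 0.1)
})

test_that("probes on air voxels are refused", {
  ph <- build_head_phantom(1e-3)
  expect_error(
    simulate_bioheat(ph, bioheat_params(duration = 1),
                     probes = list(out = c(0, 0, 5e-3))),
    "air voxel")
})

test_that("without the nanoparticle source all tissues stay near baseline", {
  ph <- build_head_phantom(1e-3)
  probes <- list(tumor = c(0, 0, 0), mid_head = c(5e-3, 0, -3e-3),
                 brain = c(0, 0, ph$head_center[3]))
  run <- simulate_bioheat(ph, bioheat_params(duration = 300, dt = 1),
                          source = NULL, probes = probes)
  # metabolic heat alone drifts every probe by less than 0.3 degC
  expect_lt(max(abs(run$probes$T_C - 37)), 0.3)
})
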