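test_that("single-loop axial field matches the closed form and its limits", {
  # mu0 I / (2R) at the loop center
  expect_equal(loop_axial_field(0.145, 8, 0), mu0 * 8 / (2 * 0.145))
  expect_equal(loop_axial_field(0.145, 8, 0), 3.4666e-5, tolerance = 1e-4)
  # decay limit
  expect_lt(loop_axial_field(0.145, 8, 100), 1e-12)
  # sign follows the current
  expect_equal(loop_axial_field(0.145, -8, 0.03),
               -loop_axial_field(0.145, 8, 0.03))
})

test_that("analytic loop fields agree with the brute-force segment sum", {
  # on-axis, half a radius away
  x <- 0.0725
  oracle <- biot_savart_segments(0.145, 8, c(x, 0, 0))
  expect_equal(loop_axial_field(0.145, 8, x), oracle[1], tolerance = 1e-4)
  # off-axis points, in and out of the loop plane
  pts <- rbind(c(0, 0.05, 0), c(0.03, 0.08, 0.02), c(-0.05, 0, 0.1))
  for (i in seq_len(nrow(pts))) {
    oracle <- biot_savart_segments(0.145, 8, pts[i, ])
    got <- loop_field_offaxis(0.145, 8, pts[i, ])
    expect_equal(as.numeric(got), oracle, tolerance = 1e-3)
  }
})

test_that("off-axis solution is regular on the axis and flips with the current", {
  B <- loop_field_offaxis(0.145, 8, c(0.02, 0, 0))
  expect_equal(B[1, "By"][[1]], 0)
  expect_equal(B[1, "Bz"][[1]], 0)
  expect_equal(B[1, "Bx"][[1]], loop_axial_field(0.145, 8, 0.02))
  expect_equal(loop_field_offaxis(0.145, -8, c(0, 0.05, 0)),
               -loop_field_offaxis(0.145, 8, c(0, 0.05, 0)))
  expect_error(loop_field_offaxis(0.145, 8, c(0, 0.145, 0)), "singular")
})

test_that("thin-coil limit reproduces the closed-form Helmholtz center field", {
  thin <- coil_spec(inner_radius = 0.145 - 1e-9, outer_radius = 0.145 + 1e-9,
                    width = 1e-9, separation = 0.145)
  drive <- drive_current(8, 1e5)
  closed <- (4 / 5)^1.5 * mu0 * 180 * 8 / 0.145   # 8.930 mT
  expect_equal(helmholtz_center_field(thin, drive), closed,
               tolerance = 1e-6)
})

test_that("axis profile is symmetric and scales linearly with current and turns", {
  coil <- coil_spec()
  drive <- drive_current(8, 1e5)
  xs <- seq(-0.06, 0.06, by = 0.02)
  prof <- helmholtz_axis_profile(coil, drive, xs)
  expect_equal(prof$B_T, rev(prof$B_T))
  expect_equal(prof$H_A_per_m, prof$B_T / mu0)
  prof2 <- helmholtz_axis_profile(coil, drive_current(16, 1e5), xs)
  expect_equal(prof2$B_T, 2 * prof$B_T)
  coilN <- coil_spec(turns = 360, layout = c(radial = 12, axial = 30))
  profN <- helmholtz_axis_profile(coilN, drive, xs)
  expect_equal(profN$B_T, 2 * prof$B_T, tolerance = 1e-3)
})

test_that("pair field is the superposition of the two single coils", {
  coil <- coil_spec()
  drive <- drive_current()
  loops <- mihsim:::coil_loops(coil)
  left <- loops[seq_len(coil$turns), ]
  right <- loops[coil$turns + seq_len(coil$turns), ]
  x <- c(-0.03, 0, 0.04)
  single <- function(set, xi) {
    sum(loop_axial_field(set$R, drive$current, xi - set$x0))
  }
  pair <- helmholtz_axis_profile(coil, drive, x)$B_T
  expect_equal(pair, vapply(x, function(xi) {
    single(left, xi) + single(right, xi)
  }, numeric(1)))
})

test_that("3-D field map matches the axis profile on the axis and doubles with current", {
  coil <- coil_spec()
  drive <- drive_current()
  pts <- rbind(c(0, 0, 0), c(0.02, 0.01, -0.015))
  fm <- field_map_3d(coil, drive, pts)
  expect_equal(fm$B_T[1], helmholtz_center_field(coil, drive))
  fm2 <- field_map_3d(coil, drive_current(16, 1e5), pts)
  expect_equal(fm2$B_T, 2 * fm$B_T)
  expect_equal(fm$H_A_per_m, fm$B_T / mu0)
})

test_that("separation calibration hits a requested center field", {
  coil <- coil_spec()
  drive <- drive_current()
  cal <- calibrate_separation(coil, drive, 8.5621e-3)
  expect_equal(helmholtz_center_field(cal, drive), 8.5621e-3,
               tolerance = 1e-8)
  # separation stays near the coil envelope scale
  expect_gt(cal$separation, 0.1)
  expect_lt(cal$separation, 0.25)
  expect_error(calibrate_separation(coil, drive, 1), "not bracketed")
})

test_that("uniformity report captures Helmholtz flatness", {
  thin <- coil_spec(inner_radius = 0.145 - 1e-9, outer_radius = 0.145 + 1e-9,
                    width = 1e-9, separation = 0.145)
  drive <- drive_current()
  xs <- seq(-0.0145, 0.0145, length.out = 31)
  prof <- helmholtz_axis_profile(thin, drive, xs)
  rep <- uniformity_report(prof)
  expect_lt(rep$ripple, 0.01)
  # quartic flatness: central second difference vanishes as the step shrinks
  d2 <- vapply(c(4e-3, 2e-3, 1e-3), function(h) {
    p <- helmholtz_axis_profile(thin, drive, c(-h, 0, h))$B_T
    abs(p[1] + p[3] - 2 * p[2]) / h^2
  }, numeric(1))
  expect_true(all(diff(d2) < 0))
  # degenerate inputs
  um <- structure(data.frame(x = 1:5, B_T = rep(2, 5)),
                  class = c("field_map", "data.frame"))
  expect_equal(uniformity_report(um)$ripple, 0)
  expect_error(uniformity_report(um, rep(TRUE, 7)), "longer than")
  expect_error(uniformity_report(um, rep(FALSE, 5)), "empty")
})

test_that("coil geometry validation rejects inconsistent layouts", {
  expect_error(coil_spec(layout = c(radial = 10, axial = 15)),
               "exactly 180 loops")
  expect_error(coil_spec(inner_radius = 0.2, outer_radius = 0.15))
})
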