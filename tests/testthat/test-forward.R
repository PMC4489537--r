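test_that("transmission and phase shift match the closed forms", {
  pm <- phantom_slab(500, c(8L, 4L), material = pet_material())
  expect_rel_equal(transmission(pm)[1, 1], 0.989343497189, 1e-9)
  expect_rel_equal(phase_shift(pm)$values[1, 1], -27.9814763755, 1e-9)
  # zero thickness: T = 1, Phi = 0
  z <- phantom_slab(0, c(4L, 4L), material = pet_material())
  expect_equal(transmission(z), matrix(1, 4, 4))
  expect_equal(phase_shift(z)$values, matrix(0, 4, 4))
  # linearity of the phase in thickness
  pm2 <- phantom_slab(1000, c(8L, 4L), material = pet_material())
  expect_equal(phase_shift(pm2)$values, 2 * phase_shift(pm)$values)
})

test_that("refraction angle is the transverse phase gradient over k", {
  # constant phase -> no refraction
  cst <- phase_shift(phantom_slab(200, c(16L, 4L), material = pet_material()))
  expect_equal(refraction_angle_y(cst)$values, matrix(0, 16, 4))
  # linear phase ramp a*y -> uniform a/k, exact for both stencils
  k <- xray_wavenumber(27)
  wg <- phantom_wedge(0, 100, "y", c(64L, 4L), step_y = 20, step_x = 46,
                      material = pet_material())
  dth <- refraction_angle_y(phase_shift(wg))$values
  slope_expect <- -pet_material()$delta * (100e-6 / (63 * 20e-6))
  expect_equal(max(abs(dth - slope_expect)), 0, tolerance = 1e-12)
  # wire: antisymmetric about the axis, matching -delta dt/dy away from
  # the steep edge
  wire <- phantom_cylinder_wire(500, center_y = 2540, shape = c(256L, 4L),
                                step_y = 20, step_x = 46,
                                material = pet_material())
  dth_w <- refraction_angle_y(phase_shift(wire))$values[, 1]
  i0 <- 128  # centre row
  expect_lt(max(abs(dth_w[i0 + (1:8)] + dth_w[i0 - (1:8)])),
            1e-12 * max(abs(dth_w)))
  y <- (seq_len(256) - 1) * 20
  u <- y - 2540
  inner <- abs(u) < 180  # away from the edge singularity
  analytic <- ifelse(abs(u) < 250,
                     -pet_material()$delta * (-2e-6 * u / sqrt(pmax(250^2 - u^2, 1))) * 1e6,
                     0)
  rel <- abs(dth_w[inner] - analytic[inner]) / max(abs(analytic[inner]))
  expect_lt(max(rel), 0.01)
})

test_that("uniform objects and empty fields give the trivial signals", {
  s <- wire_setup()
  slab <- phantom_slab(500, c(32L, 16L), step_y = 20, step_x = 46,
                       material = pet_material())
  img <- simulate_mixed_image(slab, s$geometry, s$curve, s$wp)
  expect_equal(img$values,
               matrix(0.989343497189, 32, 16), tolerance = 1e-9)
  empty <- phantom_slab(0, c(32L, 16L), step_y = 20, step_x = 46,
                        material = pet_material())
  expect_equal(simulate_mixed_image(empty, s$geometry, s$curve, s$wp)$values,
               matrix(1, 32, 16))
  # exact-curve mode agrees on the trivial cases
  expect_equal(simulate_mixed_image(empty, s$geometry, s$curve, s$wp,
                                    mode = "exact-curve")$values,
               matrix(1, 32, 16))
})

test_that("spatial simulator matches the compact spectral form", {
  # same central-difference symbols on both routes: the regrouping
  # T dt/dy = -(1/mu) d/dy exp(-mu t) is exact in the small-gradient
  # regime, so a gentle compact-support bump agrees to high precision
  s <- wire_setup()
  geom0 <- ei_geometry(27, 3.85, 20, 46, lsf_fwhm_x = 0)
  bump <- gaussian_bump_map()
  sp <- simulate_mixed_image(bump, geom0, s$curve, s$wp)
  ce <- simulate_mixed_spectral(bump, geom0, s$wp, stencil = "central")
  expect_lt(sqrt(mean((sp$values - ce$values)^2)), 1e-6)
  # the wire exercises steeper gradients; the two routes still agree to
  # the level set by the discrete product-rule mismatch
  wire <- phantom_cylinder_wire(500, center_y = 2540, shape = c(256L, 64L),
                                step_y = 20, step_x = 46,
                                material = pet_material())
  sw <- simulate_mixed_image(wire, geom0, s$curve, s$wp)
  cw <- simulate_mixed_spectral(wire, geom0, s$wp, stencil = "central")
  expect_lt(sqrt(mean((sw$values - cw$values)^2)), 5e-4)
})

test_that("exact-curve mode converges quadratically to the linearized mode", {
  # a working point off the symmetric 50% level, on a strongly blurred
  # curve, has genuine curvature, so the first-order expansion error is
  # quadratic in the refraction angle
  geom0 <- ei_geometry(27, 3.85, 20, 46, lsf_fwhm_x = 0)
  cv <- ei_curve_analytic(20, 250, sigma_src = 8)
  wp <- working_point(cv, 0.3, "lower")
  gap <- function(delta) {
    mat <- ei_material("scaled", delta, 7.83e-11, 27)
    bump <- gaussian_bump_map(amplitude = 100, width_um = 150, material = mat)
    a <- simulate_mixed_image(bump, geom0, cv, wp)
    b <- simulate_mixed_image(bump, geom0, cv, wp, mode = "exact-curve")
    max(abs(a$values - b$values))
  }
  g1 <- gap(4.09e-7)
  g2 <- gap(4.09e-7 / 2)
  expect_gt(g1, 0)
  # halving the refraction angles quarters the discrepancy
  expect_lt(abs(g1 / g2 - 4), 0.6)
})

test_that("the LSF convolution preserves the image mean and acts along x only", {
  s <- wire_setup()
  bump <- gaussian_bump_map(amplitude = 80, width_um = 200)
  g46 <- ei_geometry(27, 3.85, 20, 46, lsf_fwhm_x = 120)
  g0 <- ei_geometry(27, 3.85, 20, 46, lsf_fwhm_x = 0)
  blurred <- simulate_mixed_image(bump, g46, s$curve, s$wp)
  sharp <- simulate_mixed_image(bump, g0, s$curve, s$wp)
  expect_lt(abs(mean(blurred$values) - mean(sharp$values)), 1e-9)
  # blur reduces variation along x but rows keep their y structure
  expect_lt(max(abs(apply(blurred$values, 1, diff))),
            max(abs(apply(sharp$values, 1, diff))))
  # an x-uniform object is untouched by the LSF
  wire <- phantom_cylinder_wire(500, shape = c(128L, 32L), step_y = 20,
                                step_x = 46, material = pet_material())
  expect_equal(simulate_mixed_image(wire, g46, s$curve, s$wp)$values,
               simulate_mixed_image(wire, g0, s$curve, s$wp)$values,
               tolerance = 1e-12)
})

test_that("working points without refraction sensitivity are rejected", {
  s <- wire_setup()
  wire <- phantom_cylinder_wire(500, shape = c(64L, 8L), step_y = 20,
                                step_x = 46, material = pet_material())
  flat_wp <- structure(list(y_e = 125, C0 = 1, C1 = 0, branch = "lower"),
                       class = "ei_working_point")
  expect_error(simulate_mixed_image(wire, s$geometry, s$curve, flat_wp),
               "slope|sensitivity")
})

test_that("taylor validity report scales linearly with propagation distance", {
  s <- wire_setup()
  wire <- phantom_cylinder_wire(500, shape = c(128L, 8L), step_y = 20,
                                step_x = 46, material = pet_material())
  empty <- phantom_slab(0, c(16L, 4L), material = pet_material())
  expect_equal(taylor_validity_check(empty, s$geometry, s$curve, s$wp)$ratio, 0)
  r1 <- taylor_validity_check(wire, s$geometry, s$curve, s$wp)
  g2 <- ei_geometry(27, 2 * 3.85, 20, 46, 46)
  r2 <- taylor_validity_check(wire, g2, s$curve, s$wp)
  expect_rel_equal(r2$ratio, 2 * r1$ratio, 1e-9)
  expect_gt(r1$max_shift_um, 0)
})
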