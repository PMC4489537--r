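test_that("the filter denominator is bounded below and exact at DC", {
  flt <- build_retrieval_filter(c(64L, 64L), 20, 46, A = 7.35e-8,
                                slope_ratio = 0.1, lsf_fwhm_x = 46)
  expect_identical(flt$D[1, 1], 1 + 0i)
  expect_true(all(Mod(flt$D) >= rep(flt$mtf_x, each = 64) - 1e-14))
  expect_true(all(flt$mtf_x > 0))
  # property sweep over random parameter draws
  set.seed(502)
  for (i in 1:15) {
    flt <- build_retrieval_filter(c(32L, 48L), runif(1, 1, 50), runif(1, 1, 50),
                                  A = 10^runif(1, -10, -6),
                                  slope_ratio = runif(1, -1, 1),
                                  lsf_fwhm_x = runif(1, 0, 100))
    expect_identical(flt$D[1, 1], 1 + 0i)
    expect_gte(min(Mod(flt$D)), min(flt$mtf_x) - 1e-14)
  }
})

test_that("the filter reduces to the known limits", {
  # A = 0, no blur: identity (pure attenuation)
  flt0 <- build_retrieval_filter(c(32L, 32L), 20, 46, A = 0, slope_ratio = 0.3)
  expect_equal(flt0$D, matrix(1 + 0i, 32, 32))
  # zero slope, no blur: the real one-directional duality filter
  # 1 + A xi_x^2, never below 1
  flt1 <- build_retrieval_filter(c(32L, 32L), 20, 46, A = 7.35e-8,
                                 slope_ratio = 0)
  expect_true(all(Im(flt1$D) == 0))
  xi_x <- flt1$xi_x
  expect_equal(Re(flt1$D), outer(rep(1, 32), 1 + 7.35e-8 * xi_x^2))
  expect_true(all(Re(flt1$D) >= 1))
})

test_that("retrieval exactly inverts the spectral forward model", {
  s <- wire_setup()
  wire <- phantom_cylinder_wire(500, center_y = 1260, shape = c(128L, 32L),
                                step_y = 20, step_x = 46,
                                material = pet_material())
  img <- simulate_mixed_spectral(wire, s$geometry, s$wp)
  t_ret <- retrieve_thickness(img, pet_material(), s$geometry, s$wp,
                              pad = "none")
  expect_lt(max(abs(t_ret$values - wire$values)), 1e-10 * max(wire$values))
  lg <- attr(t_ret, "retrieval_log")
  expect_lt(lg$imag_rms_ratio, 1e-9)
  expect_equal(lg$clipped_fraction, 0)
})

test_that("a flat unit image retrieves zero thickness and density", {
  s <- wire_setup()
  ones <- ei_image(matrix(1, 32, 32), 20, 46)
  t0 <- retrieve_thickness(ones, pet_material(), s$geometry, s$wp)
  expect_lt(max(abs(t0$values)), 1e-10)
  rho <- retrieve_electron_density(ones, 2.46e-6 / 5.94e-9,
                                   petal_benchmark_geometry(),
                                   petal_setup()$wp)
  expect_lt(max(abs(rho$values)), 1e-10)
})

test_that("delta = 0 reduces retrieval to the pure-attenuation logarithm", {
  s <- wire_setup()
  geom0 <- ei_geometry(27, 3.85, 20, 46, lsf_fwhm_x = 0)
  absorber <- ei_material("absorber", 0, 7.83e-11, 27)
  wire <- phantom_cylinder_wire(500, shape = c(64L, 16L), step_y = 20,
                                step_x = 46, material = absorber)
  img <- simulate_mixed_image(wire, geom0, s$curve, s$wp)
  t_f <- retrieve_thickness(img, absorber, geom0, s$wp)
  t_l <- retrieve_thickness_log(img, absorber)
  expect_lt(max(abs(t_f$values - t_l$values)), 1e-10 * max(abs(t_l$values)))
})

test_that("electron density equals delta t / sigma for a single material", {
  s <- petal_setup()
  ph <- phantom_textured(seed = 5, shape = c(96L, 96L),
                         material = water_material())
  img <- simulate_mixed_image(ph, s$geometry, s$curve, s$wp)
  noisy <- add_poisson_noise(img, 100, seed = 3)
  for (im in list(img, noisy)) {
    t_ret <- retrieve_thickness(im, water_material(), s$geometry, s$wp)
    rho <- retrieve_electron_density(im, 2.46e-6 / 5.94e-9, s$geometry, s$wp)
    sigma <- electron_density_scale(9.7)
    # delta * t / sigma, t in m, reported per um^2
    expected <- 2.46e-6 * (t_ret$values * 1e-6) / sigma * 1e-12
    expect_lt(max(abs(rho$values - expected)), 1e-10 * max(abs(rho$values)))
  }
})

test_that("the filter behaves as a low-pass under white noise", {
  s <- wire_setup()
  set.seed(77)
  noise <- ei_image(matrix(1 + 0.05 * rnorm(64 * 64), 64, 64), 20, 46)
  geom0 <- ei_geometry(27, 3.85, 20, 46, lsf_fwhm_x = 0)
  t_filt <- retrieve_thickness(noise, pet_material(), geom0, s$wp)
  t_log <- retrieve_thickness_log(noise, pet_material())
  expect_lt(var(as.vector(t_filt$values)), var(as.vector(t_log$values)))
})

test_that("a wedge spanning the frame shows no boundary spikes", {
  s <- wire_setup()
  wg <- phantom_wedge(20, 120, "y", c(256L, 64L), step_y = 20, step_x = 46,
                      material = pet_material())
  img <- simulate_mixed_image(wg, s$geometry, s$curve, s$wp)
  t_ret <- retrieve_thickness(img, pet_material(), s$geometry, s$wp)
  r <- abs(t_ret$values - wg$values)
  band <- 4L
  boundary <- r[c(seq_len(band), 257 - seq_len(band)), ]
  interior <- r[(band + 1):(256 - band), ]
  expect_lt(max(boundary), 2 * max(interior))
})

test_that("inconsistent input (all pixels clipped) raises an error", {
  s <- wire_setup()
  bad <- ei_image(matrix(-5, 16, 16), 20, 46)
  expect_error(retrieve_thickness(bad, pet_material(), s$geometry, s$wp),
               "inconsistent")
})

test_that("clipping is counted and reported", {
  s <- wire_setup()
  # a block of impossible (negative) columns survives the low-pass and
  # drives the filtered image below eps there, but not everywhere
  v <- matrix(1, 32, 32); v[, 1:12] <- -1
  img <- ei_image(v, 20, 46)
  t_ret <- retrieve_thickness(img, pet_material(), s$geometry, s$wp,
                              pad = "none")
  lg <- attr(t_ret, "retrieval_log")
  expect_gt(lg$clipped_fraction, 0.05)
  expect_lt(lg$clipped_fraction, 0.95)
})
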