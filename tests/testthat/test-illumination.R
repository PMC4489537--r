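test_that("analytic curve hits the geometric anchor points", {
  # sharp beam profile, wide detector aperture
  cv <- ei_curve_analytic(a1 = 20, a2 = 250, sigma_src = 0)
  # full overlap at the apex
  expect_equal(curve_eval(cv, 125), 1)
  # lower aperture edge at the beam centre: exactly half the beam enters
  expect_identical(curve_eval(cv, 0), 0.5)
  # far away the curve vanishes
  expect_equal(curve_eval(cv, -1e4), 0)
  expect_equal(curve_eval(cv, 1e4), 0)
  # single-edge curve sweeps the full 0 -> 1 transition
  ce <- ei_curve_analytic(a1 = 3, a2 = Inf, sigma_src = 0.5)
  expect_lt(curve_eval(ce, -30), 1e-12)
  expect_gt(curve_eval(ce, 30), 1 - 1e-12)
  expect_identical(curve_eval(ce, 0), 0.5)
})

test_that("analytic curve equals adaptive quadrature of the beam profile", {
  cv <- ei_curve_analytic(a1 = 20, a2 = 250, sigma_src = 3)
  pdf <- function(y) (pnorm(y + 10, sd = 3) - pnorm(y - 10, sd = 3)) / 20
  for (ye in c(-15, -3, 0, 7, 120, 243, 260)) {
    ref <- stats::integrate(pdf, -ye, 250 - ye, rel.tol = 1e-12,
                            abs.tol = 1e-13)$value
    expect_lt(abs(curve_eval(cv, ye) - ref), 1e-10)
  }
})

test_that("slope matches the closed-form geometry and a finite-difference oracle", {
  cv0 <- ei_curve_analytic(a1 = 20, a2 = 250, sigma_src = 0)
  # stationary apex
  expect_equal(curve_slope(cv0, 125), 0)
  # on the ramps the slope is +-1/a1: the transition happens over the
  # width of the unit-mass beam profile
  expect_equal(curve_slope(cv0, 0), 1 / 20)
  expect_equal(curve_slope(cv0, 250), -1 / 20)
  # blurred curve vs central differences
  cv <- ei_curve_analytic(a1 = 20, a2 = 250, sigma_src = 2)
  h <- 1e-4
  ys <- seq(-25, 275, by = 12.5)
  fd <- (curve_eval(cv, ys + h) - curve_eval(cv, ys - h)) / (2 * h)
  an <- curve_slope(cv, ys)
  expect_lt(max(abs(an - fd)), 1e-6 * max(abs(an)))
})

test_that("curve values stay within [0, 1] and branches are monotone", {
  set.seed(401)
  for (i in 1:20) {
    a1 <- runif(1, 1, 50)
    a2 <- if (i %% 4 == 0) Inf else runif(1, a1, 400)
    sig <- runif(1, 0, 5)
    cv <- ei_curve_analytic(a1, a2, sig)
    span <- if (is.finite(a2)) a2 else 0
    ys <- seq(-3 * a1 - 20 * sig, span + 3 * a1 + 20 * sig, length.out = 301)
    C <- curve_eval(cv, ys)
    expect_true(all(C >= 0 & C <= 1))
    lower <- ys[ys < (if (is.finite(a2)) a2 / 2 else Inf)]
    expect_true(all(diff(curve_eval(cv, lower)) >= -1e-12))
  }
})

test_that("working point inversion round-trips and picks the right branch", {
  cv <- ei_curve_analytic(20, 250, 0.28)
  for (f in c(0.1, 0.3, 0.5, 0.9)) {
    lo <- working_point(cv, f, "lower")
    hi <- working_point(cv, f, "upper")
    expect_lt(abs(curve_eval(cv, lo$y_e) - f), 1e-8)
    expect_lt(abs(curve_eval(cv, hi$y_e) - f), 1e-8)
    expect_gt(lo$C1, 0)
    expect_lt(hi$C1, 0)
  }
  # 50% on the lower branch = edge aligned with the beam-profile centre
  wp <- working_point(cv, 0.5, "lower")
  expect_lt(abs(wp$y_e), 1e-7)
  # the apex cannot serve as a working point
  expect_error(working_point(cv, 1, "lower"), "apex|maximum")
  # single-edge curves have no upper branch
  expect_error(working_point(ei_curve_analytic(3, Inf, 0.5), 0.5, "upper"),
               "unreachable")
})

test_that("tabulated curves reproduce their analytic source", {
  cv <- ei_curve_analytic(20, 250, 2)
  ys <- seq(-60, 310, by = 1)  # knot spacing well below the 2 um blur
  tab <- ei_curve_tabulated(ys, curve_eval(cv, ys))
  off <- seq(-55, 305, by = 3.7)  # off-grid points
  expect_lt(max(abs(curve_eval(tab, off) - curve_eval(cv, off))), 1e-4)
  slope_err <- abs(curve_slope(tab, off) - curve_slope(cv, off))
  expect_lt(max(slope_err), 1e-3 * max(abs(curve_slope(cv, off))) + 1e-6)
  # no extrapolation outside the tabulated support
  expect_error(curve_eval(tab, -100), "support")
  expect_error(curve_slope(tab, 400), "support")
})

test_that("tabulated curves are re-normalized with a warning beyond 5%", {
  ys <- seq(-40, 40, by = 1)
  C <- 0.9 * exp(-ys^2 / 200)  # apex 0.9: off by 10%
  expect_warning(tab <- ei_curve_tabulated(ys, C), "re-normalizing")
  expect_equal(max(tab$C), 1)
  # a 2% apex deviation is normalized silently
  expect_silent(ei_curve_tabulated(ys, 0.98 * exp(-ys^2 / 200)))
  expect_error(ei_curve_tabulated(c(0, 1, 1, 2), c(0, 1, 1, 0)), "increasing")
})
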