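# Illumination curves C(y_e): the fraction of the unperturbed beam entering
# the detector aperture as a function of the working point y_e.
#
# Coordinate convention (used consistently by the forward model and the
# retrieval filter): y_e is the height of the beam-profile centre above the
# LOWER edge of the detector aperture. Increasing y_e moves the beam up
# into the aperture, so on the lower-edge branch C'(y_e) > 0 and an upward
# refraction shift z * dtheta_y increases the counts; the effective signal
# is C(y_e + z * dtheta_y). The classical 50% working point (lower edge of
# the detector aperture aligned with the beam-profile centre) is y_e = 0.

#' Analytic illumination curve
#'
#' Models the beam profile at the detector plane as a rectangle of width
#' `a1` (the pre-sample aperture) convolved with a Gaussian of standard
#' deviation `sigma_src` (source blur projected to the detector plane),
#' normalized to unit mass. The curve is the integral of this profile over
#' the detector aperture of width `a2` whose lower edge sits a distance
#' `y_e` below the profile centre. For `sigma_src = 0` the curve is the
#' piecewise-linear overlap of two rectangles; `a2 = Inf` models a single
#' edge (e.g. a virtual edge on a high-resolution detector).
#'
#' @param a1 Pre-sample aperture width, micrometres (> 0).
#' @param a2 Detector aperture width, micrometres (> 0, may be `Inf`).
#' @param sigma_src Gaussian source blur sigma at the detector plane,
#'   micrometres (>= 0).
#' @return An object of class `ei_curve`, kind `"analytic"`.
#' @export
#' @examples
#' cv <- ei_curve_analytic(a1 = 20, a2 = 250, sigma_src = 0)
#' curve_eval(cv, 0) # 0.5: lower edge at the beam centre
ei_curve_analytic <- function(a1, a2 = Inf, sigma_src = 0) {
  check_scalar(a1, "a1", positive = TRUE)
  check_scalar(a2, "a2", positive = TRUE, allow_inf = TRUE)
  check_scalar(sigma_src, "sigma_src", nonneg = TRUE)
  structure(list(kind = "analytic", a1 = a1, a2 = a2, sigma_src = sigma_src),
            class = "ei_curve")
}

# Beam profile P (unit mass), its CDF I, and the antiderivative H of the
# Gaussian CDF: H(u) = u G(u) + sigma^2 g(u), so that
# I(y) = [H(y + a1/2) - H(y - a1/2)] / a1. For sigma = 0, H(u) = max(u, 0).
.h_fun <- function(u, sigma) {
  if (sigma == 0) return(pmax(u, 0))
  u * stats::pnorm(u, sd = sigma) + sigma^2 * stats::dnorm(u, sd = sigma)
}

.profile_pdf <- function(y, a1, sigma) {
  if (sigma == 0) return(as.numeric(abs(y) <= a1 / 2) / a1)
  (stats::pnorm(y + a1 / 2, sd = sigma) - stats::pnorm(y - a1 / 2, sd = sigma)) / a1
}

.profile_cdf <- function(y, a1, sigma) {
  (.h_fun(y + a1 / 2, sigma) - .h_fun(y - a1 / 2, sigma)) / a1
}

#' Tabulated illumination curve
#'
#' Wraps a measured (y_e, C) table with a cubic-spline interpolant. The
#' table is re-normalized so its apex equals 1; a warning is emitted when
#' the raw apex differs from 1 by more than 5%.
#'
#' @param y_e Strictly increasing grid of edge positions, micrometres.
#' @param C Illumination fractions on the grid (0 <= C <= 1 after
#'   normalization).
#' @param normalize Re-scale so `max(C) = 1` (default `TRUE`).
#' @return An object of class `ei_curve`, kind `"tabulated"`.
#' @export
ei_curve_tabulated <- function(y_e, C, normalize = TRUE) {
  if (length(y_e) != length(C) || length(y_e) < 4L)
    stop_field("need matching y_e and C vectors of length >= 4")
  if (anyNA(y_e) || anyNA(C)) stop_field("y_e and C must not contain NA")
  if (any(diff(y_e) <= 0)) stop_field("y_e grid must be strictly increasing")
  apex_raw <- max(C)
  if (apex_raw <= 0) stop_field("curve must be positive somewhere")
  if (normalize) {
    if (abs(apex_raw - 1) > 0.05)
      warning(sprintf("raw curve apex %.4g differs from 1 by more than 5%%; re-normalizing",
                      apex_raw), call. = FALSE)
    C <- C / apex_raw
  }
  if (any(C < -1e-9) || any(C > 1 + 1e-9))
    stop_field("C values must lie in [0, 1]")
  C <- pmin(pmax(C, 0), 1)
  structure(list(kind = "tabulated", y_e = as.numeric(y_e), C = as.numeric(C),
                 spline = stats::splinefun(y_e, C, method = "fmm")),
            class = "ei_curve")
}

#' @export
print.ei_curve <- function(x, ...) {
  if (x$kind == "analytic")
    cat(sprintf("<ei_curve> analytic: a1 = %g um, a2 = %g um, sigma_src = %g um\n",
                x$a1, x$a2, x$sigma_src))
  else
    cat(sprintf("<ei_curve> tabulated on [%g, %g] um (%d points)\n",
                min(x$y_e), max(x$y_e), length(x$y_e)))
  invisible(x)
}

#' Supported y_e range of a curve
#' @param curve An `ei_curve`.
#' @return Length-2 numeric range (micrometres); infinite for analytic curves.
#' @export
curve_support <- function(curve) {
  stopifnot(inherits(curve, "ei_curve"))
  if (curve$kind == "analytic") c(-Inf, Inf) else range(curve$y_e)
}

.check_in_support <- function(curve, y_e) {
  if (curve$kind == "tabulated") {
    r <- range(curve$y_e)
    if (any(y_e < r[1] | y_e > r[2]))
      stop_field("y_e outside the tabulated support [%g, %g]; extrapolation is not allowed",
                 r[1], r[2])
  }
  invisible(TRUE)
}

#' Evaluate an illumination curve
#'
#' @param curve An `ei_curve`.
#' @param y_e Edge position(s), micrometres; must lie within the tabulated
#'   support for tabulated curves (no extrapolation).
#' @return Illumination fraction(s) in `[0, 1]`.
#' @export
curve_eval <- function(curve, y_e) {
  stopifnot(inherits(curve, "ei_curve"))
  if (anyNA(y_e)) stop_field("y_e must not contain NA")
  .check_in_support(curve, y_e)
  if (curve$kind == "analytic") {
    upper <- if (is.finite(curve$a2)) {
      .profile_cdf(curve$a2 - y_e, curve$a1, curve$sigma_src)
    } else rep(1, length(y_e))
    val <- upper - .profile_cdf(-y_e, curve$a1, curve$sigma_src)
  } else {
    val <- curve$spline(y_e)
  }
  pmin(pmax(val, 0), 1)
}

#' Slope of an illumination curve
#'
#' Closed-form derivative for analytic curves; spline derivative for
#' tabulated ones.
#'
#' @inheritParams curve_eval
#' @return `dC/dy_e` in 1/micrometre.
#' @export
curve_slope <- function(curve, y_e) {
  stopifnot(inherits(curve, "ei_curve"))
  if (anyNA(y_e)) stop_field("y_e must not contain NA")
  .check_in_support(curve, y_e)
  if (curve$kind == "analytic") {
    low <- .profile_pdf(-y_e, curve$a1, curve$sigma_src)
    high <- if (is.finite(curve$a2)) {
      .profile_pdf(curve$a2 - y_e, curve$a1, curve$sigma_src)
    } else 0
    low - high
  } else {
    curve$spline(y_e, deriv = 1)
  }
}

# Apex (position and value of the curve maximum). For the analytic
# symmetric model the apex is at y_e = a2/2; a single edge (a2 = Inf) has
# its supremum C -> 1 as y_e -> Inf, reported as an infinite apex.
curve_apex <- function(curve) {
  if (curve$kind == "analytic") {
    if (!is.finite(curve$a2)) return(list(y_e = Inf, C = 1))
    y <- curve$a2 / 2
    return(list(y_e = y, C = curve_eval(curve, y)))
  }
  i <- which.max(curve$C)
  lo <- curve$y_e[max(1L, i - 1L)]
  hi <- curve$y_e[min(length(curve$y_e), i + 1L)]
  if (lo == hi) return(list(y_e = curve$y_e[i], C = curve$C[i]))
  opt <- stats::optimize(function(y) curve$spline(y), c(lo, hi), maximum = TRUE)
  if (opt$objective >= curve$C[i]) list(y_e = opt$maximum, C = min(opt$objective, 1))
  else list(y_e = curve$y_e[i], C = curve$C[i])
}

#' Full width at half-maximum of an illumination curve
#'
#' Distance between the two half-apex crossings; `NA` when one side has no
#' crossing (e.g. a single-edge curve whose upper branch never falls).
#'
#' @param curve An `ei_curve`.
#' @return FWHM in micrometres, or `NA`.
#' @export
curve_fwhm <- function(curve) {
  apex <- curve_apex(curve)
  half <- apex$C / 2
  lower <- tryCatch(working_point(curve, half, "lower")$y_e,
                    error = function(e) NA_real_)
  upper <- tryCatch(working_point(curve, half, "upper")$y_e,
                    error = function(e) NA_real_)
  upper - lower
}

#' Find the working point at a given illumination fraction
#'
#' Inverts `C(y_e) = fraction` on one monotone branch of the curve by
#' bisection (relative tolerance 1e-9) and returns the edge position
#' together with the local value and slope, the quantities entering the
#' forward model and the retrieval filter.
#'
#' @param curve An `ei_curve`.
#' @param fraction Target illumination fraction, `0 < fraction < max(C)`.
#' @param branch `"lower"` (beam entering through the aperture's lower
#'   edge, `C' > 0`, the default) or `"upper"` (`C' < 0`).
#' @return An object of class `ei_working_point` with fields `y_e` (um),
#'   `C0`, `C1` (1/um) and `branch`.
#' @export
#' @examples
#' cv <- ei_curve_analytic(20, 250, 0)
#' working_point(cv, 0.5, "lower") # y_e = 0, C1 = +1/20
working_point <- function(curve, fraction, branch = c("lower", "upper")) {
  stopifnot(inherits(curve, "ei_curve"))
  branch <- match.arg(branch)
  check_scalar(fraction, "fraction", positive = TRUE)
  apex <- curve_apex(curve)
  if (fraction >= apex$C)
    stop_field("fraction %g is not below the curve maximum %g; the apex has zero slope and cannot serve as a working point",
               fraction, apex$C)
  f <- function(y) curve_eval(curve, y) - fraction
  if (branch == "lower") {
    hi <- if (is.finite(apex$y_e)) apex$y_e else {
      y <- 1
      while (f(y) < 0) y <- y * 2
      y
    }
    lo <- .bracket_down(curve, f, hi, -1)
  } else {
    if (!is.finite(apex$y_e))
      stop_field("fraction %g unreachable on the upper branch of a single-edge curve",
                 fraction)
    lo <- apex$y_e
    hi <- .bracket_down(curve, f, lo, +1)
  }
  root <- stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi),
                         tol = 1e-9 * max(1, abs(lo), abs(hi)))$root
  wp <- structure(list(y_e = root, C0 = curve_eval(curve, root),
                       C1 = curve_slope(curve, root), branch = branch),
                  class = "ei_working_point")
  if (wp$C0 <= 0) stop_field("working point has non-positive illumination")
  wp
}

# Walk away from `start` in direction `dir` until f changes sign, staying
# inside the tabulated support.
.bracket_down <- function(curve, f, start, dir) {
  sup <- curve_support(curve)
  step <- if (curve$kind == "analytic")
    max(curve$a1, if (is.finite(curve$a2)) curve$a2 else 0, curve$sigma_src, 1)
  else diff(range(curve$y_e)) / 8
  y <- start
  for (i in 1:60) {
    y_new <- y + dir * step
    y_new <- min(max(y_new, sup[1]), sup[2])
    if (f(y_new) < 0) return(y_new)
    if (y_new == y || y_new <= sup[1] || y_new >= sup[2]) break
    y <- y_new
    step <- step * 2
  }
  stop_field("requested fraction unreachable on this branch of the curve")
}

#' @export
print.ei_working_point <- function(x, ...) {
  cat(sprintf("<ei_working_point> %s branch: y_e = %.6g um, C = %.6g, C' = %.6g /um\n",
              x$branch, x$y_e, x$C0, x$C1))
  invisible(x)
}
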