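# Forward image formation for edge illumination: refraction-modulated
# illumination along y (the scan direction) plus a near-field
# transport-of-intensity term along x (parallel to the slits), blurred by
# the system LSF along x only.
#
# Shared sign convention (binding for the retrieval filter too):
#   Phi = -k delta t,   dtheta_y = (1/k) dPhi/dy = -delta dt/dy,
# working points on the lower-edge branch have C' > 0, and the exact
# signal along y is T * C(y_e + z * dtheta_y) / C(y_e).

.require_material <- function(t_map, material = NULL) {
  m <- if (!is.null(material)) material else t_map$material
  if (is.null(m))
    stop_field("a material is required: attach one to the thickness map or pass it explicitly")
  stopifnot(inherits(m, "ei_material"))
  m
}

#' Transmission of a single-material object
#'
#' `T = exp(-mu t)` with `mu = 2 k beta`.
#'
#' @param t_map A [thickness_map()] (micrometres).
#' @param material Optional [ei_material()] overriding the map's material.
#' @return Numeric matrix of transmission values in `(0, 1]`.
#' @export
transmission <- function(t_map, material = NULL) {
  stopifnot(inherits(t_map, "thickness_map"))
  m <- .require_material(t_map, material)
  exp(-attenuation_coefficient(m) * t_map$values * 1e-6)
}

#' Phase shift of a single-material object
#'
#' `Phi = -k delta t` (radians), negative for `delta > 0` and `t > 0`.
#'
#' @inheritParams transmission
#' @return An object of class `phase_map` (values in radians).
#' @export
phase_shift <- function(t_map, material = NULL) {
  stopifnot(inherits(t_map, "thickness_map"))
  m <- .require_material(t_map, material)
  k <- xray_wavenumber(m$energy_keV)
  structure(list(values = -k * m$delta * t_map$values * 1e-6,
                 step_y = t_map$step_y, step_x = t_map$step_x,
                 energy_keV = m$energy_keV),
            class = "phase_map")
}

#' Refraction angle along the scan direction
#'
#' `dtheta_y = (1/k) dPhi/dy`, computed with central differences in the
#' interior and one-sided differences at the frame edges.
#'
#' @param phase_map A `phase_map` from [phase_shift()].
#' @return An object of class `refraction_map` (values in radians).
#' @export
refraction_angle_y <- function(phase_map) {
  stopifnot(inherits(phase_map, "phase_map"))
  k <- xray_wavenumber(phase_map$energy_keV)
  d <- deriv1(phase_map$values, phase_map$step_y * 1e-6, dim = 1L)
  structure(list(values = d / k, step_y = phase_map$step_y,
                 step_x = phase_map$step_x, energy_keV = phase_map$energy_keV),
            class = "refraction_map")
}

# Convolve along x only with a unit-area Gaussian of the given FWHM,
# using FFT on a mirror-padded x axis. Identity for fwhm_um = 0.
lsf_convolve_x <- function(m, step_x_um, fwhm_um) {
  if (fwhm_um == 0) return(m)
  nx <- ncol(m)
  ix <- pad_indices(nx, padded_size(nx), "mirror")
  mp <- m[, ix$idx, drop = FALSE]
  nxp <- ncol(mp)
  xi <- fft_xi(nxp, step_x_um * 1e-6)
  mtf <- exp(-gaussian_sigma_from_fwhm(fwhm_um * 1e-6)^2 * xi^2 / 2)
  f <- stats::mvfft(t(mp)) * mtf
  t(Re(stats::mvfft(f, inverse = TRUE)) / nxp)[, ix$first:ix$last, drop = FALSE]
}

#' Simulate the normalized mixed EI image from a thickness map
#'
#' In `"linearized"` mode (first-order Taylor expansion of the
#' illumination curve about the working point) the signal is
#' `S_n = [ T + z (C'/C0) T dtheta_y - (z/k) d/dx (T dPhi/dx) ]`
#' convolved along x with the Gaussian LSF of the configured FWHM. In
#' `"exact-curve"` mode the first two terms are replaced by
#' `T C(y_e + z dtheta_y) / C0`, evaluating the illumination curve without
#' expansion. `S_n = 1` wherever the object vanishes in a neighbourhood.
#'
#' @param t_map A [thickness_map()] carrying a material.
#' @param geometry An [ei_geometry()].
#' @param curve An `ei_curve` (required in `"exact-curve"` mode; used in
#'   `"linearized"` mode only through the working point).
#' @param working_point An `ei_working_point` on an edge branch.
#' @param mode `"linearized"` (default) or `"exact-curve"`.
#' @return An [ei_image()] with provenance metadata.
#' @export
simulate_mixed_image <- function(t_map, geometry, curve = NULL, working_point,
                                 mode = c("linearized", "exact-curve")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t_map, "thickness_map"), inherits(geometry, "ei_geometry"),
            inherits(working_point, "ei_working_point"))
  m <- .require_material(t_map)
  k <- xray_wavenumber(m$energy_keV)
  z <- geometry$z_od
  tr <- transmission(t_map)
  phi <- phase_shift(t_map)
  dth <- refraction_angle_y(phi)$values
  hx <- geometry$step_x * 1e-6
  tie <- -(z / k) * deriv1(tr * deriv1(phi$values, hx, dim = 2L), hx, dim = 2L)
  if (mode == "linearized") {
    if (working_point$C1 == 0)
      stop_field("working point has zero slope: no refraction sensitivity in linearized mode")
    sy <- tr + z * (working_point$C1 * 1e6 / working_point$C0) * tr * dth
  } else {
    if (is.null(curve)) stop_field("exact-curve mode needs the illumination curve")
    shift_um <- z * dth * 1e6
    ye <- working_point$y_e + shift_um
    sup <- curve_support(curve)
    if (any(ye < sup[1] | ye > sup[2]))
      stop_field("refraction shift (max %.3g um) drives the edge outside the curve's tabulated support",
                 max(abs(shift_um)))
    cy <- matrix(curve_eval(curve, as.vector(ye)), nrow(ye), ncol(ye))
    sy <- tr * cy / working_point$C0
  }
  s <- lsf_convolve_x(sy + tie, geometry$step_x, geometry$lsf_fwhm_x)
  ei_image(s, t_map$step_y, t_map$step_x,
           meta = list(geometry = unclass(geometry),
                       working_point = unclass(working_point),
                       material = unclass(m), mode = mode))
}

#' Spectral evaluation of the compact single-material forward model
#'
#' Evaluates the regrouped form of the mixed signal,
#' `S_n = [ exp(-mu t) + (z delta / mu)(C'/C0) d/dy exp(-mu t)
#'          - (z delta / mu) d2/dx2 exp(-mu t) ] (x) LSF_x`,
#' entirely in the Fourier domain on the periodic (unpadded) grid, i.e.
#' `F(S_n) = D F(exp(-mu t))` with the same denominator `D` the retrieval
#' divides by. With `stencil = "fourier"` (true `i xi` derivative
#' multipliers) this simulator is the exact forward counterpart of
#' [retrieve_thickness()] with `pad = "none"`; with `stencil = "central"`
#' the DFT symbols of the central-difference stencils are used instead,
#' cross-validating the spatial-domain simulator.
#'
#' @inheritParams simulate_mixed_image
#' @param stencil `"fourier"` (default) or `"central"`.
#' @return An [ei_image()].
#' @export
simulate_mixed_spectral <- function(t_map, geometry, working_point,
                                    stencil = c("fourier", "central")) {
  stencil <- match.arg(stencil)
  stopifnot(inherits(t_map, "thickness_map"), inherits(geometry, "ei_geometry"),
            inherits(working_point, "ei_working_point"))
  m <- .require_material(t_map)
  mu <- attenuation_coefficient(m)
  amp <- geometry$z_od * m$delta / mu
  flt <- build_retrieval_filter(dim(t_map$values), t_map$step_y, t_map$step_x,
                                A = amp,
                                slope_ratio = working_point$C1 / working_point$C0,
                                lsf_fwhm_x = geometry$lsf_fwhm_x,
                                stencil = stencil)
  g <- exp(-mu * t_map$values * 1e-6)
  s <- Re(ifft2(flt$D * stats::fft(g)))
  ei_image(s, t_map$step_y, t_map$step_x,
           meta = list(geometry = unclass(geometry),
                       working_point = unclass(working_point),
                       material = unclass(m), mode = "spectral",
                       stencil = stencil))
}

#' Check the validity of the first-order illumination-curve expansion
#'
#' The linearized model assumes the refraction beam shift `z dtheta_y` is
#' small compared with the width of the illumination curve. Reports the
#' maximum shift and its ratio to the curve FWHM, warning above
#' `warn_ratio`.
#'
#' @inheritParams simulate_mixed_image
#' @param warn_ratio Warning threshold on shift / FWHM (default 0.2).
#' @return A list with `max_shift_um`, `curve_fwhm_um` and `ratio`
#'   (`NA` when the curve has no finite FWHM).
#' @export
taylor_validity_check <- function(t_map, geometry, curve, working_point,
                                  warn_ratio = 0.2) {
  stopifnot(inherits(t_map, "thickness_map"), inherits(curve, "ei_curve"))
  m <- .require_material(t_map)
  dth <- refraction_angle_y(phase_shift(t_map))$values
  max_shift <- max(abs(geometry$z_od * dth)) * 1e6
  fwhm <- curve_fwhm(curve)
  ratio <- if (is.na(fwhm)) NA_real_ else max_shift / fwhm
  if (!is.na(ratio) && ratio > warn_ratio)
    warning(sprintf("refraction beam shift is %.3g of the illumination-curve FWHM (> %g): the first-order expansion is questionable",
                    ratio, warn_ratio), call. = FALSE)
  list(max_shift_um = max_shift, curve_fwhm_um = fwhm, ratio = ratio)
}
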