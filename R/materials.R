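#' Physical constants used throughout the package
#'
#' CODATA values for the classical electron radius and the photon
#' energy--wavelength product. All internal computations are carried out in
#' SI units (metres, 1/m); public interfaces accept keV, micrometres and
#' metres as documented per field and convert at the boundary.
#'
#' @return A list with `r_e` (classical electron radius, m) and `hc`
#'   (photon energy times wavelength, keV nm).
#' @export
#' @examples
#' ei_constants()$r_e
ei_constants <- function() {
  list(r_e = 2.8179403e-15, hc = 1.23984193)
}

#' X-ray wavenumber
#'
#' `k = 2 pi E / (hc)` for photon energy `E` in keV.
#'
#' @param energy_keV Photon energy in keV (> 0).
#' @return Wavenumber in 1/m.
#' @export
#' @examples
#' xray_wavenumber(27) # ~1.368e11 1/m
xray_wavenumber <- function(energy_keV) {
  check_scalar(energy_keV, "energy_keV", positive = TRUE)
  2 * pi * energy_keV / (ei_constants()$hc * 1e-9)
}

#' X-ray wavelength
#'
#' @param energy_keV Photon energy in keV (> 0).
#' @return Wavelength in metres.
#' @export
xray_wavelength <- function(energy_keV) {
  check_scalar(energy_keV, "energy_keV", positive = TRUE)
  ei_constants()$hc * 1e-9 / energy_keV
}

#' Define a material by its complex refractive index
#'
#' The refractive index is `n = 1 - delta + i beta`; `delta` drives the
#' phase shift and `beta` the attenuation (`mu = 2 k beta`). Values are
#' taken from standard tabulations at the stated energy. `delta = 0` is
#' admitted as the degenerate pure-attenuation material.
#'
#' @param name Material name.
#' @param delta Refractive index decrement (dimensionless, >= 0).
#' @param beta Imaginary part of the refractive index (dimensionless, > 0).
#' @param energy_keV Photon energy (keV) at which `delta`, `beta` hold.
#' @return An object of class `ei_material`.
#' @export
#' @examples
#' pet <- ei_material("PET", delta = 4.09e-7, beta = 7.83e-11, energy_keV = 27)
ei_material <- function(name, delta, beta, energy_keV) {
  if (!is.character(name) || length(name) != 1L)
    stop_field("`name` must be a single string")
  check_scalar(delta, "delta", nonneg = TRUE)
  check_scalar(beta, "beta", positive = TRUE)
  check_scalar(energy_keV, "energy_keV", positive = TRUE)
  if (!is.finite(delta / beta))
    stop_field("delta/beta must be finite")
  structure(list(name = name, delta = delta, beta = beta,
                 energy_keV = energy_keV),
            class = "ei_material")
}

#' @export
print.ei_material <- function(x, ...) {
  cat(sprintf("<ei_material> %s at %g keV: delta = %g, beta = %g (delta/beta = %.4g)\n",
              x$name, x$energy_keV, x$delta, x$beta, x$delta / x$beta))
  invisible(x)
}

#' Beam and detector geometry of an edge-illumination setup
#'
#' @param energy_keV Photon energy (keV).
#' @param z_od Object-to-detector distance in metres (> 0).
#' @param step_y Sampling step along the scan direction y, in micrometres.
#' @param step_x Pixel size along x (parallel to the slits), in micrometres.
#' @param lsf_fwhm_x FWHM of the system line spread function along x, in
#'   micrometres (>= 0; 0 disables the blur). In EI the y direction is not
#'   blurred: source blur is carried by the illumination curve and the
#'   detector point spread function does not affect the y signal.
#' @return An object of class `ei_geometry`.
#' @export
ei_geometry <- function(energy_keV, z_od, step_y, step_x, lsf_fwhm_x = 0) {
  check_scalar(energy_keV, "energy_keV", positive = TRUE)
  check_scalar(z_od, "z_od", positive = TRUE)
  check_scalar(step_y, "step_y", positive = TRUE)
  check_scalar(step_x, "step_x", positive = TRUE)
  check_scalar(lsf_fwhm_x, "lsf_fwhm_x", nonneg = TRUE)
  structure(list(energy_keV = energy_keV, z_od = z_od, step_y = step_y,
                 step_x = step_x, lsf_fwhm_x = lsf_fwhm_x),
            class = "ei_geometry")
}

#' @export
print.ei_geometry <- function(x, ...) {
  cat(sprintf("<ei_geometry> %g keV, z = %g m, steps (y, x) = (%g, %g) um, LSF_x FWHM = %g um\n",
              x$energy_keV, x$z_od, x$step_y, x$step_x, x$lsf_fwhm_x))
  invisible(x)
}

#' Linear attenuation coefficient
#'
#' `mu = 2 k beta` at the material's energy.
#'
#' @param material An [ei_material()].
#' @return Attenuation coefficient in 1/m.
#' @export
#' @examples
#' attenuation_coefficient(ei_material("PET", 4.09e-7, 7.83e-11, 27)) # ~21.4
attenuation_coefficient <- function(material) {
  stopifnot(inherits(material, "ei_material"))
  2 * xray_wavenumber(material$energy_keV) * material$beta
}

#' Projected electron density scale factor
#'
#' The line integral of `delta` relates to the projected electron density
#' by `int delta dz = sigma * rho_ep` with `sigma = r_e lambda^2 / (2 pi)`.
#' For a single-material object `rho_ep = delta * t / sigma`.
#'
#' @param energy_keV Photon energy in keV (> 0).
#' @return `sigma` in m^3 (per unit projected electron density in 1/m^2).
#' @export
electron_density_scale <- function(energy_keV) {
  lambda <- xray_wavelength(energy_keV)
  ei_constants()$r_e * lambda^2 / (2 * pi)
}

#' Reference materials table
#'
#' The four tabulated optical constants used in the worked examples: PET
#' and PEEK at 27 keV, water at 9.7 keV, shipped as a plain-text table.
#'
#' @param name Optional material name to look up (case-insensitive). When
#'   given with `energy_keV`, selects the matching row and returns an
#'   [ei_material()].
#' @param energy_keV Optional energy filter for the lookup.
#' @return A data frame of all rows, or an `ei_material` when `name` is
#'   given.
#' @export
#' @examples
#' ei_materials()
#' ei_materials("PET")
ei_materials <- function(name = NULL, energy_keV = NULL) {
  path <- system.file("extdata", "materials.csv", package = "eiphase",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(name)) return(tab)
  hit <- tolower(tab$name) == tolower(name)
  if (!is.null(energy_keV)) hit <- hit & tab$energy_keV == energy_keV
  if (!any(hit)) stop_field("material '%s' not found in the bundled table", name)
  row <- tab[which(hit)[1L], ]
  ei_material(row$name, row$delta, row$beta, row$energy_keV)
}
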