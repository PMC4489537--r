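# End-to-end simulate-then-retrieve parameter recovery on a cylindrical
# wire: the synchrotron wire-phantom benchmark (27 keV, slit apertures
# 20/250 um, object-to-detector distance 3.85 m, 50% illumination, 20 um
# scan step, 46 um pixels).

#' Default beam geometry of the wire benchmark
#' @return An [ei_geometry()]: 27 keV, z = 3.85 m, 20 um scan step, 46 um
#'   pixels, 46 um LSF FWHM along x.
#' @export
wire_benchmark_geometry <- function() ei_geometry(27, 3.85, 20, 46, lsf_fwhm_x = 46)

#' Default illumination curve of the wire benchmark
#'
#' Analytic model of the slit system: 20 um pre-sample aperture, 250 um
#' detector aperture, 0.28 um Gaussian source blur (24 um FWHM vertical
#' source projected over 3.85 m from 140 m away).
#' @return An `ei_curve`.
#' @export
wire_benchmark_curve <- function() ei_curve_analytic(a1 = 20, a2 = 250,
                                                     sigma_src = 0.28)

#' Default geometry of the petal-like benchmark
#'
#' Conditions of the high-resolution virtual-edge configuration used for
#' complex biological samples: 9.7 keV, 0.30 m propagation, 1.6 um
#' sampling in both directions, 1.6 um LSF FWHM along x.
#' @return An [ei_geometry()].
#' @export
petal_benchmark_geometry <- function() ei_geometry(9.7, 0.30, 1.6, 1.6,
                                                   lsf_fwhm_x = 1.6)

#' Default illumination curve of the petal-like benchmark
#'
#' Single-edge (virtual edge on a high-resolution detector) model: 3 um
#' pre-sample aperture, semi-infinite detector aperture, 0.5 um source
#' blur.
#' @return An `ei_curve`.
#' @export
petal_benchmark_curve <- function() ei_curve_analytic(a1 = 3, a2 = Inf,
                                                      sigma_src = 0.5)

#' Simulate and retrieve a cylindrical wire end to end
#'
#' Builds the chord-function thickness map of a horizontal wire, simulates
#' the noiseless (or Poisson-noisy) normalized mixed EI image with the
#' linearized forward model, retrieves the thickness with the single-image
#' Fourier filter using the same material constants, and reports the peak
#' of the vertical profile through the wire centre — which should recover
#' the nominal diameter.
#'
#' @param material An [ei_material()] (its energy must match the geometry).
#' @param diameter Nominal wire diameter, micrometres.
#' @param geometry An [ei_geometry()].
#' @param curve An `ei_curve`.
#' @param fraction Working-point illumination fraction (default 0.5).
#' @param shape `c(ny, nx)` simulation grid.
#' @param mode Forward-model mode, `"linearized"` or `"exact-curve"`.
#' @param photons Optional photons per pixel for Poisson noise (`NULL` for
#'   a noiseless run).
#' @param seed Seed for the noise draw (ignored when `photons` is `NULL`).
#' @return A list: `peak_um` (profile maximum), `thickness` (retrieved
#'   map), `truth`, `image`, `working_point`, `comparison`
#'   (an `ei_comparison`), and `profile` (data frame).
#' @export
#' @examples
#' \donttest{
#' res <- wire_recovery_experiment(ei_materials("PET"), 500)
#' res$peak_um # ~500
#' }
wire_recovery_experiment <- function(material, diameter,
                                     geometry = wire_benchmark_geometry(),
                                     curve = wire_benchmark_curve(),
                                     fraction = 0.5, shape = c(256L, 64L),
                                     mode = "linearized", photons = NULL,
                                     seed = 1L) {
  stopifnot(inherits(material, "ei_material"))
  if (material$energy_keV != geometry$energy_keV)
    warning("material and geometry energies differ; using the material's constants",
            call. = FALSE)
  truth <- phantom_cylinder_wire(diameter, shape = shape,
                                 step_y = geometry$step_y,
                                 step_x = geometry$step_x, material = material)
  wp <- working_point(curve, fraction, "lower")
  img <- simulate_mixed_image(truth, geometry, curve, wp, mode = mode)
  if (!is.null(photons)) img <- add_poisson_noise(img, photons, seed)
  t_ret <- retrieve_thickness(img, material, geometry, wp)
  cmp <- compare_maps(t_ret, truth)
  list(peak_um = max(cmp$profile$retrieved), thickness = t_ret, truth = truth,
       image = img, working_point = wp, comparison = cmp,
       profile = cmp$profile)
}
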