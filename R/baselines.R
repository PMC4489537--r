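# The classical two-image EI retrieval and the 1D-integration route to a
# thickness map — the baseline the single-image filter is compared against —
# plus quantitative comparison metrics (RMSE, streak index, profiles).

.as_values <- function(x) {
  if (is.matrix(x)) x
  else if (is.list(x) && is.matrix(x$values)) x$values
  else stop_field("expected a matrix or a map object with a `values` matrix")
}

#' Two-image retrieval of transmission and refraction
#'
#' Inverts the linearized EI signal model from two images acquired at
#' symmetric working points on opposite edges of the illumination curve
#' (equal `C0`, slopes of opposite sign):
#' `T = (S+ + S-) / 2` and
#' `dtheta_y = (C0 / (z C')) (S+ - S-) / (S+ + S-)`.
#' Exact at the level of the linearized simulator for objects uniform
#' along x; under noise it inherits the full per-pixel variance that the
#' single-image method filters out.
#'
#' @param s_plus,s_minus [ei_image()]s acquired at `wp_plus` / `wp_minus`.
#' @param wp_plus,wp_minus Working points with equal `C0` and opposite
#'   `C1` (checked to 1e-6 relative).
#' @param geometry An [ei_geometry()] (provides `z_od`).
#' @param eps Lower clamp on the sum image before division (guards
#'   zero-count pixels under Poisson noise).
#' @return A list with `transmission` (matrix) and `refraction` (a
#'   `refraction_map`, radians).
#' @export
two_image_retrieval <- function(s_plus, s_minus, wp_plus, wp_minus, geometry,
                                eps = 1e-8) {
  stopifnot(inherits(s_plus, "ei_image"), inherits(s_minus, "ei_image"),
            inherits(geometry, "ei_geometry"))
  .check_wp_slope(wp_plus); .check_wp_slope(wp_minus)
  if (!all(dim(s_plus$values) == dim(s_minus$values)))
    stop_field("the two images must share a grid")
  c0 <- wp_plus$C0
  if (abs(wp_plus$C0 - wp_minus$C0) > 1e-6 * max(c0, wp_minus$C0))
    stop_field("working points are not symmetric: C0 differ (%g vs %g)",
               wp_plus$C0, wp_minus$C0)
  if (abs(wp_plus$C1 + wp_minus$C1) > 1e-6 * abs(wp_plus$C1))
    stop_field("working points are not symmetric: slopes are not opposite (%g vs %g)",
               wp_plus$C1, wp_minus$C1)
  ssum <- s_plus$values + s_minus$values
  tr <- ssum / 2
  c1_m <- wp_plus$C1 * 1e6
  dth <- (c0 / (geometry$z_od * c1_m)) *
    (s_plus$values - s_minus$values) / pmax(ssum, eps)
  list(transmission = tr,
       refraction = structure(list(values = dth, step_y = s_plus$step_y,
                                   step_x = s_plus$step_x,
                                   energy_keV = geometry$energy_keV),
                              class = "refraction_map"))
}

#' Integrate a refraction image into a thickness map
#'
#' One-dimensional cumulative (trapezoidal) integration of
#' `dtheta_y = -delta dt/dy` along the scan direction,
#' `t(x, y) = -(1/delta) int_0^y dtheta_y dy'`, anchored at zero thickness
#' on the first row (the frame edge must lie outside the object). Noise in
#' the refraction image accumulates as an independent random walk per
#' column, producing the characteristic vertical streak artefacts.
#'
#' @param refraction_map A `refraction_map` (radians).
#' @param material An [ei_material()] supplying `delta` (> 0), or a bare
#'   positive number taken as `delta`.
#' @return A thickness map (micrometres); being an estimate it may go
#'   negative under noise.
#' @export
integrate_refraction <- function(refraction_map, material) {
  stopifnot(inherits(refraction_map, "refraction_map"))
  delta <- if (inherits(material, "ei_material")) material$delta else material
  check_scalar(delta, "delta", positive = TRUE)
  v <- refraction_map$values
  ny <- nrow(v); h <- refraction_map$step_y
  if (ny < 3L) stop_field("need at least 3 rows to integrate")
  # cumulative sum matched to the derivative stencils of the forward model
  # (one-sided at the first row, central elsewhere), i.e. their exact
  # discrete inverse: two interleaved chains t[j] = t[j-2] + 2h d[j-1]
  d <- -v / delta                       # dt/dy samples, t units per um
  t <- matrix(0, ny, ncol(v))
  t[2, ] <- h * d[1, ]                  # one-sided first-row derivative
  for (j in 3:ny) t[j, ] <- t[j - 2, ] + 2 * h * d[j - 1, ]
  new_thickness_map(t, refraction_map$step_y, refraction_map$step_x,
                    if (inherits(material, "ei_material")) material else NULL)
}

#' Streak index of a residual map
#'
#' `Var_x( mean_y(residual) ) / Var_{x,y}(residual)` (population
#' variances): close to 1 when the error is constant along each column
#' (pure vertical streaks), about `1/N_y` for i.i.d. noise, and 0 for a
#' constant (or zero) residual.
#'
#' @param residual Matrix (retrieved minus ground truth), rows = y.
#' @return Scalar in `[0, 1]`.
#' @export
streak_index <- function(residual) {
  r <- .as_values(residual)
  pvar <- function(x) mean((x - mean(x))^2)
  tot <- pvar(as.vector(r))
  if (tot == 0) return(0)
  pvar(colMeans(r)) / tot
}

#' Root-mean-square error between two maps
#' @param map,truth Matrices or map objects of identical shape.
#' @return Scalar RMSE in the maps' units.
#' @export
rmse_map <- function(map, truth) {
  a <- .as_values(map); b <- .as_values(truth)
  if (!all(dim(a) == dim(b))) stop_field("shape mismatch: %dx%d vs %dx%d",
                                         nrow(a), ncol(a), nrow(b), ncol(b))
  sqrt(mean((a - b)^2))
}

#' Extract a 1D profile from a map
#'
#' @param map Matrix or map object (with `step_y`, `step_x` when a map).
#' @param axis `"vertical"` (along y at fixed x, the default — the
#'   direction of the wire profiles) or `"horizontal"`.
#' @param coordinate Position along the other axis in micrometres (map
#'   objects) or as an index (matrices); defaults to the centre.
#' @return A data frame with `position_um` and `value`.
#' @export
extract_profile <- function(map, axis = c("vertical", "horizontal"),
                            coordinate = NULL) {
  axis <- match.arg(axis)
  v <- .as_values(map)
  is_map <- is.list(map) && !is.null(map$step_y)
  sy <- if (is_map) map$step_y else 1
  sx <- if (is_map) map$step_x else 1
  if (axis == "vertical") {
    j <- if (is.null(coordinate)) (ncol(v) + 1L) %/% 2L
         else if (is_map) round(coordinate / sx) + 1L else as.integer(coordinate)
    if (j < 1L || j > ncol(v)) stop_field("coordinate outside the map")
    data.frame(position_um = (seq_len(nrow(v)) - 1) * sy, value = v[, j])
  } else {
    i <- if (is.null(coordinate)) (nrow(v) + 1L) %/% 2L
         else if (is_map) round(coordinate / sy) + 1L else as.integer(coordinate)
    if (i < 1L || i > nrow(v)) stop_field("coordinate outside the map")
    data.frame(position_um = (seq_len(ncol(v)) - 1) * sx, value = v[i, ])
  }
}

#' Compare a retrieved map against its ground truth
#'
#' @param retrieved Map object or matrix (a `"retrieval_log"` attribute,
#'   if present, supplies the clipped fraction).
#' @param truth Ground-truth map or matrix of the same shape.
#' @param profile_at Optional x coordinate (micrometres) for the vertical
#'   profile pair; defaults to the column containing the truth maximum.
#' @return An object of class `ei_comparison`: `rmse`, `streak_index`,
#'   `clipped_fraction`, and a `profile` data frame (position, retrieved,
#'   expected).
#' @export
compare_maps <- function(retrieved, truth, profile_at = NULL) {
  a <- .as_values(retrieved); b <- .as_values(truth)
  if (!all(dim(a) == dim(b))) stop_field("shape mismatch between retrieved and truth")
  res <- a - b
  lg <- attr(retrieved, "retrieval_log")
  if (is.null(profile_at)) {
    j <- ((which.max(b) - 1L) %/% nrow(b)) + 1L
    sx <- if (is.list(truth) && !is.null(truth$step_x)) truth$step_x else 1
    profile_at <- (j - 1L) * sx
  }
  pr <- extract_profile(retrieved, "vertical", profile_at)
  pe <- extract_profile(truth, "vertical", profile_at)
  structure(list(rmse = rmse_map(a, b),
                 streak_index = streak_index(res),
                 clipped_fraction = if (is.null(lg)) 0 else lg$clipped_fraction,
                 profile = data.frame(position_um = pr$position_um,
                                      retrieved = pr$value,
                                      expected = pe$value)),
            class = "ei_comparison")
}

#' @export
print.ei_comparison <- function(x, ...) {
  cat(sprintf("<ei_comparison> rmse = %.6g, streak_index = %.4g, clipped_fraction = %.4g\n",
              x$rmse, x$streak_index, x$clipped_fraction))
  invisible(x)
}
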