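# Synthetic phantoms with known ground truth, and Poisson noise injection.
# All generators are pure functions of their arguments (plus an explicit
# seed); grids have rows indexed by y (the scan direction) and columns by x.

#' Projected thickness map
#'
#' @param values Matrix of projected thickness t(x, y) in micrometres,
#'   rows = y, columns = x; all values finite and >= 0.
#' @param step_y,step_x Grid spacing in micrometres.
#' @param material Optional [ei_material()] the object is made of.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(values, step_y, step_x, material = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("`values` must be a numeric matrix")
  if (any(!is.finite(values))) stop_field("thickness values must be finite")
  if (any(values < 0)) stop_field("thickness values must be >= 0")
  check_scalar(step_y, "step_y", positive = TRUE)
  check_scalar(step_x, "step_x", positive = TRUE)
  if (!is.null(material)) stopifnot(inherits(material, "ei_material"))
  structure(list(values = values, step_y = step_y, step_x = step_x,
                 material = material),
            class = "thickness_map")
}

# Unvalidated variant for *estimated* thickness maps (retrieval,
# integration baselines), which may legitimately dip below zero under
# noise or ringing. Ground-truth constructors always go through
# thickness_map() and its invariants.
new_thickness_map <- function(values, step_y, step_x, material = NULL) {
  structure(list(values = values, step_y = step_y, step_x = step_x,
                 material = material),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d x %d (y by x), steps (%g, %g) um, t in [%g, %g] um%s\n",
              nrow(x$values), ncol(x$values), x$step_y, x$step_x,
              min(x$values), max(x$values),
              if (is.null(x$material)) "" else paste0(", material ", x$material$name)))
  invisible(x)
}

#' Normalized edge-illumination image
#'
#' Container for the normalized mixed signal S_n(x, y), the single
#' measured input of the retrieval.
#'
#' @param values Numeric matrix (rows = y, columns = x), finite.
#' @param step_y,step_x Grid spacing in micrometres.
#' @param meta Named list of provenance metadata (geometry, working point,
#'   noise settings, ...).
#' @return An object of class `ei_image`.
#' @export
ei_image <- function(values, step_y, step_x, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("`values` must be a numeric matrix")
  if (any(!is.finite(values))) stop_field("image values must be finite")
  check_scalar(step_y, "step_y", positive = TRUE)
  check_scalar(step_x, "step_x", positive = TRUE)
  structure(list(values = values, step_y = step_y, step_x = step_x,
                 meta = meta),
            class = "ei_image")
}

#' @export
print.ei_image <- function(x, ...) {
  cat(sprintf("<ei_image> %d x %d (y by x), steps (%g, %g) um, S_n in [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$step_y, x$step_x,
              min(x$values), max(x$values)))
  invisible(x)
}

.grid_coords <- function(shape, step_y, step_x) {
  list(y = (seq_len(shape[1]) - 1) * step_y,
       x = (seq_len(shape[2]) - 1) * step_x)
}

#' Cylindrical wire phantom
#'
#' A perfect cylinder with its axis along x (horizontal wire, perpendicular
#' to the scan direction y), so the projected thickness is the chord
#' function `t(y) = 2 sqrt((d/2)^2 - (y - c)^2)` inside the wire and 0
#' outside.
#'
#' @param diameter Wire diameter in micrometres (> step_y: thinner wires are
#'   unresolvable on the grid).
#' @param center_y Wire axis position in micrometres (row coordinate
#'   `(i - 1) * step_y`); defaults to the field centre snapped to the grid.
#' @param shape `c(ny, nx)` grid size.
#' @param step_y,step_x Grid spacing, micrometres.
#' @param material Optional [ei_material()].
#' @param supersample Integer >= 1; when > 1, each pixel value is the
#'   average of `supersample` sub-samples across the pixel in y
#'   (anti-aliasing off by default: pixel-centre sampling).
#' @return A [thickness_map()].
#' @export
phantom_cylinder_wire <- function(diameter, center_y = NULL, shape = c(256L, 64L),
                                  step_y = 20, step_x = 46, material = NULL,
                                  supersample = 1L) {
  check_scalar(diameter, "diameter", positive = TRUE)
  if (diameter < step_y)
    stop_field("diameter (%g um) smaller than one grid step (%g um): unresolvable",
               diameter, step_y)
  if (is.null(center_y))
    center_y <- floor((shape[1] - 1) / 2) * step_y
  supersample <- as.integer(supersample)
  stopifnot(supersample >= 1L)
  g <- .grid_coords(shape, step_y, step_x)
  chord <- function(y) {
    u2 <- (diameter / 2)^2 - (y - center_y)^2
    ifelse(u2 > 0, 2 * sqrt(pmax(u2, 0)), 0)
  }
  if (supersample == 1L) {
    prof <- chord(g$y)
  } else {
    off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample * step_y
    prof <- rowMeans(vapply(off, function(o) chord(g$y + o),
                            numeric(length(g$y))))
  }
  thickness_map(matrix(prof, nrow = shape[1], ncol = shape[2]),
                step_y, step_x, material)
}

#' Uniform slab phantom
#' @param thickness Constant thickness, micrometres (>= 0).
#' @inheritParams phantom_cylinder_wire
#' @return A [thickness_map()].
#' @export
phantom_slab <- function(thickness, shape = c(256L, 64L), step_y = 20,
                         step_x = 46, material = NULL) {
  check_scalar(thickness, "thickness", nonneg = TRUE)
  thickness_map(matrix(thickness, shape[1], shape[2]), step_y, step_x, material)
}

#' Sphere phantom
#' @param diameter Sphere diameter, micrometres.
#' @param center `c(y, x)` centre in micrometres; defaults to the field centre.
#' @inheritParams phantom_cylinder_wire
#' @return A [thickness_map()] with `t = 2 sqrt(r^2 - rho^2)` radially.
#' @export
phantom_sphere <- function(diameter, center = NULL, shape = c(256L, 64L),
                           step_y = 20, step_x = 46, material = NULL) {
  check_scalar(diameter, "diameter", positive = TRUE)
  g <- .grid_coords(shape, step_y, step_x)
  if (is.null(center)) center <- c(mean(range(g$y)), mean(range(g$x)))
  rho2 <- outer((g$y - center[1])^2, (g$x - center[2])^2, `+`)
  r2 <- (diameter / 2)^2
  vals <- ifelse(rho2 < r2, 2 * sqrt(pmax(r2 - rho2, 0)), 0)
  thickness_map(vals, step_y, step_x, material)
}

#' Wedge phantom (linear thickness ramp)
#' @param t_min,t_max Thickness at the two ends of the ramp, micrometres
#'   (both >= 0).
#' @param axis `"y"` (ramp along rows, default) or `"x"`.
#' @inheritParams phantom_cylinder_wire
#' @return A [thickness_map()].
#' @export
phantom_wedge <- function(t_min, t_max, axis = c("y", "x"),
                          shape = c(256L, 64L), step_y = 20, step_x = 46,
                          material = NULL) {
  axis <- match.arg(axis)
  check_scalar(t_min, "t_min", nonneg = TRUE)
  check_scalar(t_max, "t_max", nonneg = TRUE)
  n <- if (axis == "y") shape[1] else shape[2]
  ramp <- seq(t_min, t_max, length.out = n)
  vals <- if (axis == "y") matrix(ramp, shape[1], shape[2])
          else matrix(ramp, shape[1], shape[2], byrow = TRUE)
  thickness_map(vals, step_y, step_x, material)
}

#' Textured phantom: blobs over a structured background
#'
#' A qualitative stand-in for a botanical sample: smooth elliptical
#' super-Gaussian blobs (pollen-grain-like) superimposed on a low-amplitude
#' slowly varying background membrane containing small low-thickness spots
#' (cell-like). Deterministic for a fixed seed.
#'
#' @param seed Integer seed (required; the generator has no hidden state).
#' @param n_blobs Number of elliptical blobs (>= 0).
#' @param blob_scale Typical blob semi-axis, micrometres.
#' @param background Mean background membrane thickness, micrometres
#'   (0 disables the background).
#' @param amplitude Peak blob thickness, micrometres.
#' @param n_spots Number of low-thickness spots carved into the background.
#' @param t_max Upper clamp on the thickness, micrometres.
#' @inheritParams phantom_cylinder_wire
#' @return A [thickness_map()] with values in `[0, t_max]`.
#' @export
phantom_textured <- function(seed, n_blobs = 10L, blob_scale = 20,
                             background = 8, amplitude = 20, n_spots = 20L,
                             t_max = 60, shape = c(192L, 192L), step_y = 1.6,
                             step_x = 1.6, material = NULL) {
  check_scalar(blob_scale, "blob_scale", positive = TRUE)
  check_scalar(background, "background", nonneg = TRUE)
  check_scalar(amplitude, "amplitude", nonneg = TRUE)
  check_scalar(t_max, "t_max", positive = TRUE)
  stopifnot(n_blobs >= 0, n_spots >= 0)
  g <- .grid_coords(shape, step_y, step_x)
  ly <- max(g$y); lx <- max(g$x)
  vals <- with_local_seed(seed, {
    t <- matrix(0, shape[1], shape[2])
    if (background > 0) {
      # slowly varying membrane: a few very broad bumps, rescaled so the
      # mean equals `background`
      mod <- matrix(0, shape[1], shape[2])
      for (i in 1:4) {
        cy <- stats::runif(1, 0, ly); cx <- stats::runif(1, 0, lx)
        sy <- stats::runif(1, 0.3, 0.8) * ly; sx <- stats::runif(1, 0.3, 0.8) * lx
        mod <- mod + stats::runif(1, 0.5, 1) *
          exp(-(outer((g$y - cy)^2 / (2 * sy^2), (g$x - cx)^2 / (2 * sx^2), `+`)))
      }
      bg <- mod / mean(mod) * background
      # cell-like low-thickness spots carved into the membrane
      for (i in seq_len(n_spots)) {
        cy <- stats::runif(1, 0, ly); cx <- stats::runif(1, 0, lx)
        r <- blob_scale * stats::runif(1, 0.2, 0.45)
        depth <- stats::runif(1, 0.3, 0.6)
        q <- outer((g$y - cy)^2, (g$x - cx)^2, `+`) / r^2
        bg <- bg * (1 - depth * exp(-q^1.5))
      }
      t <- t + bg
    }
    for (i in seq_len(n_blobs)) {
      cy <- stats::runif(1, 0.1, 0.9) * ly
      cx <- stats::runif(1, 0.1, 0.9) * lx
      r1 <- blob_scale * stats::runif(1, 0.7, 1.3)
      r2 <- blob_scale * stats::runif(1, 0.7, 1.3)
      th <- stats::runif(1, 0, pi)
      amp <- amplitude * stats::runif(1, 0.5, 1)
      dy <- outer(g$y - cy, rep(1, shape[2]))
      dx <- outer(rep(1, shape[1]), g$x - cx)
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      q <- (u / r1)^2 + (v / r2)^2
      # super-Gaussian: flat-topped, smooth-edged grains
      t <- t + amp * exp(-q^1.5)
    }
    t
  })
  thickness_map(pmin(pmax(vals, 0), t_max), step_y, step_x, material)
}

#' Add Poisson counting noise to a normalized image
#'
#' Scales the normalized image to expected counts (`photons_per_pixel *
#' S_n`), draws Poisson counts per pixel and scales back, so the expected
#' value of the output equals the input. With ~10 photons per pixel the
#' relative standard deviation on a unit image is ~1/sqrt(10) = 32%.
#'
#' @param image An [ei_image()] (or plain numeric matrix) with values >= 0.
#' @param photons_per_pixel Mean photon count on a unit signal (> 0).
#' @param seed Integer seed; the draw is reproducible and leaves the
#'   caller's RNG state untouched.
#' @return Same type as `image`, with noisy values.
#' @export
add_poisson_noise <- function(image, photons_per_pixel, seed) {
  check_scalar(photons_per_pixel, "photons_per_pixel", positive = TRUE)
  vals <- if (inherits(image, "ei_image")) image$values else image
  if (!is.numeric(vals)) stop_field("`image` must be numeric")
  if (any(vals < 0))
    stop_field("Poisson noise requires non-negative image values (min = %g); the linearized signal went negative",
               min(vals))
  noisy <- with_local_seed(seed, {
    matrix(stats::rpois(length(vals), lambda = photons_per_pixel * vals),
           nrow(vals), ncol(vals)) / photons_per_pixel
  })
  if (inherits(image, "ei_image")) {
    meta <- image$meta
    meta$noise <- list(photons_per_pixel = photons_per_pixel, seed = seed)
    ei_image(noisy, image$step_y, image$step_x, meta)
  } else noisy
}
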