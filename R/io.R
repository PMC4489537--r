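# File formats: 32-bit float single-channel TIFF for images and maps (with
# grid spacing in the resolution tags, an ImageDescription JSON and a
# sidecar JSON file), two-column CSV for illumination curves and profiles,
# and a flat key = value run-configuration format.
#
# Reading goes through tiff::readTIFF. Writing uses a minimal uncompressed
# single-strip little-endian IEEE-float writer implemented here, because
# tiff::writeTIFF clamps data to [0, 1] and cannot store physical units
# (micrometres of thickness, electrons per square micrometre).

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.ifd_entry <- function(tag, type, count, value_raw4) {
  c(.u16(tag), .u16(type), .u32(count), value_raw4)
}

.short_val <- function(x) c(.u16(x), .u16(0))

# Represent micrometre spacing as a pixels-per-centimetre RATIONAL.
.res_rational <- function(step_um) {
  den <- round(step_um * 1000)
  if (den <= 0 || den > 2^31 - 1) c(.u32(1), .u32(1))
  else c(.u32(10000000), .u32(den))
}

write_float_tiff <- function(m, path, step_y, step_x, description = "") {
  stopifnot(is.matrix(m), is.numeric(m))
  ny <- nrow(m); nx <- ncol(m)
  desc <- c(charToRaw(description), as.raw(0))  # NUL-terminated ASCII
  if (length(desc) %% 2 == 1) desc <- c(desc, as.raw(0))
  data_len <- ny * nx * 4
  off_desc <- 8 + data_len
  off_xres <- off_desc + length(desc)
  off_yres <- off_xres + 8
  off_ifd <- off_yres + 8
  entries <- list(
    .ifd_entry(256, 4, 1, .u32(nx)),            # ImageWidth
    .ifd_entry(257, 4, 1, .u32(ny)),            # ImageLength
    .ifd_entry(258, 3, 1, .short_val(32)),      # BitsPerSample
    .ifd_entry(259, 3, 1, .short_val(1)),       # Compression: none
    .ifd_entry(262, 3, 1, .short_val(1)),       # Photometric: black is zero
    .ifd_entry(270, 2, length(desc), .u32(off_desc)),  # ImageDescription
    .ifd_entry(273, 4, 1, .u32(8)),             # StripOffsets
    .ifd_entry(277, 3, 1, .short_val(1)),       # SamplesPerPixel
    .ifd_entry(278, 4, 1, .u32(ny)),            # RowsPerStrip
    .ifd_entry(279, 4, 1, .u32(data_len)),      # StripByteCounts
    .ifd_entry(282, 5, 1, .u32(off_xres)),      # XResolution
    .ifd_entry(283, 5, 1, .u32(off_yres)),      # YResolution
    .ifd_entry(296, 3, 1, .short_val(3)),       # ResolutionUnit: cm
    .ifd_entry(339, 3, 1, .short_val(3))        # SampleFormat: IEEE float
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16(42), .u32(off_ifd)), con)
  # pixel data, row-major as TIFF expects
  writeBin(as.double(t(m)), con, size = 4, endian = "little")
  writeBin(desc, con)
  writeBin(.res_rational(step_x), con)
  writeBin(.res_rational(step_y), con)
  writeBin(.u16(length(entries)), con)
  for (e in entries) writeBin(e, con)
  writeBin(.u32(0), con)
  invisible(path)
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write an image or map as a 32-bit float TIFF
#'
#' Values are stored as uncompressed IEEE floats (no clamping to the unit
#' interval).
#' The grid spacing is carried in the TIFF resolution tags, in an
#' ImageDescription JSON, and in a sidecar `<path>.json` together with any
#' provenance metadata (material, geometry, seed, ...).
#'
#' @param x An [ei_image()], [thickness_map()], `electron_density_map`, or
#'   a plain matrix (then `step_y`/`step_x` are required).
#' @param path Output file path.
#' @param step_y,step_x Grid spacing in micrometres (taken from `x` when
#'   it is a map object).
#' @param meta Extra named metadata merged into the sidecar.
#' @param sidecar Write the sidecar JSON (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_ei_image <- function(x, path, step_y = NULL, step_x = NULL,
                           meta = list(), sidecar = TRUE) {
  if (is.list(x) && !is.null(x$values)) {
    m <- x$values
    step_y <- x$step_y; step_x <- x$step_x
    if (inherits(x, "thickness_map") && !is.null(x$material))
      meta$material <- unclass(x$material)
    if (inherits(x, "ei_image")) meta <- utils::modifyList(x$meta, meta)
    meta$class <- class(x)[1]
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(step_y) || is.null(step_x))
      stop_field("step_y and step_x are required when writing a bare matrix")
  } else stop_field("don't know how to write an object of class '%s'", class(x)[1])
  desc <- jsonlite::toJSON(list(step_y_um = step_y, step_x_um = step_x),
                           auto_unbox = TRUE, digits = NA)
  write_float_tiff(m, path, step_y, step_x, description = as.character(desc))
  if (sidecar) {
    side <- utils::modifyList(list(step_y_um = step_y, step_x_um = step_x,
                                   shape = dim(m)), meta)
    jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a 32-bit float single-channel TIFF
#'
#' Grid spacing is recovered from the ImageDescription JSON, the sidecar
#' file, or the resolution tags, in that order. Multi-channel or integer
#' TIFFs are rejected with a conversion hint.
#'
#' @param path Path to the TIFF file.
#' @return An [ei_image()]; the sidecar metadata (if any) is in `$meta`.
#' @export
read_ei_image <- function(path) {
  if (!file.exists(path)) stop_field("file not found: %s", path)
  v <- tiff::readTIFF(path, info = TRUE, all = FALSE)
  at <- attributes(v)
  if (length(dim(v)) > 2L && dim(v)[3] > 1L)
    stop_field("%s is a multi-channel TIFF (%d channels); convert it to a single-channel float image first",
               path, dim(v)[3])
  if (!identical(at$sample.format, "float"))
    stop_field("%s is not a float TIFF (sample format '%s'); convert it to 32-bit float first",
               path, at$sample.format %||% "integer")
  m <- matrix(as.numeric(v), nrow(v), ncol(v))
  step_y <- step_x <- NULL
  if (!is.null(at$description)) {
    d <- tryCatch(jsonlite::fromJSON(at$description), error = function(e) NULL)
    step_y <- d$step_y_um; step_x <- d$step_x_um
  }
  meta <- list()
  if (file.exists(.sidecar_path(path))) {
    meta <- jsonlite::fromJSON(.sidecar_path(path), simplifyVector = TRUE)
    if (is.null(step_y)) { step_y <- meta$step_y_um; step_x <- meta$step_x_um }
  }
  if (is.null(step_y)) {
    step_y <- if (!is.null(at$y.resolution) && at$y.resolution > 0)
      1e4 / at$y.resolution else 1
    step_x <- if (!is.null(at$x.resolution) && at$x.resolution > 0)
      1e4 / at$x.resolution else 1
  }
  ei_image(m, step_y, step_x, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tabulated illumination curve from CSV
#'
#' Expects a two-column numeric CSV (`y_e_um`, `C`) with a one-line
#' header. The abscissa must be strictly increasing and cells must be
#' numeric; violations are reported with their row number. The curve is
#' re-normalized to unit apex (with a warning when the raw apex is off by
#' more than 5%).
#'
#' @param path CSV file path.
#' @return An `ei_curve` of kind `"tabulated"`.
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop_field("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop_field("%s contains a header but no data rows", path)
  if (ncol(tab) < 2) stop_field("%s must have two columns (y_e_um, C)", path)
  y <- suppressWarnings(as.numeric(tab[[1]]))
  C <- suppressWarnings(as.numeric(tab[[2]]))
  bad <- which(!is.finite(y) | !is.finite(C))
  if (length(bad))
    stop_field("%s: non-numeric or missing cell in row %d", path, bad[1])
  nonmono <- which(diff(y) <= 0)
  if (length(nonmono))
    stop_field("%s: abscissa not strictly increasing at row %d", path,
               nonmono[1] + 1L)
  ei_curve_tabulated(y, C)
}

#' Write an illumination curve to CSV
#'
#' Tabulated curves are dumped on their grid; analytic curves are sampled
#' on `n` points covering the full transition region.
#'
#' @param curve An `ei_curve`.
#' @param path Output CSV path.
#' @param n Number of samples for analytic curves.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, n = 1001L) {
  stopifnot(inherits(curve, "ei_curve"))
  if (curve$kind == "tabulated") {
    y <- curve$y_e; C <- curve$C
  } else {
    span <- curve$a1 / 2 + 6 * curve$sigma_src + curve$a1
    hi <- if (is.finite(curve$a2)) curve$a2 + span else 3 * span
    y <- seq(-span, hi, length.out = n)
    C <- curve_eval(curve, y)
  }
  utils::write.csv(data.frame(y_e_um = y, C = C), path, row.names = FALSE)
  invisible(path)
}

#' Write a 1D profile to CSV
#' @param profile Data frame as returned by [extract_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(is.data.frame(profile))
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a flat key = value run configuration
#'
#' Every CLI run writes its fully resolved configuration next to its
#' outputs, so that re-running from that file (with equal seeds)
#' reproduces the outputs bit for bit.
#'
#' @param config Named list of scalar settings.
#' @param path File path.
#' @return `path` (write) or a named list with numeric strings converted
#'   (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), length(names(config)) == length(config))
  vals <- vapply(config, function(v)
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v), character(1))
  writeLines(paste(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_field("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) stop_field("malformed config line: %s", m[1])
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}
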