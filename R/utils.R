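# Internal numerical helpers shared by the forward model and the retrieval:
# discrete derivatives, mirror padding, FFT frequency grids, seeded RNG.

stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field("`%s` must be a single non-missing number", name)
  if (!allow_inf && !is.finite(x))
    stop_field("`%s` must be finite", name)
  if (positive && x <= 0)
    stop_field("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0)
    stop_field("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# First derivative along rows (dim = 1, the y/scan direction) or columns
# (dim = 2, the x direction): central differences in the interior,
# one-sided at the two boundary samples. `h` is the sample spacing.
deriv1 <- function(m, h, dim = 1L) {
  if (dim == 2L) return(t(deriv1(t(m), h, dim = 1L)))
  n <- nrow(m)
  if (n < 2L) stop_field("need at least 2 samples to differentiate")
  d <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 1)), , drop = FALSE]) /
    (2 * h)
  d[1, ] <- (m[2, ] - m[1, ]) / h
  d[n, ] <- (m[n, ] - m[n - 1, ]) / h
  d
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Padded size: next power of two of 1.5*n, giving at least a 25% margin
# per side. The margin never exceeds n - 1, so a single mirror reflection
# suffices.
padded_size <- function(n) max(next_pow2(ceiling(1.5 * n)), 4L)

pad_indices <- function(n, n_pad, style = c("replicate", "mirror")) {
  style <- match.arg(style)
  before <- (n_pad - n) %/% 2L
  after <- n_pad - n - before
  idx <- (1L - before):(n + after)
  if (style == "mirror") {
    if (before >= n || after >= n)
      stop_field("mirror padding margin exceeds the image size")
    idx[idx < 1L] <- 1L - idx[idx < 1L]          # reflect below, edge repeated
    idx[idx > n] <- 2L * n + 1L - idx[idx > n]   # reflect above
  } else {
    idx <- pmin(pmax(idx, 1L), n)                # repeat the edge sample
  }
  list(idx = idx, first = before + 1L, last = before + n)
}

# Pad a matrix to (ny_pad, nx_pad). "replicate" extends each side with a
# constant equal to the per-column (resp. per-row) mean over an edge band
# of `band` samples: under noise, copying a single raw edge sample across
# a margin longer than the filter's y kernel would inject strong
# column-constant structure straight into its passband, so the band mean
# is used as a noise-robust edge estimate (band = 1 reproduces plain edge
# replication). "mirror" is the classical symmetric reflection.
pad_matrix <- function(m, ny_pad, nx_pad, style = "replicate", band = 8L) {
  if (style == "mirror") {
    iy <- pad_indices(nrow(m), ny_pad, "mirror")
    ix <- pad_indices(ncol(m), nx_pad, "mirror")
    return(list(values = m[iy$idx, ix$idx, drop = FALSE],
                crop_y = iy$first:iy$last, crop_x = ix$first:ix$last))
  }
  ny <- nrow(m); nx <- ncol(m)
  by <- min(band, ny); bx <- min(band, nx)
  pb <- (ny_pad - ny) %/% 2L; pa <- ny_pad - ny - pb
  top <- colMeans(m[1:by, , drop = FALSE])
  bot <- colMeans(m[(ny - by + 1):ny, , drop = FALSE])
  vp <- rbind(matrix(top, pb, nx, byrow = TRUE), m,
              matrix(bot, pa, nx, byrow = TRUE))
  qb <- (nx_pad - nx) %/% 2L; qa <- nx_pad - nx - qb
  left <- rowMeans(vp[, 1:bx, drop = FALSE])
  right <- rowMeans(vp[, (nx - bx + 1):nx, drop = FALSE])
  list(values = cbind(matrix(left, ny_pad, qb), vp,
                      matrix(right, ny_pad, qa)),
       crop_y = (pb + 1L):(pb + ny), crop_x = (qb + 1L):(qb + nx))
}

# Angular spatial frequencies (rad / unit of `step`) in FFT layout.
fft_xi <- function(n, step) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  2 * pi * k / (n * step)
}

ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package
# take one explicit integer seed; nothing touches the global stream.
with_local_seed <- function(seed, expr) {
  check_scalar(seed, "seed")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

gaussian_sigma_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
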