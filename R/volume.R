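#' Scalar volume on a regular axis-aligned grid
#'
#' A `scalar_volume` bundles a 3D numeric array with its physical geometry:
#' per-axis voxel spacing (mm) and the world position of voxel `(0,0,0)`.
#' Voxel indices are 0-based and refer to voxel centers, so the world
#' position of index `(i,j,k)` is `origin + c(i,j,k) * spacing`. Grids are
#' axis-aligned: no direction matrix is stored.
#'
#' @param values 3D numeric array of intensities (index order i, j, k).
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3, world mm of the center of voxel (0,0,0).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array (got ",
         paste(dim(values), collapse = "x"), ")")
  if (any(dim(values) < 2L))
    stop("grid dimensions must be >= 2 per axis")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  if (any(!is.finite(values)))
    stop("volume values must all be finite")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' Binary label volume
#'
#' Same geometry model as [scalar_volume()] but values restricted to {0, 1}.
#'
#' @inheritParams scalar_volume
#' @return An object of class `label_volume` (also `scalar_volume`).
#' @export
label_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vol <- scalar_volume(values, spacing, origin)
  if (!all(vol$values %in% c(0, 1)))
    stop("label values must be 0 or 1")
  class(vol) <- c("label_volume", "scalar_volume")
  vol
}

#' Probability volume
#'
#' Same geometry model as [scalar_volume()] but values restricted to `[0, 1]`.
#'
#' @inheritParams scalar_volume
#' @return An object of class `probability_volume` (also `scalar_volume`).
#' @export
probability_volume <- function(values, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  vol <- scalar_volume(values, spacing, origin)
  if (min(vol$values) < 0 || max(vol$values) > 1)
    stop("probability values must lie in [0, 1]")
  class(vol) <- c("probability_volume", "scalar_volume")
  vol
}

#' @exportS3Method base::print
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing (%s) mm, origin (%s) mm, range [%.4g, %.4g]\n",
              class(x)[1L], paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$values)

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("volumes are not on the same grid (dims/spacing/origin differ)")
  invisible(TRUE)
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel centers sit at `origin + index * spacing` with 0-based, possibly
#' fractional, indices. The two maps are exact inverses.
#'
#' @param vol A [scalar_volume()].
#' @param ijk,xyz Numeric length-3 vector or n-by-3 matrix of 0-based voxel
#'   indices (`ijk`) or world mm coordinates (`xyz`).
#' @return A vector/matrix of the same shape in the other coordinate system.
#' @export
index_to_world <- function(vol, ijk) {
  ijk <- as_points(ijk)
  sweep(sweep(ijk, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

#' @rdname index_to_world
#' @export
world_to_index <- function(vol, xyz) {
  xyz <- as_points(xyz)
  sweep(sweep(xyz, 2L, vol$origin, "-"), 2L, vol$spacing, "/")
}

as_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("points must have 3 components")
    matrix(as.numeric(p), 1L, 3L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("points must be an n-by-3 matrix")
    storage.mode(p) <- "double"
    p
  }
}

#' Trilinear interpolation of a volume at world points
#'
#' Samples the volume at arbitrary world-mm positions by trilinear
#' interpolation of the 8 surrounding voxel centers. Points outside the grid
#' are clamped to the border voxel centers; the fraction of clamped points is
#' reported so a caller (e.g. a deforming surface transiently leaving the
#' grid) can detect extrapolation.
#'
#' @param vol A [scalar_volume()].
#' @param points n-by-3 matrix (or length-3 vector) of world mm coordinates.
#' @return Numeric vector of sampled values with attribute
#'   `clamped_fraction`, the fraction of points that fell outside the grid.
#' @export
sample_trilinear <- function(vol, points) {
  idx <- world_to_index(vol, points)
  d <- dim(vol$values)
  clamped <- rowSums(idx < 0 | idx > matrix(d - 1L, nrow(idx), 3L,
                                            byrow = TRUE)) > 0
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 0), d[a] - 1L)
  i0 <- floor(idx)
  # keep the base corner one voxel inside so i0+1 is valid
  for (a in 1:3) i0[, a] <- pmin(i0[, a], d[a] - 2L)
  f <- idx - i0
  v <- vol$values
  corner <- function(di, dj, dk) {
    v[cbind(i0[, 1] + di + 1L, i0[, 2] + dj + 1L, i0[, 3] + dk + 1L)]
  }
  w <- function(fa, da) if (da == 0) 1 - fa else fa
  out <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    out <- out + corner(di, dj, dk) *
      w(f[, 1], di) * w(f[, 2], dj) * w(f[, 3], dk)
  }
  attr(out, "clamped_fraction") <- mean(clamped)
  out
}

#' Physical-space gradient magnitude of a volume
#'
#' Central differences scaled by voxel spacing (one-sided at the grid faces),
#' i.e. units of intensity per mm, optionally after Gaussian presmoothing.
#' This is the gradient field `G` consumed by the surface-alignment energy.
#'
#' @param vol A [scalar_volume()].
#' @param presmooth_sigma Gaussian presmoothing SD in voxels (0 = none).
#' @return A [scalar_volume()] of gradient magnitudes on the same grid.
#' @export
gradient_magnitude_volume <- function(vol, presmooth_sigma = 0) {
  stopifnot(presmooth_sigma >= 0)
  g <- volume_gradient(vol, presmooth_sigma)
  scalar_volume(sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2), vol$spacing, vol$origin)
}

# list of 3 arrays: spatial derivative along each axis (per mm)
volume_gradient <- function(vol, presmooth_sigma = 0) {
  v <- vol$values
  if (presmooth_sigma > 0) v <- gaussian_blur3(v, presmooth_sigma)
  lapply(1:3, function(a) axis_central_diff(v, a) / vol$spacing[a])
}

# central differences along axis `a`, one-sided at the two faces
axis_central_diff <- function(v, a) {
  d <- dim(v)
  n <- d[a]
  idx_shift <- function(off) {
    ii <- pmin(pmax(seq_len(n) + off, 1L), n)
    slice_index(v, a, ii)
  }
  hi <- idx_shift(1L); lo <- idx_shift(-1L)
  # interior: (v[i+1]-v[i-1])/2 ; faces: one-sided difference
  denom <- rep(2, n); denom[1L] <- 1; denom[n] <- 1
  sweep(hi - lo, a, denom, "/")
}

# index array `v` along axis `a` with index vector ii (keeps dims)
slice_index <- function(v, a, ii) {
  switch(a, v[ii, , , drop = FALSE], v[, ii, , drop = FALSE],
         v[, , ii, drop = FALSE])
}

# separable 3D Gaussian blur, sigma in voxels, replicated borders
gaussian_blur3 <- function(v, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  for (a in 1:3) v <- axis_convolve(v, a, k)
  v
}

# 1D convolution along axis a with kernel k (odd length), replicate borders
axis_convolve <- function(v, a, k) {
  n <- dim(v)[a]
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim(v))
  for (t in seq_along(k)) {
    off <- t - r - 1L
    ii <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[t] * slice_index(v, a, ii)
  }
  out
}
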