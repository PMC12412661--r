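#' Resample a volume by a scale factor with tricubic interpolation
#'
#' Increases (factor > 1) or decreases resolution using separable
#' Catmull-Rom cubic interpolation; the new spacing is `spacing / factor`
#' and the world origin is unchanged, so world extent is preserved to
#' within one voxel. A factor of 1.5 increases resolution by 50%.
#'
#' @param vol A [scalar_volume()].
#' @param factor Positive scale factor on resolution.
#' @param max_voxels Memory guard: error if the output grid would exceed
#'   this many voxels.
#' @return A resampled [scalar_volume()].
#' @export
resample_volume <- function(vol, factor, max_voxels = 512^3) {
  stopifnot(factor > 0)
  d <- dim(vol$values)
  nd <- pmax(2L, as.integer(round(d * factor)))
  if (prod(nd) > max_voxels)
    stop("resampled grid (", paste(nd, collapse = "x"),
         ") exceeds max_voxels guard")
  new_spacing <- vol$spacing / factor
  v <- vol$values
  for (a in 1:3) {
    # fractional source index of each target voxel center along axis a
    src <- (seq_len(nd[a]) - 1L) * new_spacing[a] / vol$spacing[a]
    M <- catmull_rom_matrix(src, dim(v)[a])
    v <- apply_axis_matrix(v, a, M)
  }
  scalar_volume(v, new_spacing, vol$origin)
}

# n_new x n_old interpolation matrix for Catmull-Rom cubic at positions
# `src` (0-based fractional indices); border indices replicate
catmull_rom_matrix <- function(src, n_old) {
  i0 <- floor(src)
  t <- src - i0
  w <- cbind(-0.5 * t + t^2 - 0.5 * t^3,
             1 - 2.5 * t^2 + 1.5 * t^3,
             0.5 * t + 2 * t^2 - 1.5 * t^3,
             -0.5 * t^2 + 0.5 * t^3)
  rows <- rep(seq_along(src), 4L)
  cols <- pmin(pmax(c(i0 - 1, i0, i0 + 1, i0 + 2), 0), n_old - 1L) + 1L
  Matrix::sparseMatrix(i = rows, j = cols, x = as.vector(w),
                       dims = c(length(src), n_old))
}

# multiply axis `a` of 3D array v by matrix M (n_new x n_a)
apply_axis_matrix <- function(v, a, M) {
  d <- dim(v)
  perm <- c(a, setdiff(1:3, a))
  vp <- aperm(v, perm)
  m <- matrix(vp, d[a], prod(d[-a]))
  out <- as.matrix(M %*% m)
  dim(out) <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(out, order(perm))
}

#' Clip and normalize intensities to [0, 1]
#'
#' Values are clamped to `[lo, hi]` then mapped linearly to `[0, 1]`. The
#' default 0-500 window targets contrast-enhanced CT angiography, where it
#' suppresses extreme outliers while preserving lumen-background contrast.
#'
#' @param vol A [scalar_volume()].
#' @param lo,hi Clip window (default 0 and 500); `hi > lo`.
#' @return A [probability_volume()]-ranged [scalar_volume()] in `[0, 1]`.
#' @export
clip_normalize <- function(vol, lo = 0, hi = 500) {
  stopifnot(hi > lo)
  v <- (pmin(pmax(vol$values, lo), hi) - lo) / (hi - lo)
  scalar_volume(v, vol$spacing, vol$origin)
}

#' Zero out intensities outside the vessel label
#'
#' Training-time background suppression: voxels with label 0 are set to
#' zero so the model attends to vessel features. Not applied at inference.
#'
#' @param vol A [scalar_volume()].
#' @param label A paired [label_volume()] on the same grid.
#' @return The masked [scalar_volume()].
#' @export
suppress_background <- function(vol, label) {
  stopifnot_same_grid(vol, label)
  scalar_volume(vol$values * label$values, vol$spacing, vol$origin)
}

#' Random flip / 90-degree rotation / crop augmentation
#'
#' Applies one seeded random geometric augmentation jointly to an image and
#' its label: independent flips per axis, a rotation by a multiple of 90
#' degrees about a random axis (so labels need no interpolation), and a
#' random crop. The transform parameters are returned for reproducibility.
#'
#' @param vol A [scalar_volume()].
#' @param label The paired [label_volume()].
#' @param seed Integer seed; the same seed reproduces the same transform.
#' @param crop_size Cube side of the crop in voxels (default 64); must not
#'   exceed the (rotated) grid.
#' @return List with `image`, `label`, and `transform` (the sampled
#'   parameters).
#' @export
random_augment <- function(vol, label, seed, crop_size = 64L) {
  stopifnot_same_grid(vol, label)
  d <- dim(vol$values)
  with_seed(seed, {
    flips <- runif(3) < 0.5
    rot_axis <- sample.int(3L, 1L)
    rot_k <- sample(0:3, 1L)
    iv <- vol$values; il <- label$values
    for (a in 1:3) if (flips[a]) {
      iv <- flip_axis(iv, a); il <- flip_axis(il, a)
    }
    iv <- rot90_3d(iv, rot_axis, rot_k)
    il <- rot90_3d(il, rot_axis, rot_k)
    d2 <- dim(iv)
    if (any(crop_size > d2))
      stop("crop_size ", crop_size, " exceeds grid ",
           paste(d2, collapse = "x"))
    corner <- sapply(1:3, function(a) sample.int(d2[a] - crop_size + 1L, 1L))
    iv <- iv[corner[1]:(corner[1] + crop_size - 1L),
             corner[2]:(corner[2] + crop_size - 1L),
             corner[3]:(corner[3] + crop_size - 1L)]
    il <- il[corner[1]:(corner[1] + crop_size - 1L),
             corner[2]:(corner[2] + crop_size - 1L),
             corner[3]:(corner[3] + crop_size - 1L)]
    list(image = scalar_volume(iv, vol$spacing, vol$origin),
         label = label_volume(il, vol$spacing, vol$origin),
         transform = list(flips = flips, rot_axis = rot_axis, rot_k = rot_k,
                          corner = corner - 1L, crop_size = crop_size))
  })
}

flip_axis <- function(v, a) {
  n <- dim(v)[a]
  slice_index(v, a, n:1)
}

# rotate k*90 degrees in the plane perpendicular to `axis`
rot90_3d <- function(v, axis, k) {
  k <- k %% 4L
  if (k == 0L) return(v)
  plane <- setdiff(1:3, axis)
  for (s in seq_len(k)) {
    perm <- 1:3
    perm[plane] <- plane[2:1]
    v <- aperm(v, perm)
    v <- flip_axis(v, plane[1])
  }
  v
}

#' Split a volume into overlapping cubic patches
#'
#' Patches of side `size` tile the grid with stride `size - overlap`,
#' starting at every stride multiple below the grid extent; patches
#' extending past the grid are zero-padded. Every voxel is covered at
#' least once.
#'
#' @param vol A [scalar_volume()].
#' @param size Patch side in voxels (default 64).
#' @param overlap Overlap between successive patches in voxels
#'   (default 16); must be smaller than `size`.
#' @return List of patches, each a list with `corner` (0-based voxel index
#'   of the patch origin) and `values` (size^3 array); the grid dimensions
#'   are attached as attribute `grid_dim`.
#' @export
extract_patches <- function(vol, size = 64L, overlap = 16L) {
  stopifnot(size >= 8L, overlap < size, overlap >= 0L)
  d <- dim(vol$values)
  stride <- size - overlap
  corners_axis <- lapply(1:3, function(a) seq(0L, d[a] - 1L, by = stride))
  patches <- list()
  for (ck in corners_axis[[3]]) for (cj in corners_axis[[2]])
    for (ci in corners_axis[[1]]) {
      patch <- array(0, c(size, size, size))
      ii <- (ci + 1L):min(ci + size, d[1])
      jj <- (cj + 1L):min(cj + size, d[2])
      kk <- (ck + 1L):min(ck + size, d[3])
      patch[seq_along(ii), seq_along(jj), seq_along(kk)] <-
        vol$values[ii, jj, kk]
      patches[[length(patches) + 1L]] <-
        list(corner = c(ci, cj, ck), values = patch)
    }
  attr(patches, "grid_dim") <- d
  attr(patches, "size") <- size
  attr(patches, "stride") <- stride
  patches
}

#' Stitch per-patch predictions back into a full volume
#'
#' Overlapping voxels receive the unweighted mean of all covering patches.
#'
#' @param patches List of patches as produced by [extract_patches()] (the
#'   `values` may have been replaced by per-patch predictions in `[0, 1]`).
#' @param template A [scalar_volume()] supplying the output geometry, or an
#'   integer length-3 grid dimension.
#' @return A [probability_volume()] when all stitched values lie in
#'   `[0, 1]`, otherwise a [scalar_volume()].
#' @export
stitch_predictions <- function(patches, template) {
  if (inherits(template, "scalar_volume")) {
    d <- dim(template$values); spacing <- template$spacing
    origin <- template$origin
  } else {
    d <- as.integer(template); spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  }
  acc <- array(0, d)
  cnt <- array(0L, d)
  for (p in patches) {
    size <- dim(p$values)[1]
    ci <- p$corner
    ii <- (ci[1] + 1L):min(ci[1] + size, d[1])
    jj <- (ci[2] + 1L):min(ci[2] + size, d[2])
    kk <- (ci[3] + 1L):min(ci[3] + size, d[3])
    acc[ii, jj, kk] <- acc[ii, jj, kk] +
      p$values[seq_along(ii), seq_along(jj), seq_along(kk)]
    cnt[ii, jj, kk] <- cnt[ii, jj, kk] + 1L
  }
  if (any(cnt == 0L)) stop("patches do not cover the full grid")
  out <- acc / cnt
  if (min(out) >= 0 && max(out) <= 1)
    probability_volume(out, spacing, origin)
  else scalar_volume(out, spacing, origin)
}
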