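#' Build a 3D Laplacian-of-Gaussian convolution kernel
#'
#' Evaluates the LoG filter
#' \deqn{(x^2+y^2+z^2-2\sigma^2)/\sigma^4 \, e^{-(x^2+y^2+z^2)/2\sigma^2}}
#' at integer voxel offsets centred on zero. The raw kernel changes sign on
#' the sphere of radius \eqn{\sqrt{2}\sigma} and has center value
#' \eqn{-2/\sigma^2}. When `normalize = TRUE` (the default, used by the
#' segmentation stream) the kernel is mean-subtracted — so a constant input
#' yields exactly zero response — and L1-normalized so response magnitudes
#' are comparable across scales.
#'
#' @param size Odd kernel side length in voxels.
#' @param sigma Scale of the filter in voxels (> 0).
#' @param normalize Mean-subtract and L1-normalize (default `TRUE`).
#' @return A `size^3` array.
#' @export
build_log_kernel <- function(size, sigma, normalize = TRUE) {
  if (size %% 2L != 1L) stop("kernel size must be odd, got ", size)
  stopifnot(sigma > 0)
  half <- (size - 1L) / 2L
  ax <- seq(-half, half)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  if (normalize) {
    k <- k - mean(k)
    k <- k / sum(abs(k))
  }
  k
}

#' Hierarchical bank of LoG kernels
#'
#' The default five-level bank pairs kernel sizes 3, 5, 7, 9, 11 with
#' scales 0.5, 1.0, 1.5, 2.0, 2.5 voxels; a LoG filter of scale
#' \eqn{\sigma} responds maximally to tubes of radius about
#' \eqn{\sqrt{2}\sigma}, so the bank spans small branch vessels up to the
#' main aorta.
#'
#' @param sizes Odd kernel sizes per level.
#' @param sigmas Scales per level (same length as `sizes`).
#' @return An object of class `log_kernel_bank`: list of `levels`
#'   (size/sigma pairs) and `kernels` (normalized arrays).
#' @export
log_kernel_bank <- function(sizes = c(3L, 5L, 7L, 9L, 11L),
                            sigmas = c(0.5, 1.0, 1.5, 2.0, 2.5)) {
  stopifnot(length(sizes) == length(sigmas))
  kernels <- mapply(build_log_kernel, sizes, sigmas, SIMPLIFY = FALSE)
  structure(list(levels = data.frame(size = as.integer(sizes),
                                     sigma = sigmas),
                 kernels = kernels),
            class = "log_kernel_bank")
}

#' @exportS3Method base::print
print.log_kernel_bank <- function(x, ...) {
  cat("<log_kernel_bank>", nrow(x$levels), "levels: sizes",
      paste(x$levels$size, collapse = ","), "sigmas",
      paste(x$levels$sigma, collapse = ","), "\n")
  invisible(x)
}
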