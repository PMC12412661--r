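#' Average symmetric surface distance (ASD)
#'
#' \deqn{ASD(A,B) = \frac{\sum_{x \in A}\min_y d(x,y) +
#'   \sum_{y \in B}\min_x d(y,x)}{|A| + |B|}}
#' between two surface point clouds (mesh vertices when meshes are given).
#'
#' @param a,b n-by-3 point matrices or [triangle_mesh()] objects.
#' @return Scalar distance in mm.
#' @export
asd <- function(a, b) {
  pa <- surface_points(a); pb <- surface_points(b)
  dab <- nn_dist(pa, pb)
  dba <- nn_dist(pb, pa)
  (sum(dab) + sum(dba)) / (nrow(pa) + nrow(pb))
}

# exact nearest-neighbour distances; grid-bucketed above the brute-force
# sweet spot
nn_dist <- function(q, r) {
  if (nrow(q) * nrow(r) > 4e6) nearest_point_grid_cpp(q, r)$distance
  else nearest_point_cpp(q, r)$distance
}

#' Hausdorff distance between surface point clouds
#'
#' The larger of the two directed worst-case nearest-point distances.
#'
#' @inheritParams asd
#' @return Scalar distance in mm.
#' @export
hausdorff <- function(a, b) {
  pa <- surface_points(a); pb <- surface_points(b)
  max(max(nn_dist(pa, pb)), max(nn_dist(pb, pa)))
}

surface_points <- function(x) {
  if (inherits(x, "triangle_mesh")) return(x$vertices)
  p <- as_points(x)
  if (nrow(p) == 0L) stop("empty point set")
  p
}

#' Local signal-to-noise ratio of an image at a point
#'
#' Mean divided by population SD of the intensities in the cubic window
#' (default 10 voxels per side) centered at the point; dimensionless
#' relative SNR. Windows are clipped at the grid border with a warning.
#'
#' @param vol A [scalar_volume()].
#' @param center World-mm position (length-3).
#' @param window Window side in voxels (default 10).
#' @return Scalar SNR; `Inf` with attribute `constant_window = TRUE` when
#'   the window has zero variance.
#' @export
snr_at_point <- function(vol, center, window = 10L) {
  d <- dim(vol$values)
  idx <- round(world_to_index(vol, center))
  lo <- as.integer(idx - floor((window - 1) / 2))
  hi <- lo + window - 1L
  lo_c <- pmax(lo, 0L); hi_c <- pmin(hi, d - 1L)
  if (any(lo_c != lo) || any(hi_c != hi))
    warning("SNR window clipped at the grid border")
  vals <- vol$values[(lo_c[1]:hi_c[1]) + 1L, (lo_c[2]:hi_c[2]) + 1L,
                     (lo_c[3]:hi_c[3]) + 1L]
  n <- length(vals)
  mu <- mean(vals)
  sd_pop <- sqrt(sum((vals - mu)^2) / n)
  if (sd_pop == 0) {
    out <- Inf
    attr(out, "constant_window") <- TRUE
    return(out)
  }
  mu / sd_pop
}

#' Segmentation and surface quality report
#'
#' Dice between label volumes, plus ASD and Hausdorff between surfaces
#' when meshes are supplied; optionally broken down by region (e.g. main
#' vessel vs branches).
#'
#' @param pred_label,truth_label [label_volume()] objects on one grid.
#' @param pred_mesh,truth_mesh Optional [triangle_mesh()] surfaces.
#' @param region Optional integer array (same grid) assigning voxels to
#'   regions (0 = background); region 1 is reported as `main`, higher
#'   regions pooled as `branch`.
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(pred_label, truth_label, pred_mesh = NULL,
                           truth_mesh = NULL, region = NULL) {
  stopifnot_same_grid(pred_label, truth_label)
  out <- list(dice = dice_coefficient(pred_label, truth_label),
              point_definition = "mesh vertices")
  if (!is.null(pred_mesh) && !is.null(truth_mesh)) {
    out$asd <- asd(pred_mesh, truth_mesh)
    out$hausdorff <- hausdorff(pred_mesh, truth_mesh)
  }
  if (!is.null(region)) {
    g <- truth_label$values; o <- pred_label$values
    main <- region == 1L
    branch <- region > 1L
    # region-restricted Dice: agreement within each region mask plus all
    # predicted foreground assigned to the nearer region is approximated
    # by masking both volumes
    out$dice_main <- {
      gm <- g * main; om <- o * main
      if (sum(gm) + sum(om) == 0) 1 else 2 * sum(gm * om) /
        (sum(gm) + sum(om))
    }
    out$dice_branch <- {
      gb <- g * branch; ob <- o * branch
      if (sum(gb) + sum(ob) == 0) 1 else 2 * sum(gb * ob) /
        (sum(gb) + sum(ob))
    }
  }
  class(out) <- "metrics_report"
  out
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> Dice %.4f", x$dice))
  if (!is.null(x$asd)) cat(sprintf(", ASD %.3f mm, Hausdorff %.3f mm",
                                   x$asd, x$hausdorff))
  if (!is.null(x$dice_main))
    cat(sprintf(" | main %.4f / branch %.4f", x$dice_main, x$dice_branch))
  cat("\n")
  invisible(x)
}

#' Surface uncertainty summary from an ensemble
#'
#' For each vertex of the mean surface: the SD (over ensemble members) of
#' the distance to the member's nearest surface point, and the local image
#' SNR. Summarized by the Spearman correlation and least-squares slope of
#' `log(SD)` against SNR — the uncertainty-vs-image-quality relation.
#'
#' @param mean_mesh The reference (mean) surface.
#' @param members List of at least 2 ensemble [triangle_mesh()] surfaces.
#' @param image The underlying [scalar_volume()] for SNR.
#' @param window SNR window in voxels (default 10).
#' @return List with `sd` and `snr` per mean-surface vertex, `spearman`,
#'   `slope` (of log-SD vs SNR), and `n_used`.
#' @export
uq_summary <- function(mean_mesh, members, image, window = 10L) {
  if (length(members) < 2L)
    stop("need at least 2 ensemble members")
  mv <- surface_points(mean_mesh)
  dists <- sapply(members, function(m)
    nearest_point_grid_cpp(mv, surface_points(m))$distance)
  sd_pt <- apply(dists, 1L, sd)
  snr <- suppressWarnings(
    vapply(seq_len(nrow(mv)), function(i)
      snr_at_point(image, mv[i, ], window), 0))
  ok <- sd_pt > 0 & is.finite(snr)
  if (sum(ok) < 3L) {
    spearman <- NA_real_; slope <- NA_real_
  } else {
    spearman <- suppressWarnings(cor(log(sd_pt[ok]), snr[ok],
                                     method = "spearman"))
    slope <- unname(coef(lm(log(sd_pt[ok]) ~ snr[ok]))[2L])
  }
  list(sd = sd_pt, snr = snr, spearman = spearman, slope = slope,
       n_used = sum(ok))
}
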