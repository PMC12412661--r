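#' Extract an isosurface as a triangular mesh
#'
#' Runs tetrahedral-decomposition isosurfacing (a marching-cubes-family
#' algorithm) on a probability or label volume. The output mesh is in
#' world mm with outward-pointing normals (from the above-level region
#' out). Binary label volumes are pre-smoothed with a 1-voxel Gaussian to
#' reduce staircase bias.
#'
#' @param vol A [probability_volume()], [label_volume()], or
#'   [scalar_volume()].
#' @param level Iso level (default 0.5); must lie inside the value range.
#' @param presmooth_labels Gaussian-smooth binary labels before extraction
#'   (default `TRUE`).
#' @return A [triangle_mesh()].
#' @export
extract_isosurface <- function(vol, level = 0.5, presmooth_labels = TRUE) {
  v <- vol$values
  if (presmooth_labels && inherits(vol, "label_volume"))
    v <- gaussian_blur3(v, 1)
  if (min(v) >= level || max(v) <= level)
    stop("volume does not cross the iso level ", level,
         " (range [", round(min(v), 4), ", ", round(max(v), 4), "])")
  res <- marching_tetrahedra_cpp(v, level, vol$spacing, vol$origin)
  if (nrow(res$faces) == 0L) stop("empty isosurface at level ", level)
  triangle_mesh(res$vertices, res$faces, validate = FALSE)
}

#' Uniformly remesh a surface by approximate centroidal clustering
#'
#' Vertices are clustered with k-means into `target_vertices` groups (an
#' approximated centroidal Voronoi partition of the surface samples); the
#' output mesh takes one vertex per cluster (its centroid) and one face
#' per original triangle whose corners fall in three distinct clusters.
#' This redistributes vertices evenly, strictly reducing the
#' coefficient of variation of edge lengths on voxelization-artifact
#' meshes, while preserving topology.
#'
#' @param mesh A [triangle_mesh()] (watertight or with boundary loops).
#' @param target_vertices Desired vertex count (>= 100).
#' @param iter_max k-means iterations (Lloyd relaxation steps).
#' @param seed Seed for cluster initialization.
#' @return A [triangle_mesh()] with about `target_vertices` vertices.
#' @export
remesh_uniform <- function(mesh, target_vertices, iter_max = 30L,
                           seed = 1L) {
  if (target_vertices < 100L)
    stop("target_vertices must be at least 100")
  if (target_vertices >= nrow(mesh$vertices))
    stop("target_vertices must be below the current vertex count (",
         nrow(mesh$vertices), ")")
  # cluster in position (+) scaled-normal space: the normal term separates
  # opposite walls of thin tubes that are close in Euclidean distance
  lambda <- 2 * mean(edge_lengths(mesh))
  feats <- cbind(mesh$vertices, lambda * vertex_normals(mesh))
  for (attempt in 1:5) {
    km <- with_seed(seed + attempt - 1L,
                    suppressWarnings(kmeans(feats,
                                            centers = target_vertices,
                                            iter.max = iter_max,
                                            nstart = 1L)))
    cl <- km$cluster
    # a few cluster pairs typically produce non-manifold dual edges;
    # merge those pairs and rebuild until the dual is 2-manifold
    for (repair in 1:25) {
      fc <- cluster_dual_faces(cl, mesh$faces)
      e <- rbind(fc[, c(1, 2)], fc[, c(2, 3)], fc[, c(3, 1)])
      ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      tab <- table(ekey)
      bad <- names(tab)[tab > 2L]
      if (length(bad) == 0L) break
      for (b in bad) {
        pair <- as.integer(strsplit(b, " ")[[1L]])
        cl[cl == pair[2L]] <- pair[1L]
      }
    }
    if (length(bad) > 0L) next  # unrepairable clustering: retry seed
    ids <- sort(unique(cl))
    map <- match(cl, ids)
    centers <- rowsum(mesh$vertices, map) / tabulate(map, length(ids))
    fc <- cluster_dual_faces(map, mesh$faces)
    out <- try(drop_unused_vertices(
      triangle_mesh(centers, fc, validate = FALSE)), silent = TRUE)
    if (inherits(out, "try-error")) next
    if (any(edge_face_count(out) > 2L)) next
    return(out)
  }
  stop("clustering-based remeshing failed to produce a manifold mesh; ",
       "try a different target_vertices")
}

# dual faces of a vertex clustering: one face per input triangle whose
# corners lie in three distinct clusters, duplicates collapsed
cluster_dual_faces <- function(cl, faces) {
  fc <- matrix(cl[faces], ncol = 3L)
  ok <- fc[, 1] != fc[, 2] & fc[, 2] != fc[, 3] & fc[, 1] != fc[, 3]
  fc <- fc[ok, , drop = FALSE]
  a <- pmin(fc[, 1], fc[, 2], fc[, 3])
  c_ <- pmax(fc[, 1], fc[, 2], fc[, 3])
  b <- fc[, 1] + fc[, 2] + fc[, 3] - a - c_
  fc[!duplicated(cbind(a, b, c_)), , drop = FALSE]
}

#' Smoothing weights for surface regularization
#'
#' @param w_normal,w_edge,w_laplacian Nonnegative weights of the three
#'   regularizers (defaults 1.0, 0.1, 0.5).
#' @param iterations Gradient-descent iterations (default 100).
#' @param step Step size (default 0.1).
#' @return A list of class `smoothing_weights`.
#' @export
smoothing_weights <- function(w_normal = 1.0, w_edge = 0.1,
                              w_laplacian = 0.5, iterations = 100L,
                              step = 0.1) {
  stopifnot(w_normal >= 0, w_edge >= 0, w_laplacian >= 0, iterations >= 0,
            step > 0)
  structure(list(w_normal = w_normal, w_edge = w_edge,
                 w_laplacian = w_laplacian,
                 iterations = as.integer(iterations), step = step),
            class = "smoothing_weights")
}

#' Smooth a mesh by minimizing normal, edge, and Laplacian losses
#'
#' Plain gradient descent on the weighted sum of the three surface
#' regularizers; the combined objective is non-increasing across accepted
#' iterations (a step that increases it, or flips a face normal, is halved
#' and retried). Connectivity is never changed.
#'
#' @param mesh A [triangle_mesh()].
#' @param weights A [smoothing_weights()].
#' @return The smoothed [triangle_mesh()] with attribute `history`
#'   (objective per iteration).
#' @export
smooth_mesh <- function(mesh, weights = smoothing_weights()) {
  stopifnot(inherits(weights, "smoothing_weights"))
  if (weights$iterations == 0L ||
      (weights$w_normal == 0 && weights$w_edge == 0 &&
       weights$w_laplacian == 0))
    return(mesh)
  cur <- mesh
  res <- mesh_reg_loss_grad(cur, weights$w_normal, weights$w_edge,
                            weights$w_laplacian)
  hist <- numeric(weights$iterations)
  step <- weights$step
  ref_normals <- face_normals(cur)$normals
  for (it in seq_len(weights$iterations)) {
    accepted <- FALSE
    s <- step
    for (try_i in 1:8) {
      cand <- cur
      cand$vertices <- cur$vertices - s * res$grad
      nn <- face_normals(cand)$normals
      inverted <- any(rowSums(nn * ref_normals) < 0)
      cand_res <- mesh_reg_loss_grad(cand, weights$w_normal,
                                     weights$w_edge, weights$w_laplacian)
      if (!inverted && cand_res$total <= res$total) {
        cur <- cand
        res <- cand_res
        ref_normals <- nn
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    hist[it] <- res$total
    if (!accepted) {
      hist <- hist[seq_len(it)]
      break  # converged: no acceptable descent step
    }
  }
  attr(cur, "history") <- hist
  cur
}
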