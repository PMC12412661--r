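#' Specification of a synthetic branched-vessel phantom
#'
#' A phantom emulates a contrast-enhanced CT angiogram: a branched tubular
#' lumen brighter than the background, Gaussian-blurred and corrupted by
#' additive Gaussian noise, with intensities inside the 0-500 clip window
#' used for preprocessing. Ground truth (binary label and surface mesh) is
#' generated alongside the image.
#'
#' Centerlines are polylines in world mm with a per-point radius profile.
#' Default intensities put the lumen at 300 and background at 50.
#'
#' @param grid_shape Integer length-3 voxel dimensions.
#' @param spacing Voxel spacing in mm.
#' @param origin World mm of voxel (0,0,0).
#' @param centerlines List of centerlines, each a list with `points`
#'   (n-by-3 mm), `radii` (length n, mm), and `open_ends` (logical length 2:
#'   is the start/end an open inlet/outlet?).
#' @param lumen_intensity,background_intensity Intensities of the two-level
#'   noise-free field; must satisfy `lumen > background`, both in `[0, 500]`.
#' @param blur_sigma Gaussian blur SD in voxels applied to the two-level
#'   field (emulates partial-volume effects).
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param seed Integer seed controlling the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), centerlines = list(),
                         lumen_intensity = 300, background_intensity = 50,
                         blur_sigma = 1, noise_sd = 15, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            all(spacing > 0), blur_sigma >= 0, noise_sd >= 0)
  if (lumen_intensity <= background_intensity)
    stop("lumen_intensity must exceed background_intensity")
  if (lumen_intensity > 500 || background_intensity < 0)
    stop("pre-noise intensities must lie in [0, 500]")
  for (cl in centerlines) check_centerline(cl)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 centerlines = centerlines,
                 lumen_intensity = lumen_intensity,
                 background_intensity = background_intensity,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

check_centerline <- function(cl) {
  stopifnot(is.list(cl), !is.null(cl$points), !is.null(cl$radii))
  p <- as_points(cl$points)
  if (nrow(p) < 2L) stop("centerline needs at least 2 points")
  if (length(cl$radii) != nrow(p)) stop("radii must match centerline points")
  if (any(cl$radii <= 0)) stop("radii must be positive")
  invisible(TRUE)
}

#' Straight or curved centerline helper
#'
#' @param points n-by-3 matrix of polyline control points (mm).
#' @param radii Radius profile in mm: scalar (constant) or length n.
#' @param open_ends Logical length 2: whether the start/end of the curve is
#'   an open inlet/outlet (its cap is cut from the ground-truth mesh).
#' @return A centerline list usable in [phantom_spec()].
#' @export
centerline <- function(points, radii, open_ends = c(TRUE, TRUE)) {
  points <- as_points(points)
  if (length(radii) == 1L) radii <- rep(radii, nrow(points))
  cl <- list(points = points, radii = as.numeric(radii),
             open_ends = as.logical(open_ends))
  check_centerline(cl)
  cl
}

# resample a polyline (and its radii) at approximately `step` mm arc length
densify_centerline <- function(cl, step) {
  p <- cl$points; r <- cl$radii
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n <- max(2L, ceiling(total / step) + 1L)
  si <- seq(0, total, length.out = n)
  out_p <- sapply(1:3, function(c) stats::approx(s, p[, c], xout = si)$y)
  out_r <- stats::approx(s, r, xout = si)$y
  list(points = out_p, radii = out_r)
}

#' Attach a branch vessel to a phantom specification
#'
#' Appends a straight branch that takes off from a parent centerline at a
#' given arc-length fraction, at a given angle from the parent tangent.
#' The takeoff end is closed (it merges into the parent); the far end is an
#' open outlet.
#'
#' @param spec A [phantom_spec()].
#' @param parent Index of the parent centerline.
#' @param takeoff Arc-length fraction in `[0, 1]` along the parent.
#' @param angle Angle in degrees between branch and parent tangent.
#' @param radius Branch radius in mm (tapered slightly toward the tip).
#' @param length Branch length in mm.
#' @param azimuth Orientation of the branch around the parent tangent, in
#'   degrees; gives deterministic but distinct directions for multiple
#'   branches.
#' @return The updated `phantom_spec`.
#' @export
add_branch <- function(spec, parent = 1L, takeoff = 0.5, angle = 60,
                       radius = 4, length = 20, azimuth = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  pc <- spec$centerlines[[parent]]
  dense <- densify_centerline(pc, min(spec$spacing) / 2)
  seg <- sqrt(rowSums(diff(dense$points)^2))
  s <- c(0, cumsum(seg)) / sum(seg)
  i0 <- which.min(abs(s - takeoff))
  p0 <- dense$points[i0, ]
  r0 <- dense$radii[i0]
  if (radius > r0)
    warning("branch radius (", radius, ") exceeds parent radius (", r0, ")")
  i1 <- min(i0 + 1L, nrow(dense$points))
  tangent <- dense$points[i1, ] - dense$points[max(1L, i0 - 1L), ]
  tangent <- tangent / sqrt(sum(tangent^2))
  # orthonormal frame around the tangent
  ref <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * tangent) * tangent
  u <- u / sqrt(sum(u^2))
  w <- c(tangent[2] * u[3] - tangent[3] * u[2],
         tangent[3] * u[1] - tangent[1] * u[3],
         tangent[1] * u[2] - tangent[2] * u[1])
  az <- azimuth * pi / 180
  perp <- cos(az) * u + sin(az) * w
  th <- angle * pi / 180
  dir <- cos(th) * tangent + sin(th) * perp
  tip <- p0 + length * dir
  lo <- spec$origin
  hi <- spec$origin + (spec$grid_shape - 1L) * spec$spacing
  if (any(tip < lo) || any(tip > hi))
    stop("branch exits the grid: tip at (", paste(round(tip, 1),
         collapse = ", "), ") mm")
  npts <- max(2L, ceiling(length / min(spec$spacing)))
  tpar <- seq(0, 1, length.out = npts)
  pts <- outer(rep(1, npts), p0) + outer(tpar * length, dir)
  radii <- radius * (1 - 0.25 * tpar)  # slight taper toward the tip
  spec$centerlines <- c(spec$centerlines,
                        list(centerline(pts, radii,
                                        open_ends = c(FALSE, TRUE))))
  spec
}

#' Default branched aortic-arch-like phantom specification
#'
#' A curved main vessel (radius 10 voxels by default) crossing the grid with
#' three smaller branches (radius 3-5 voxels) taking off from its upper
#' side, loosely emulating the supra-aortic branch topology.
#'
#' @param grid_shape Voxel dimensions (default 64^3).
#' @param spacing Voxel spacing (mm).
#' @param main_radius Main vessel radius in mm.
#' @param n_branches Number of branches (0-3 supported by the default
#'   layout).
#' @param seed Noise seed, forwarded to [phantom_spec()].
#' @param ... Passed on to [phantom_spec()] (intensities, blur, noise).
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(grid_shape = c(64, 64, 64),
                                 spacing = c(1, 1, 1), main_radius = 10,
                                 n_branches = 3, seed = 1L, ...) {
  ext <- (grid_shape - 1) * spacing
  # gentle arc through the volume, ends a few voxels inside the grid
  t <- seq(0, 1, length.out = 40)
  margin <- main_radius + 2 * max(spacing)
  pts <- cbind(margin + t * (ext[1] - 2 * margin),
               ext[2] * 0.40 + 0.12 * ext[2] * sin(pi * t),
               ext[3] * 0.5 + 0.05 * ext[3] * cos(2 * pi * t))
  spec <- phantom_spec(grid_shape, spacing,
                       centerlines = list(centerline(pts, main_radius)),
                       seed = seed, ...)
  # takeoff fraction, takeoff angle (deg), radius fraction, azimuth (deg)
  br <- list(c(0.20, 65, 0.45, 90), c(0.45, 60, 0.35, 40),
             c(0.68, 70, 0.50, 140))
  for (b in seq_len(min(n_branches, 3))) {
    prm <- br[[b]]
    spec <- add_branch(spec, parent = 1L, takeoff = prm[1], angle = prm[2],
                       radius = prm[3] * main_radius,
                       length = min(ext) * 0.28, azimuth = prm[4])
  }
  spec
}

#' Generate a phantom image, label, and ground-truth surface
#'
#' The binary label is 1 exactly where the distance to the nearest
#' centerline point falls below the local radius. The image is the blurred
#' two-level intensity field plus seeded Gaussian noise. The mesh is the
#' lumen isosurface of the noise-free signed tube field, with the designated
#' inlet/outlet caps cut open (so their boundary loops exercise the scaling
#' gate downstream).
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `image` ([scalar_volume()]), `label`
#'   ([label_volume()]), `mesh` ([triangle_mesh()]), and `region` (integer
#'   array: 0 outside, otherwise the index of the nearest centerline —
#'   the main/branch split used by region-resolved metrics).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$centerlines) == 0L)
    stop("phantom_spec has no centerlines")
  dims <- spec$grid_shape
  lo <- spec$origin
  hi <- spec$origin + (dims - 1L) * spec$spacing
  step <- min(spec$spacing) / 2
  fields <- vector("list", length(spec$centerlines))
  for (ci in seq_along(spec$centerlines)) {
    cl <- spec$centerlines[[ci]]
    if (any(t(cl$points) < lo) || any(t(cl$points) > hi))
      stop("centerline ", ci, " exits the grid")
    dense <- densify_centerline(cl, step)
    fields[[ci]] <- tube_field_cpp(dims, spec$spacing, spec$origin,
                                   dense$points, dense$radii)
  }
  field <- Reduce(pmin, fields)
  dim(field) <- dims
  label <- array(as.numeric(field < 0), dims)
  region <- array(0L, dims)
  which_curve <- apply(simplify2array(lapply(fields, as.vector)), 1L,
                       which.min)
  region[label > 0] <- which_curve[label > 0]
  two_level <- spec$background_intensity +
    (spec$lumen_intensity - spec$background_intensity) * label
  img <- two_level
  if (spec$blur_sigma > 0) img <- gaussian_blur3(img, spec$blur_sigma)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       array(rnorm(prod(dims), sd = spec$noise_sd), dims))
    img <- img + noise
  }
  mesh <- phantom_surface(spec, field)
  list(image = scalar_volume(img, spec$spacing, spec$origin),
       label = label_volume(label, spec$spacing, spec$origin),
       mesh = mesh, region = region)
}

# isosurface of the signed tube field, caps cut at open centerline ends
phantom_surface <- function(spec, field) {
  res <- marching_tetrahedra_cpp(-field, 0, spec$spacing, spec$origin)
  mesh <- triangle_mesh(res$vertices, res$faces, validate = FALSE)
  cut_phantom_caps(mesh, spec)
}

#' Cut open inlet/outlet caps into a phantom surface
#'
#' Removes the faces covering each designated open end of the phantom's
#' centerlines (a plane cut about one local radius inward from the tube
#' end), producing the boundary loops that the deformation scaling gate
#' anchors to. Faces are assigned to their nearest tube first so a cut
#' never clips a neighbouring branch.
#'
#' @param mesh A [triangle_mesh()] of the phantom lumen (e.g. the
#'   ground-truth mesh after remeshing, with caps filled).
#' @param spec The [phantom_spec()] that generated the geometry.
#' @return The mesh with open caps (one boundary loop per open end).
#' @export
cut_phantom_caps <- function(mesh, spec) {
  step <- min(spec$spacing) / 2
  keep <- rep(TRUE, nrow(mesh$faces))
  fc <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
         mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
         mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  dense_all <- lapply(spec$centerlines, densify_centerline, step = step)
  # which tube does each face belong to? (nearest by signed tube distance,
  # so a cap cut never clips the wall of a neighbouring branch)
  owner_dist <- sapply(dense_all, function(d) {
    nn <- nearest_point_grid_cpp(fc, d$points)
    nn$distance - d$radii[nn$index]
  })
  owner <- max.col(-owner_dist)
  for (ci in seq_along(spec$centerlines)) {
    cl <- spec$centerlines[[ci]]
    dense <- dense_all[[ci]]
    np <- nrow(dense$points)
    ends <- list(list(i0 = 1L, i1 = 2L, open = cl$open_ends[1]),
                 list(i0 = np, i1 = np - 1L, open = cl$open_ends[2]))
    for (e in ends) {
      if (!e$open) next
      p_end <- dense$points[e$i0, ]
      r_end <- dense$radii[e$i0]
      inward <- dense$points[e$i1, ] - p_end
      inward <- inward / sqrt(sum(inward^2))
      # cut plane ~one radius inward from the end, normal = inward tangent:
      # drop this tube's faces whose centroid lies on the cap side
      plane_pt <- p_end + r_end * 0.8 * inward
      side <- (fc - matrix(plane_pt, nrow(fc), 3, byrow = TRUE)) %*% inward
      near <- sqrt(rowSums((fc - matrix(p_end, nrow(fc), 3,
                                        byrow = TRUE))^2)) < 2.5 * r_end
      keep <- keep & !(side < 0 & near & owner == ci)
    }
  }
  drop_unused_vertices(
    triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
                  validate = FALSE))
}

#' Convert a closed surface mesh to a binary voxel label (hole filling)
#'
#' For each voxel center the nearest mesh vertex is located; the voxel is
#' classified inside when the angle between that vertex's outward normal and
#' the vector from the voxel to the vertex is strictly below 90 degrees
#' (ties count as outside). This is the surface-to-voxel hole-filling rule
#' used to turn mesh-form ground truth into voxel labels.
#'
#' @param mesh A [triangle_mesh()]; open inlet/outlet caps are closed by
#'   centroid fans first when `fill_caps = TRUE`.
#' @param template A [scalar_volume()] supplying the output grid geometry.
#' @param fill_caps Close boundary loops before classification.
#' @return A [label_volume()] on the template grid.
#' @export
voxelize_surface <- function(mesh, template, fill_caps = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"),
            inherits(template, "scalar_volume"))
  if (fill_caps) mesh <- fill_mesh_caps(mesh)
  if (length(mesh_boundary_loops(mesh)) > 0L)
    stop("mesh must be closed (caps filled) for voxelization")
  vn <- vertex_normals(mesh)
  ensure_outward(mesh, vn)
  dims <- dim(template$values)
  ijk <- as.matrix(expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                               k = 0:(dims[3] - 1L)))
  centers <- index_to_world(template, ijk)
  nn <- nearest_point_grid_cpp(centers, mesh$vertices)
  to_vertex <- mesh$vertices[nn$index, , drop = FALSE] - centers
  inside <- rowSums(to_vertex * vn[nn$index, , drop = FALSE]) > 0
  label_volume(array(as.numeric(inside), dims), template$spacing,
               template$origin)
}

# flip all faces if vertex normals point inward on average (signed volume)
ensure_outward <- function(mesh, vn) {
  fn <- face_normals(mesh)
  fc <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
         mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
         mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  vol <- sum(rowSums(fc * fn$normals) * fn$areas) / 3
  if (vol < 0)
    stop("mesh orientation is inward; apply repair_orientation() first")
  invisible(TRUE)
}

#' Close the boundary loops of an open mesh with centroid fans
#'
#' @param mesh A [triangle_mesh()].
#' @return A watertight [triangle_mesh()]; unchanged if already closed.
#' @export
fill_mesh_caps <- function(mesh) {
  loops <- mesh_boundary_loops(mesh)
  if (length(loops) == 0L) return(mesh)
  v <- mesh$vertices; f <- mesh$faces
  # boundary edge -> its face, to orient cap fans opposite the rim face
  for (loop in loops) {
    centroid <- colMeans(v[loop, , drop = FALSE])
    cid <- nrow(v) + 1L
    v <- rbind(v, centroid)
    n <- length(loop)
    for (t in seq_len(n)) {
      a <- loop[t]; b <- loop[if (t == n) 1L else t + 1L]
      f <- rbind(f, c(b, a, cid))
    }
  }
  out <- triangle_mesh(v, f, validate = FALSE)
  out <- repair_orientation(out)
  out
}

#' Make face windings globally consistent and outward
#'
#' Breadth-first traversal over face adjacency flips faces so every shared
#' edge is traversed in opposite directions by its two faces; the whole
#' mesh is then flipped if its signed volume is negative.
#'
#' @param mesh A watertight or open [triangle_mesh()].
#' @return The reoriented mesh.
#' @export
repair_orientation <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  e <- face_edge_pairs(mesh)
  key <- paste(e[, 1], e[, 2])
  face_of <- split(rep(seq_len(nf), 3L), key)
  adj <- vector("list", nf)
  for (fs in face_of) {
    if (length(fs) == 2L) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  }
  visited <- rep(FALSE, nf)
  directed <- function(fc) list(c(fc[1], fc[2]), c(fc[2], fc[3]),
                                c(fc[3], fc[1]))
  for (start in seq_len(nf)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        # shared edge must appear in opposite directions
        de_cur <- directed(f[cur, ])
        de_nb <- directed(f[nb, ])
        flip <- FALSE
        for (a in de_cur) for (b in de_nb) {
          if (a[1] == b[1] && a[2] == b[2]) flip <- TRUE
        }
        if (flip) f[nb, ] <- f[nb, c(1L, 3L, 2L)]
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  out <- triangle_mesh(mesh$vertices, f, validate = FALSE)
  fn <- face_normals(out)
  fc <- (out$vertices[f[, 1], , drop = FALSE] +
         out$vertices[f[, 2], , drop = FALSE] +
         out$vertices[f[, 3], , drop = FALSE]) / 3
  vol <- sum(rowSums(fc * fn$normals) * fn$areas) / 3
  if (vol < 0) out$faces <- f[, c(1L, 3L, 2L)]
  out
}
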