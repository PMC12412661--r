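#' Triangular surface mesh
#'
#' Vertices are world-mm coordinates; faces index vertices (1-based).
#' Open meshes are allowed: edges incident to a single face form boundary
#' loops (vessel inlets/outlets). Orientation is taken from face winding.
#'
#' @param vertices n-by-3 numeric matrix of vertex positions (mm).
#' @param faces m-by-3 integer matrix of vertex indices (1-based).
#' @param validate Check structural invariants (default `TRUE`).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  if (nrow(vertices) == 0L || nrow(faces) == 0L)
    stop("empty mesh: need at least one vertex and one face")
  if (ncol(faces) != 3L) stop("faces must be an m-by-3 index matrix")
  storage.mode(faces) <- "integer"
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @exportS3Method base::print
print.triangle_mesh <- function(x, ...) {
  nb <- length(mesh_boundary_loops(x))
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, %d boundary loop(s)\n",
              nrow(x$vertices), nrow(x$faces), nb))
  invisible(x)
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate face repeats a vertex")
  cnt <- edge_face_count(mesh)
  if (any(cnt > 2L))
    stop("non-manifold edge shared by more than 2 faces")
  invisible(TRUE)
}

# m-by-3 edges as sorted index pairs, one row per face edge (3m rows)
face_edge_pairs <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_face_count <- function(mesh) {
  e <- face_edge_pairs(mesh)
  key <- paste(e[, 1], e[, 2])
  table(key)
}

#' Unique edges of a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @return 2-column integer matrix of unique undirected edges.
#' @export
mesh_edges <- function(mesh) {
  e <- face_edge_pairs(mesh)
  unique(e)
}

#' Per-face unit normals and areas
#'
#' Normals follow the face winding (counter-clockwise seen from outside for
#' an outward-oriented mesh).
#'
#' @param mesh A [triangle_mesh()].
#' @return List with `normals` (m-by-3, unit), `areas` (length m).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cross3(e1, e2)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  list(normals = cr / nrm, areas = sqrt(rowSums(cr^2)) / 2)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Area-weighted vertex normals
#'
#' Each vertex normal is the normalized sum of incident-face normals
#' weighted by face area.
#'
#' @param mesh A [triangle_mesh()].
#' @return n-by-3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  wn <- fn$normals * fn$areas
  out <- matrix(0, nrow(mesh$vertices), 3L)
  for (c in 1:3) {
    idx <- mesh$faces[, c]
    for (a in 1:3) {
      acc <- rowsum(wn[, a], idx)
      out[as.integer(rownames(acc)), a] <- out[as.integer(rownames(acc)), a] + acc
    }
  }
  nrm <- sqrt(rowSums(out^2))
  nrm[nrm == 0] <- 1
  out / nrm
}

#' Total surface area of a mesh (mm^2)
#' @param mesh A [triangle_mesh()].
#' @return Scalar area.
#' @export
mesh_area <- function(mesh) sum(face_normals(mesh)$areas)

#' Euler characteristic V - E + F
#' @param mesh A [triangle_mesh()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Ordered boundary loops of an open mesh
#'
#' Boundary edges (incident to exactly one face) are chained into closed
#' vertex cycles, one per opening (inlet/outlet cap).
#'
#' @param mesh A [triangle_mesh()].
#' @return List of integer vectors, each an ordered cycle of vertex indices;
#'   empty list for a watertight mesh.
#' @export
mesh_boundary_loops <- function(mesh) {
  e <- face_edge_pairs(mesh)
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  if (length(bkey) == 0L) return(list())
  be <- do.call(rbind, strsplit(bkey, " "))
  be <- matrix(as.integer(be), ncol = 2L)
  # adjacency: each boundary vertex has exactly 2 boundary neighbors
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  loops <- list()
  visited <- character(0)
  for (start in unique(c(be))) {
    if (as.character(start) %in% visited) next
    loop <- integer(0)
    prev <- NA_integer_; cur <- start
    repeat {
      loop <- c(loop, cur)
      visited <- c(visited, as.character(cur))
      nbrs <- adj[[as.character(cur)]]
      nxt <- setdiff(nbrs, loop)
      if (length(nxt) == 0L) break  # loop closed back to start
      prev <- cur; cur <- nxt[1L]
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Is the mesh watertight?
#' @param mesh A [triangle_mesh()].
#' @return `TRUE` if every edge is shared by exactly 2 faces.
#' @export
is_watertight <- function(mesh) all(edge_face_count(mesh) == 2L)

# merge vertices closer than tol; returns a triangle_mesh
merge_duplicate_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- apply(round(vertices / tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- vertices[first, , drop = FALSE]
  newf <- matrix(map[faces], ncol = 3L)
  keep <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] &
    newf[, 1] != newf[, 3]
  triangle_mesh(newv, newf[keep, , drop = FALSE], validate = FALSE)
}

# drop vertices not referenced by any face, remapping indices
drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices)); map[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(map[mesh$faces], ncol = 3L), validate = FALSE)
}
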