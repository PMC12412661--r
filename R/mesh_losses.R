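# Surface regularization losses and their analytic vertex gradients.
# All three are means over mesh elements, so their magnitudes are
# comparable across mesh resolutions.

# unique edges with adjacent face indices (face2 is NA on the boundary)
edge_face_adjacency <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e_sorted <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  face_id <- rep(seq_len(nf), 3L)
  ord <- order(e_sorted[, 1], e_sorted[, 2])
  es <- e_sorted[ord, , drop = FALSE]
  fo <- face_id[ord]
  first <- !duplicated(es)
  grp <- cumsum(first)
  edges <- es[first, , drop = FALSE]
  f1 <- fo[first]
  f2 <- rep(NA_integer_, nrow(edges))
  dup_pos <- which(!first)
  f2[grp[dup_pos]] <- fo[dup_pos]
  list(edges = edges, face1 = f1, face2 = f2)
}

#' Normal loss: misalignment of adjacent face normals
#'
#' Mean over interior edges of `1 - n1 . n2` where `n1`, `n2` are the unit
#' normals of the two faces sharing the edge. Zero for a planar mesh;
#' penalizes creases and folds.
#'
#' @param mesh A [triangle_mesh()].
#' @return Scalar loss.
#' @export
normal_loss <- function(mesh) {
  adj <- edge_face_adjacency(mesh)
  interior <- !is.na(adj$face2)
  if (!any(interior)) stop("mesh has no interior edges")
  fn <- face_normals(mesh)$normals
  n1 <- fn[adj$face1[interior], , drop = FALSE]
  n2 <- fn[adj$face2[interior], , drop = FALSE]
  mean(1 - rowSums(n1 * n2))
}

#' Edge loss: non-uniformity of edge lengths
#'
#' Mean squared deviation of edge lengths from their mesh-wide mean.
#'
#' @param mesh A [triangle_mesh()].
#' @return Scalar loss (mm^2).
#' @export
edge_loss <- function(mesh) {
  e <- mesh_edges(mesh)
  len <- edge_lengths(mesh, e)
  mean((len - mean(len))^2)
}

edge_lengths <- function(mesh, e = mesh_edges(mesh)) {
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                mesh$vertices[e[, 2], , drop = FALSE])^2))
}

#' Laplacian loss: deviation from the local neighbor centroid
#'
#' Mean squared distance between each vertex and the centroid of its
#' edge-connected neighbors. Vertices on boundary loops are excluded
#' (their neighbor centroid is biased inward by the missing fan).
#'
#' @param mesh A [triangle_mesh()].
#' @return Scalar loss (mm^2).
#' @export
laplacian_loss <- function(mesh) {
  lap <- laplacian_terms(mesh)
  if (lap$n == 0L) stop("no interior vertices with neighbors")
  sum(lap$d[lap$included, ]^2) / lap$n
}

# umbrella vectors d_i = v_i - mean(neighbors), plus inclusion mask
laplacian_terms <- function(mesh) {
  n <- nrow(mesh$vertices)
  e <- mesh_edges(mesh)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  centroid <- as.matrix(A %*% mesh$vertices) / deg
  d <- mesh$vertices - centroid
  boundary <- unique(unlist(mesh_boundary_loops(mesh)))
  included <- setdiff(seq_len(n), boundary)
  list(d = d, A = A, deg = deg, included = included, n = length(included))
}

# total weighted regularization loss and its analytic vertex gradient;
# weights = c(normal, edge, laplacian)
mesh_reg_loss_grad <- function(mesh, w_normal, w_edge, w_laplacian,
                               want_grad = TRUE) {
  v <- mesh$vertices
  n <- nrow(v)
  grad <- if (want_grad) matrix(0, n, 3L) else NULL
  # ---- edge loss ----
  e <- mesh_edges(mesh)
  len <- edge_lengths(mesh, e)
  lbar <- mean(len)
  L_edge <- mean((len - lbar)^2)
  if (want_grad && w_edge != 0) {
    u <- (v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE]) /
      pmax(len, 1e-12)
    coefs <- 2 * (len - lbar) / length(len)
    ge <- u * coefs
    for (c in 1:3) {
      grad[, c] <- grad[, c] + w_edge *
        (vec_accumulate(e[, 1], ge[, c], n) -
           vec_accumulate(e[, 2], ge[, c], n))
    }
  }
  # ---- laplacian loss ----
  lap <- laplacian_terms(mesh)
  L_lap <- if (lap$n > 0L) sum(lap$d[lap$included, ]^2) / lap$n else 0
  if (want_grad && w_laplacian != 0 && lap$n > 0L) {
    dmask <- lap$d
    dmask[-lap$included, ] <- 0
    # dL/dv = (2/NA) (I - Deg^-1 A)^T d_included
    gl <- dmask - as.matrix(Matrix::t(lap$A) %*% (dmask / lap$deg))
    grad <- grad + w_laplacian * (2 / lap$n) * gl
  }
  # ---- normal loss ----
  adj <- edge_face_adjacency(mesh)
  interior <- !is.na(adj$face2)
  fn <- face_normals(mesh)
  nrm <- fn$normals
  A2 <- 2 * fn$areas  # |cross| = 2 * area
  f1 <- adj$face1[interior]; f2 <- adj$face2[interior]
  nie <- length(f1)
  L_norm <- if (nie > 0L) mean(1 - rowSums(nrm[f1, , drop = FALSE] *
                                             nrm[f2, , drop = FALSE])) else 0
  if (want_grad && w_normal != 0 && nie > 0L) {
    fidx <- mesh$faces
    add_face_side <- function(faces_this, n_other) {
      # q = (I - n n^T) n_other / |cross| ; dL contribution -q via dN
      n_this <- nrm[faces_this, , drop = FALSE]
      q <- (n_other - rowSums(n_this * n_other) * n_this) /
        pmax(A2[faces_this], 1e-12)
      # vertex pullback: dN/dp_i = skew(w_i), w_1 = p3-p2, w_2 = p1-p3,
      # w_3 = p2-p1 ; grad_p_i += -(1/NIE) * (q x w_i) ... since
      # d(n1.n2) = q . dN and dN(e) = w_i x e => d = q.(w_i x e) =
      # e.(q x w_i)... careful with sign: q.(w x e) = e.(q x w)? Use
      # scalar triple identity q.(w x e) = e.(q x w).
      p1 <- fidx[faces_this, 1]; p2 <- fidx[faces_this, 2]
      p3 <- fidx[faces_this, 3]
      w1 <- v[p3, , drop = FALSE] - v[p2, , drop = FALSE]
      w2 <- v[p1, , drop = FALSE] - v[p3, , drop = FALSE]
      w3 <- v[p2, , drop = FALSE] - v[p1, , drop = FALSE]
      gl <- matrix(0, n, 3L)
      for (side in list(list(p = p1, w = w1), list(p = p2, w = w2),
                        list(p = p3, w = w3))) {
        contrib <- cross3(q, side$w)  # e-direction coefficient of d(n1.n2)
        for (c in 1:3)
          gl[, c] <- gl[, c] + vec_accumulate(side$p, contrib[, c], n)
      }
      gl
    }
    gn <- add_face_side(f1, nrm[f2, , drop = FALSE]) +
      add_face_side(f2, nrm[f1, , drop = FALSE])
    grad <- grad - w_normal * gn / nie
  }
  total <- w_normal * L_norm + w_edge * L_edge + w_laplacian * L_lap
  list(total = total, normal = L_norm, edge = L_edge, laplacian = L_lap,
       grad = grad)
}

# sum `x` into bins given by `idx` over 1..n
vec_accumulate <- function(idx, x, n) {
  out <- numeric(n)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}
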