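#' Gaussian interpolation kernel
#'
#' `K(x, y) = exp(-||x - y||^2 / sigma^2)`: the reproducing kernel that
#' spreads control-point momenta into a smooth velocity field. `K(x,x)=1`
#' and `K = 1/e` at distance `sigma`.
#'
#' @param x,y n-by-3 matrices (or length-3 vectors) of points (mm).
#' @param sigma Kernel width in mm (> 0).
#' @return Vector of kernel values in `(0, 1]` (rowwise).
#' @export
gaussian_kernel <- function(x, y, sigma) {
  stopifnot(sigma > 0)
  x <- as_points(x); y <- as_points(y)
  exp(-rowSums((x - y)^2) / sigma^2)
}

# full kernel matrix K[i,j] = exp(-|a_i - b_j|^2 / sigma^2)
kernel_matrix <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  exp(-pmax(d2, 0) / sigma^2)
}

#' Control-point system for diffeomorphic surface flow
#'
#' Bundles control points, their momenta, the kernel width, and the time
#' discretization of the Hamiltonian flow.
#'
#' @param points N_s-by-3 matrix of control points (mm).
#' @param momenta N_s-by-3 matrix of momenta.
#' @param sigma_k Gaussian kernel width (mm).
#' @param t_span Flow duration (default 1).
#' @param steps Number of integration steps (default 15).
#' @return A list of class `control_point_system`.
#' @export
control_point_system <- function(points, momenta, sigma_k, t_span = 1,
                                 steps = 15L) {
  points <- as_points(points); momenta <- as_points(momenta)
  stopifnot(nrow(points) >= 1L, nrow(points) == nrow(momenta),
            sigma_k > 0, steps >= 1L)
  structure(list(points = points, momenta = momenta, sigma_k = sigma_k,
                 t_span = t_span, steps = as.integer(steps)),
            class = "control_point_system")
}

#' Farthest-point subsampling of mesh vertices into control points
#'
#' Greedy farthest-point sampling from a seeded start vertex: each added
#' point maximizes the distance to the already-chosen set, giving
#' near-uniform coverage of the surface.
#'
#' @param mesh A [triangle_mesh()].
#' @param n_s Number of control points (<= vertex count).
#' @param seed Seed selecting the start vertex.
#' @return Integer vector of `n_s` vertex indices.
#' @export
subsample_control_points <- function(mesh, n_s, seed = 1L) {
  v <- mesh$vertices
  n <- nrow(v)
  if (n_s > n) stop("n_s (", n_s, ") exceeds vertex count (", n, ")")
  if (n_s == n) return(seq_len(n))
  start <- with_seed(seed, sample.int(n, 1L))
  chosen <- integer(n_s)
  chosen[1L] <- start
  mind <- rowSums(sweep(v, 2L, v[start, ], "-")^2)
  for (i in seq_len(n_s - 1L)) {
    nxt <- which.max(mind)
    chosen[i + 1L] <- nxt
    mind <- pmin(mind, rowSums(sweep(v, 2L, v[nxt, ], "-")^2))
  }
  chosen
}

#' Velocity field induced by a control-point system
#'
#' `v(x) = sum_i K(x, s_i) xi_i`: kernel interpolation of the momenta;
#' linear in the momenta.
#'
#' @param points Query points (n-by-3 mm).
#' @param cps A [control_point_system()].
#' @return n-by-3 matrix of velocities.
#' @export
velocity_field <- function(points, cps) {
  K <- kernel_matrix(as_points(points), cps$points, cps$sigma_k)
  K %*% cps$momenta
}

#' Hamiltonian right-hand side of the control-point dynamics
#'
#' `ds/dt = K(s,s) xi` and `dxi/dt = -(1/2) grad_s [xi^T K(s,s) xi]`, with
#' the analytic gradient of the Gaussian kernel.
#'
#' @param cps A [control_point_system()].
#' @return List with `ds` and `dxi` (N_s-by-3 each).
#' @export
hamiltonian_rhs <- function(cps) {
  s <- cps$points; xi <- cps$momenta
  K <- kernel_matrix(s, s, cps$sigma_k)
  ds <- K %*% xi
  ip <- xi %*% t(xi)          # xi_i . xi_j
  Wt <- ip * K * (2 / cps$sigma_k^2)
  # dxi_i = sum_j Wt_ij (s_i - s_j)
  dxi <- s * rowSums(Wt) - Wt %*% s
  list(ds = ds, dxi = dxi)
}

# kinetic energy H = 1/2 xi^T K(s,s) xi (conserved by the exact flow)
hamiltonian_energy <- function(cps) {
  K <- kernel_matrix(cps$points, cps$points, cps$sigma_k)
  0.5 * sum((K %*% cps$momenta) * cps$momenta)
}

#' Integrate the diffeomorphic flow carrying a mesh
#'
#' Second-order (midpoint) Runge-Kutta co-integration of control points,
#' momenta, and all mesh vertices over `t_span` divided into `steps`
#' steps. With zero momenta the map is the exact identity. An optional
#' per-vertex mobility field (the scaling gate) multiplies the carried
#' vertex velocity, freezing gated regions exactly.
#'
#' @param mesh A [triangle_mesh()].
#' @param cps A [control_point_system()].
#' @param vertex_alpha Optional per-vertex mobility in `[0, 1]`.
#' @return List with `mesh` (deformed), `cps` (final state), `hamiltonian`
#'   (energy at each step, constant under exact dynamics).
#' @export
integrate_flow <- function(mesh, cps, vertex_alpha = NULL) {
  x <- mesh$vertices
  s <- cps$points; xi <- cps$momenta
  sk <- cps$sigma_k
  dt <- cps$t_span / cps$steps
  alpha <- if (is.null(vertex_alpha)) 1 else vertex_alpha
  H <- numeric(cps$steps + 1L)
  H[1L] <- hamiltonian_energy(cps)
  for (st in seq_len(cps$steps)) {
    r1 <- hamiltonian_rhs(control_point_system(s, xi, sk, steps = 1L))
    vx1 <- kernel_matrix(x, s, sk) %*% xi
    s_m <- s + dt / 2 * r1$ds
    xi_m <- xi + dt / 2 * r1$dxi
    x_m <- x + dt / 2 * (alpha * vx1)
    r2 <- hamiltonian_rhs(control_point_system(s_m, xi_m, sk, steps = 1L))
    vx2 <- kernel_matrix(x_m, s_m, sk) %*% xi_m
    s <- s + dt * r2$ds
    xi <- xi + dt * r2$dxi
    x <- x + dt * (alpha * vx2)
    if (any(!is.finite(s)) || any(!is.finite(x)))
      stop("flow diverged at step ", st, " (non-finite state)")
    H[st + 1L] <- hamiltonian_energy(control_point_system(s, xi, sk,
                                                          steps = 1L))
  }
  out <- mesh
  out$vertices <- x
  list(mesh = out, cps = control_point_system(s, xi, sk, cps$t_span,
                                              cps$steps),
       hamiltonian = H)
}

# ---- scaling gate ----

#' Detect inlet/outlet caps from mesh boundary loops
#'
#' One cap per boundary loop: the center is the centroid of the loop (the
#' middle of the opening) and the cap radius is the largest distance from
#' the center to the loop vertices — for a circular opening of a tube of
#' radius r this recovers r.
#'
#' @param mesh A [triangle_mesh()].
#' @return List of caps, each `list(center, radius, loop)`; empty for a
#'   watertight mesh.
#' @export
detect_caps <- function(mesh) {
  loops <- mesh_boundary_loops(mesh)
  if (length(loops) == 0L) return(list())
  lapply(loops, function(loop) {
    pts <- mesh$vertices[loop, , drop = FALSE]
    centroid <- colMeans(pts)
    d <- sqrt(rowSums(sweep(pts, 2L, centroid, "-")^2))
    # mean distance: robust to the jagged rims of voxel-derived meshes
    list(center = centroid, radius = mean(d), loop = loop)
  })
}

mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- edge_lengths(mesh, e)
  g
}

#' Scaling-gate mobility field over the mesh
#'
#' Per-vertex scalar field: 0 within each cap's radius `r_i` of its
#' center, `1 - exp(-(d - r_i)^2 / (2 sigma^2))` in the buffer zone
#' `r_i <= d < r_i + 3 sigma`, and 1 beyond — freezing inlet/outlet
#' regions while leaving the vessel wall fully mobile. For multiple caps
#' the most restrictive (smallest) value wins.
#'
#' @param mesh A [triangle_mesh()].
#' @param caps Caps from [detect_caps()] (detected automatically if
#'   `NULL`).
#' @param sigma_g Buffer width in mm; default a quarter of each cap's
#'   radius.
#' @return List of class `scaling_gate_field`: `alpha` (per vertex in
#'   `[0, 1]`), `caps`, `sigma_g`.
#' @export
compute_scaling_field <- function(mesh, caps = NULL, sigma_g = NULL) {
  if (is.null(caps)) caps <- detect_caps(mesh)
  n <- nrow(mesh$vertices)
  if (length(caps) == 0L) {
    warning("mesh has no boundary caps; scaling field is all ones")
    return(structure(list(alpha = rep(1, n), caps = caps,
                          sigma_g = sigma_g),
                     class = "scaling_gate_field"))
  }
  alpha <- rep(1, n)
  for (cap in caps) {
    sg <- if (is.null(sigma_g)) cap$radius / 4 else sigma_g
    d <- sqrt(rowSums(sweep(mesh$vertices, 2L, cap$center, "-")^2))
    a <- ifelse(d < cap$radius, 0,
                ifelse(d < cap$radius + 3 * sg,
                       1 - exp(-(d - cap$radius)^2 / (2 * sg^2)), 1))
    # rim vertices are the cap boundary itself: always fully immobilized
    a[cap$loop] <- 0
    alpha <- pmin(alpha, a)
  }
  structure(list(alpha = alpha, caps = caps, sigma_g = sigma_g),
            class = "scaling_gate_field")
}

#' Gate control-point momenta by the scaling field
#'
#' Multiplies each momentum by the mobility of its control-point vertex
#' before integration, immobilizing cap regions.
#'
#' @param momenta N_s-by-3 momenta.
#' @param gate A [compute_scaling_field()] result.
#' @param cp_index Vertex indices of the control points.
#' @return Gated momenta.
#' @export
apply_gate <- function(momenta, gate, cp_index) {
  momenta * gate$alpha[cp_index]
}

# ---- unsupervised alignment objective ----

#' Image-misalignment energy of a surface point cloud
#'
#' `-w1 * log(sum_i G(s_i) + eps)` where `G` is the gradient-magnitude
#' volume sampled trilinearly at the surface points: minimized when the
#' surface sits on strong image gradients (the vessel wall).
#'
#' @param points n-by-3 surface points (mm).
#' @param gradmag A [scalar_volume()] of gradient magnitudes.
#' @param w1 Energy weight (default 1).
#' @param eps Stabilizer inside the log (default 1e-8).
#' @return Scalar energy.
#' @export
misalignment_energy <- function(points, gradmag, w1 = 1, eps = 1e-8) {
  G <- sample_trilinear(gradmag, points)
  -w1 * log(sum(G) + eps)
}

#' Configuration of the unsupervised surface deformation
#'
#' @param w1,w2,w3,w4 Weights of misalignment energy, normal, edge, and
#'   Laplacian losses (defaults 1.0, 0.2, 0.01, 0.1).
#' @param epochs Optimization epochs (default 300).
#' @param learning_rate Adam step size for the predictor (default 2e-3).
#' @param n_s Number of control points (default 300).
#' @param sigma_k Kernel width in mm; default 2x the mean nearest-neighbor
#'   spacing of the control points.
#' @param sigma_g Gate buffer width in mm; default half each cap radius.
#' @param steps,t_span Flow discretization (defaults 15 and 1).
#' @param hidden,cheb_order Predictor width and Chebyshev order.
#' @param energy_eps Stabilizer inside the energy log.
#' @param presmooth_sigma Gaussian presmoothing (voxels) of the gradient
#'   volume.
#' @param seed Master seed.
#' @return A list of class `deform_config`.
#' @export
deform_config <- function(w1 = 1.0, w2 = 0.2, w3 = 0.01, w4 = 0.1,
                          epochs = 300L, learning_rate = 2e-3, n_s = 300L,
                          sigma_k = NULL, sigma_g = NULL, steps = 15L,
                          t_span = 1, hidden = 64L, cheb_order = 3L,
                          energy_eps = 1e-8, presmooth_sigma = 1,
                          seed = 1L) {
  stopifnot(w1 >= 0, w2 >= 0, w3 >= 0, w4 >= 0, epochs >= 1L, n_s >= 1L,
            steps >= 1L, learning_rate > 0)
  structure(as.list(environment()), class = "deform_config")
}

#' Total deformation loss with components
#'
#' `w1`-weighted misalignment energy plus the three weighted mesh
#' regularizers.
#'
#' @param mesh A [triangle_mesh()].
#' @param gradmag Gradient-magnitude [scalar_volume()].
#' @param config A [deform_config()].
#' @return List with `total`, `energy`, `normal`, `edge`, `laplacian`.
#' @export
total_loss <- function(mesh, gradmag, config = deform_config()) {
  energy <- if (config$w1 > 0)
    misalignment_energy(mesh$vertices, gradmag, config$w1,
                        config$energy_eps) else 0
  reg <- mesh_reg_loss_grad(mesh, config$w2, config$w3, config$w4,
                            want_grad = FALSE)
  list(total = energy + reg$total, energy = energy, normal = reg$normal,
       edge = reg$edge, laplacian = reg$laplacian)
}

# gradient of the total loss w.r.t. vertex positions
total_loss_grad <- function(mesh, energy_vol, config) {
  reg <- mesh_reg_loss_grad(mesh, config$w2, config$w3, config$w4)
  G <- sample_trilinear(energy_vol$gradmag, mesh$vertices)
  denom <- sum(G) + config$energy_eps
  gG <- sapply(energy_vol$gradgrad, function(gv)
    sample_trilinear(gv, mesh$vertices))
  grad <- reg$grad - config$w1 / denom * gG
  energy <- -config$w1 * log(denom)
  list(total = energy + reg$total, energy = energy, normal = reg$normal,
       edge = reg$edge, laplacian = reg$laplacian, grad = grad)
}

# gradient-magnitude volume plus its own spatial gradient (for the energy
# chain rule)
prepare_energy_volume <- function(image, presmooth_sigma = 1) {
  gradmag <- gradient_magnitude_volume(image, presmooth_sigma)
  comps <- volume_gradient(gradmag, 0)
  gradgrad <- lapply(comps, function(c)
    scalar_volume(c, image$spacing, image$origin))
  list(gradmag = gradmag, gradgrad = gradgrad)
}

#' Unsupervised diffeomorphic surface alignment to an image
#'
#' Per-case self-supervised optimization: a Chebyshev graph network
#' predicts per-vertex momenta from the surface geometry; momenta at
#' control-point vertices (gated at inlets/outlets) drive a Hamiltonian
#' LDDMM flow that deforms the surface; the total loss (image
#' misalignment energy plus mesh regularizers) is backpropagated into the
#' predictor weights through a first-order sensitivity of the flow
#' endpoint. Returns the best iterate by total loss.
#'
#' With `method = "direct"`, per-vertex displacements are optimized
#' directly (no flow, no predictor) — the ablation baseline.
#'
#' @param mesh Initial surface ([triangle_mesh()]), roughly at the target
#'   boundary.
#' @param image A [scalar_volume()] (raw or normalized intensities).
#' @param config A [deform_config()].
#' @param method `"gnn-lddmm"` (default) or `"direct"`.
#' @param use_gate Apply the inlet/outlet scaling gate (default `TRUE`).
#' @return List of class `deform_fit`: `mesh` (best deformed surface),
#'   `history` (loss components per epoch), `alpha` (vertex mobility),
#'   `cp_index`, `config`.
#' @export
optimize_deformation <- function(mesh, image, config = deform_config(),
                                 method = c("gnn-lddmm", "direct"),
                                 use_gate = TRUE) {
  method <- match.arg(method)
  ev <- prepare_energy_volume(image, config$presmooth_sigma)
  caps <- detect_caps(mesh)
  gate <- if (use_gate && length(caps) > 0L)
    compute_scaling_field(mesh, caps, config$sigma_g)
  else list(alpha = rep(1, nrow(mesh$vertices)), caps = caps)
  n_s <- min(config$n_s, nrow(mesh$vertices))
  cp_idx <- subsample_control_points(mesh, n_s, seed = config$seed)
  cp0 <- mesh$vertices[cp_idx, , drop = FALSE]
  sigma_k <- config$sigma_k
  if (is.null(sigma_k)) {
    dd <- as.matrix(stats::dist(cp0))
    diag(dd) <- Inf
    sigma_k <- 2 * mean(apply(dd, 1L, min))
  }
  alpha_cp <- gate$alpha[cp_idx]
  alpha_v <- gate$alpha
  history <- vector("list", config$epochs)
  best <- NULL
  if (method == "gnn-lddmm") {
    pred <- momentum_predictor(config$hidden, config$cheb_order,
                               seed = config$seed)
    st <- predictor_adam_init(pred)
    K0 <- kernel_matrix(mesh$vertices, cp0, sigma_k)
    for (ep in seq_len(config$epochs)) {
      m_all <- predict_momentum(mesh, pred)
      cache <- attr(m_all, "cache")
      xi <- m_all[cp_idx, , drop = FALSE] * alpha_cp
      cps <- control_point_system(cp0, xi, sigma_k, config$t_span,
                                  config$steps)
      flow <- integrate_flow(mesh, cps, vertex_alpha = alpha_v)
      lg <- total_loss_grad(flow$mesh, ev, config)
      if (!is.finite(lg$total)) {
        warning("non-finite loss at epoch ", ep, "; stopping early")
        history <- history[seq_len(ep - 1L)]
        break
      }
      if (is.null(best) || lg$total < best$total)
        best <- list(total = lg$total, mesh = flow$mesh, epoch = ep)
      # first-order endpoint sensitivity: dx_v/dxi_i ~ T * alpha_v K0 diag
      dxi <- config$t_span * (t(K0) %*% (alpha_v * lg$grad)) * alpha_cp
      dm <- matrix(0, nrow(m_all), 3L)
      dm[cp_idx, ] <- as.matrix(dxi)
      grads <- predictor_backward(pred, cache, dm)
      upd <- predictor_adam_update(pred, grads, st, config$learning_rate)
      pred <- upd$predictor
      st <- upd$state
      history[[ep]] <- data.frame(epoch = ep, total = lg$total,
                                  energy = lg$energy, normal = lg$normal,
                                  edge = lg$edge, laplacian = lg$laplacian)
    }
  } else {
    disp <- matrix(0, nrow(mesh$vertices), 3L)
    m_adam <- list(t = 0L, m = disp, v = disp)
    for (ep in seq_len(config$epochs)) {
      cand <- mesh
      cand$vertices <- mesh$vertices + alpha_v * disp
      lg <- total_loss_grad(cand, ev, config)
      if (!is.finite(lg$total)) {
        warning("non-finite loss at epoch ", ep, "; stopping early")
        history <- history[seq_len(ep - 1L)]
        break
      }
      if (is.null(best) || lg$total < best$total)
        best <- list(total = lg$total, mesh = cand, epoch = ep)
      g <- alpha_v * lg$grad
      m_adam$t <- m_adam$t + 1L
      m_adam$m <- 0.9 * m_adam$m + 0.1 * g
      m_adam$v <- 0.999 * m_adam$v + 0.001 * g^2
      mhat <- m_adam$m / (1 - 0.9^m_adam$t)
      vhat <- m_adam$v / (1 - 0.999^m_adam$t)
      disp <- disp - config$learning_rate * mhat / (sqrt(vhat) + 1e-8)
      history[[ep]] <- data.frame(epoch = ep, total = lg$total,
                                  energy = lg$energy, normal = lg$normal,
                                  edge = lg$edge, laplacian = lg$laplacian)
    }
  }
  structure(list(mesh = best$mesh, best_epoch = best$epoch,
                 history = do.call(rbind, history), alpha = alpha_v,
                 cp_index = cp_idx, sigma_k = sigma_k, config = config,
                 method = method, gate = gate),
            class = "deform_fit")
}
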