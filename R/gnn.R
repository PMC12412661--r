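# Chebyshev spectral graph-convolution momentum predictor.
# Two blocks, each two ChebConv layers with a residual connection; input
# features are the centered/scale-normalized vertex coordinates, output is
# a 3-vector (initial momentum) per vertex. Permutation-equivariant by
# construction (all operators act through the graph Laplacian).

# scaled Laplacian operator L_hat = L - I = -D^{-1/2} A D^{-1/2}
# (lambda_max of the normalized Laplacian approximated by 2)
mesh_cheb_operator <- function(mesh) {
  n <- nrow(mesh$vertices)
  e <- mesh_edges(mesh)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0))
    warning("mesh graph has isolated vertices; they receive zero momentum")
  dis <- 1 / sqrt(pmax(deg, 1))
  -Matrix::Diagonal(n, dis) %*% A %*% Matrix::Diagonal(n, dis)
}

cheb_layer_init <- function(n_in, n_out, order, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (n_in * order))
  list(W = lapply(seq_len(order), function(k)
    matrix(rnorm(n_in * n_out, sd = scale), n_in, n_out)),
    b = numeric(n_out))
}

# forward: y = sum_k T_k(L_hat) X W_k + b ; caches the T_k X bases
cheb_forward <- function(Lhat, X, layer) {
  order <- length(layer$W)
  Tk <- vector("list", order)
  Tk[[1]] <- X
  if (order >= 2L) Tk[[2]] <- as.matrix(Lhat %*% X)
  if (order >= 3L) for (k in 3:order)
    Tk[[k]] <- as.matrix(2 * (Lhat %*% Tk[[k - 1]])) - Tk[[k - 2]]
  y <- matrix(0, nrow(X), ncol(layer$W[[1]]))
  for (k in seq_len(order)) y <- y + Tk[[k]] %*% layer$W[[k]]
  y <- sweep(y, 2L, layer$b, "+")
  attr(y, "Tk") <- Tk
  y
}

# backward: gradients for W_k, b and the input X (T_k symmetric in L_hat)
cheb_backward <- function(Lhat, layer, Tk, dY) {
  order <- length(layer$W)
  dW <- vector("list", order)
  for (k in seq_len(order)) dW[[k]] <- crossprod(Tk[[k]], dY)
  db <- colSums(dY)
  # dX via the recurrence run on dY: sum_k T_k(L_hat) dY W_k^T
  Sk <- dY
  dX <- Sk %*% t(layer$W[[1]])
  if (order >= 2L) {
    Skm1 <- Sk
    Sk <- as.matrix(Lhat %*% dY)
    dX <- dX + Sk %*% t(layer$W[[2]])
    if (order >= 3L) for (k in 3:order) {
      Snew <- as.matrix(2 * (Lhat %*% Sk)) - Skm1
      Skm1 <- Sk
      Sk <- Snew
      dX <- dX + Sk %*% t(layer$W[[k]])
    }
  }
  list(dW = dW, db = db, dX = dX)
}

#' Initialize the graph momentum predictor
#'
#' Two blocks of two Chebyshev graph-convolution layers with residual
#' connections, followed by a zero-initialized linear read-out to a
#' 3-vector per vertex (so the initial momentum field is exactly zero
#' before optimization).
#'
#' @param hidden Hidden width (default 64).
#' @param order Chebyshev polynomial order (default 3).
#' @param seed Seed for weight initialization.
#' @return A list of class `momentum_predictor`.
#' @export
momentum_predictor <- function(hidden = 64L, order = 3L, seed = 1L) {
  stopifnot(hidden >= 1L, order >= 1L)
  with_seed(seed, {
    p <- list(
      b1c1 = cheb_layer_init(3L, hidden, order),
      b1c2 = cheb_layer_init(hidden, hidden, order),
      proj1 = list(W = matrix(rnorm(3L * hidden, sd = sqrt(2 / 3)), 3L,
                              hidden)),
      b2c1 = cheb_layer_init(hidden, hidden, order),
      b2c2 = cheb_layer_init(hidden, hidden, order),
      out = list(W = matrix(0, hidden, 3L), b = numeric(3L)))
    structure(list(params = p, hidden = as.integer(hidden),
                   order = as.integer(order)),
              class = "momentum_predictor")
  })
}

# normalized input features: centered coordinates / RMS radius
predictor_features <- function(mesh) {
  X <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices), "-")
  X / sqrt(mean(rowSums(X^2)))
}

#' Predict a per-vertex momentum field on a mesh
#'
#' Runs the Chebyshev predictor on the mesh graph using normalized vertex
#' coordinates as input features. Equivariant under vertex permutation.
#'
#' @param mesh A [triangle_mesh()].
#' @param predictor A [momentum_predictor()].
#' @return n-by-3 matrix of momenta; forward cache attached as attribute
#'   `cache` for the training backward pass.
#' @export
predict_momentum <- function(mesh, predictor) {
  Lhat <- mesh_cheb_operator(mesh)
  X <- predictor_features(mesh)
  p <- predictor$params
  c1 <- cheb_forward(Lhat, X, p$b1c1)
  a1 <- pmax(c1, 0)
  c2 <- cheb_forward(Lhat, a1, p$b1c2)
  r1 <- c2 + X %*% p$proj1$W
  h1 <- pmax(r1, 0)
  c3 <- cheb_forward(Lhat, h1, p$b2c1)
  a3 <- pmax(c3, 0)
  c4 <- cheb_forward(Lhat, a3, p$b2c2)
  r2 <- c4 + h1
  h2 <- pmax(r2, 0)
  out <- sweep(h2 %*% p$out$W, 2L, p$out$b, "+")
  attr(out, "cache") <- list(Lhat = Lhat, X = X, c1 = c1, a1 = a1, c2 = c2,
                             r1 = r1, h1 = h1, c3 = c3, a3 = a3, c4 = c4,
                             r2 = r2, h2 = h2)
  out
}

# backward pass: gradient of a scalar loss w.r.t. all predictor parameters
predictor_backward <- function(predictor, cache, dout) {
  p <- predictor$params
  g <- list()
  g$out <- list(W = crossprod(cache$h2, dout), b = colSums(dout))
  dh2 <- dout %*% t(p$out$W)
  dr2 <- dh2 * (cache$r2 > 0)
  bc4 <- cheb_backward(cache$Lhat, p$b2c2, attr(cache$c4, "Tk"), dr2)
  g$b2c2 <- list(W = bc4$dW, b = bc4$db)
  da3 <- bc4$dX
  dc3 <- da3 * (cache$c3 > 0)
  bc3 <- cheb_backward(cache$Lhat, p$b2c1, attr(cache$c3, "Tk"), dc3)
  g$b2c1 <- list(W = bc3$dW, b = bc3$db)
  dh1 <- bc3$dX + dr2  # residual path
  dr1 <- dh1 * (cache$r1 > 0)
  bc2 <- cheb_backward(cache$Lhat, p$b1c2, attr(cache$c2, "Tk"), dr1)
  g$b1c2 <- list(W = bc2$dW, b = bc2$db)
  g$proj1 <- list(W = crossprod(cache$X, dr1))
  da1 <- bc2$dX
  dc1 <- da1 * (cache$c1 > 0)
  bc1 <- cheb_backward(cache$Lhat, p$b1c1, attr(cache$c1, "Tk"), dc1)
  g$b1c1 <- list(W = bc1$dW, b = bc1$db)
  g
}

predictor_adam_init <- function(predictor) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(t = 0L, m = zero_like(predictor$params),
       v = zero_like(predictor$params))
}

predictor_adam_update <- function(predictor, grads, st, lr, b1 = 0.9,
                                  b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  upd <- function(val, g, m, v) {
    if (is.list(val)) {
      out <- list(val = val, m = m, v = v)
      for (nm in names(val)) {
        if (is.null(g[[nm]])) next
        r <- upd(val[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$val[[nm]] <- r$val; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^st$t)
    vhat <- v / (1 - b2^st$t)
    list(val = val - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(predictor$params, grads, st$m, st$v)
  predictor$params <- r$val
  st$m <- r$m
  st$v <- r$v
  list(predictor = predictor, state = st)
}
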