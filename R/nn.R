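# Internal neural-network engine for the segmentation model: a small 3D
# U-Net ("regular stream"), a bank of Bayesian LoG convolutions ("LoG
# stream"), and a dilated-convolution fusion block (ASPP). Forward passes
# cache activations; backward passes are hand-derived reverse mode over the
# C++ convolution kernels. Tensors are R arrays (nx, ny, nz, channels).

as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

conv_fwd <- function(x, W, b, k, dil = 1L, pad_mode = 0L) {
  conv3d_forward_cpp(as4d(x), W, b, as.integer(k), as.integer(dil),
                     as.integer(pad_mode))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

upsample2 <- function(x) {
  x <- as4d(x)
  d <- dim(x)
  idx <- function(n) rep(seq_len(n), each = 2L)
  x[idx(d[1]), idx(d[2]), idx(d[3]), , drop = FALSE]
}

upsample2_bwd <- function(dout) {
  dout <- as4d(dout)
  d <- dim(dout)
  half <- function(n) (seq_len(n) + 1L) %/% 2L
  # sum gradients over each 2x2x2 block
  out <- array(0, c(d[1] / 2L, d[2] / 2L, d[3] / 2L, d[4]))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    out <- out + dout[seq(1L + dx, d[1], 2L), seq(1L + dy, d[2], 2L),
                      seq(1L + dz, d[3], 2L), , drop = FALSE]
  }
  out
}

maxpool_fwd <- function(x) maxpool2_cpp(as4d(x))

maxpool_bwd <- function(dout, argmax, xdim) {
  dx <- numeric(prod(xdim))
  # accumulate (argmax entries are unique per pooled cell but can repeat
  # across channels only via distinct linear indices, so direct add is safe)
  tab <- rowsum(as.vector(dout), argmax)
  dx[as.integer(rownames(tab))] <- tab
  dim(dx) <- xdim
  dx
}

concat_ch <- function(lst) {
  lst <- lapply(lst, as4d)
  d <- dim(lst[[1L]])[1:3]
  arr <- array(0, c(d, sum(vapply(lst, function(x) dim(x)[4L], 0L))))
  off <- 0L
  for (x in lst) {
    nc <- dim(x)[4L]
    arr[, , , (off + 1L):(off + nc)] <- x
    off <- off + nc
  }
  arr
}

split_ch <- function(x, sizes) {
  out <- vector("list", length(sizes))
  off <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, , , (off + 1L):(off + sizes[i]), drop = FALSE]
    off <- off + sizes[i]
  }
  out
}

he_init <- function(rows, cols) {
  matrix(rnorm(rows * cols, sd = sqrt(2 / rows)), rows, cols)
}

# ---- model construction ----

#' Configuration of the multiscale Bayesian segmentation model
#'
#' Architecture and training hyper-parameters. The reference-scale training
#' setup uses a learning rate of 1e-5 and batches of 8 patches of side 64;
#' test-scale runs use far smaller settings (see the package vignette).
#'
#' @param patch_size Cubic patch side in voxels; must be divisible by
#'   `2^(depth-1)`.
#' @param base_channels U-Net channels at full resolution (doubled per
#'   level).
#' @param depth Number of U-Net resolution levels.
#' @param log_sizes,log_sigmas LoG bank kernel sizes (odd) and scales.
#' @param prior_sds Per-level prior SDs of the Bayesian LoG kernels.
#' @param init_log_sd Initial posterior log-SD of the LoG kernel weights.
#' @param aspp_rates Dilation rates of the fusion block.
#' @param learning_rate,batch_size,epochs,mc_samples,kl_scale Optimization
#'   settings; `batch_size` is used when training without the balanced
#'   gate, otherwise the gate's `draw` per class sets the batch.
#'   `kl_scale = NULL` defaults to 1/(patches per epoch) at training time.
#' @param vp_tau Voxel-percentage threshold on LoG features (gate input).
#' @param gate_beta Class threshold: voxel percentage at or above this is
#'   a "main" patch, below is "branch".
#' @param gate_capacity,gate_draw Candidate pool capacity and per-class
#'   draw of the balanced gate.
#' @param seed Master seed for initialization and training.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(patch_size = 64L, base_channels = 16L, depth = 3L,
                       log_sizes = c(3L, 5L, 7L, 9L, 11L),
                       log_sigmas = c(0.5, 1.0, 1.5, 2.0, 2.5),
                       prior_sds = c(0.5, 1.0, 1.5, 2.0, 2.5),
                       init_log_sd = log(0.02),
                       aspp_rates = c(1L, 2L, 4L),
                       learning_rate = 1e-5, batch_size = 8L, epochs = 10L,
                       mc_samples = 1L, kl_scale = NULL, vp_tau = 0.5,
                       gate_beta = 0.15, gate_capacity = 10L,
                       gate_draw = 5L, seed = 1L) {
  nl <- length(log_sizes)
  stopifnot(length(log_sigmas) == nl, nl >= 1L,
            patch_size %% 2^(depth - 1L) == 0L,
            all(log_sizes %% 2L == 1L), all(log_sigmas > 0),
            learning_rate > 0, batch_size >= 1L, gate_draw <= gate_capacity)
  prior_sds <- rep_len(prior_sds, nl)
  structure(as.list(environment()), class = "seg_config")
}

#' Initialize a segmentation model
#'
#' Builds the parameter set: Bayesian LoG-stream kernels (posterior means
#' initialized to the precomputed LoG bank), U-Net encoder/decoder weights
#' (He initialization), and the dilated fusion block.
#'
#' @param config A [seg_config()].
#' @return A list of class `seg_model` with `params`, `variational`,
#'   `config`.
#' @export
seg_model_init <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  C <- config$base_channels
  D <- config$depth
  L <- length(config$log_sizes)
  ch <- C * 2^(seq_len(D) - 1L)
  with_seed(config$seed, {
    params <- list()
    inc <- 1L
    for (l in seq_len(D)) {
      params[[paste0("enc", l, "_W")]] <- he_init(inc * 27L, ch[l])
      params[[paste0("enc", l, "_b")]] <- numeric(ch[l])
      inc <- ch[l]
    }
    for (l in seq(D - 1L, 1L)) {
      if (D == 1L) break
      params[[paste0("dec", l, "_W")]] <- he_init((ch[l + 1L] + ch[l]) * 27L,
                                                  ch[l])
      params[[paste0("dec", l, "_b")]] <- numeric(ch[l])
    }
    fuse_in <- C + L
    for (r in config$aspp_rates) {
      params[[paste0("aspp", r, "_W")]] <- he_init(fuse_in * 27L, C)
      params[[paste0("aspp", r, "_b")]] <- numeric(C)
    }
    params$out_W <- he_init(C, 1L)
    params$out_b <- 0
    variational <- lapply(seq_len(L), function(i) {
      k <- build_log_kernel(config$log_sizes[i], config$log_sigmas[i])
      variational_gaussian(as.vector(k), config$init_log_sd,
                           prior_mean = 0,
                           prior_sd = config$prior_sds[i])
    })
    structure(list(params = params, variational = variational,
                   config = config),
              class = "seg_model")
  })
}

#' @exportS3Method base::print
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L)) +
    2L * sum(vapply(x$variational, function(v) length(v$mean), 0L))
  cat(sprintf("<seg_model> %d LoG levels, depth %d, %d base channels, %d parameters\n",
              length(x$variational), x$config$depth,
              x$config$base_channels, np))
  invisible(x)
}

# ---- forward / backward ----

#' LoG-stream forward pass
#'
#' Convolves a normalized patch with each level's Bayesian LoG kernel
#' (posterior mean, or a reparameterized sample) under edge-replicating
#' padding, then maps responses through a sigmoid to `[0, 1]`.
#'
#' @param patch 3D array with values in `[0, 1]`.
#' @param model A [seg_model()], or a [log_kernel_bank()] for a plain
#'   (non-Bayesian) forward pass.
#' @param sample Draw kernel weights from the posterior instead of using
#'   the mean.
#' @return List of per-level feature arrays (same shape as the patch);
#'   the raw responses and draws are attached as attributes `raw`/`eps`.
#' @export
log_stream_forward <- function(patch, model, sample = FALSE) {
  if (inherits(model, "log_kernel_bank")) {
    sizes <- model$levels$size
    weights <- lapply(model$kernels, as.vector)
    eps <- vector("list", length(sizes))
  } else {
    sizes <- model$config$log_sizes
    weights <- vector("list", length(sizes))
    eps <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      if (sample) {
        w <- sample_weights(model$variational[[i]])
        eps[[i]] <- attr(w, "eps")
        weights[[i]] <- as.vector(w)
      } else {
        weights[[i]] <- as.vector(model$variational[[i]]$mean)
      }
    }
  }
  feats <- vector("list", length(sizes))
  raw <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    raw[[i]] <- conv3d_single_cpp(as4d(patch), weights[[i]],
                                  as.integer(sizes[i]))
    feats[[i]] <- sigmoid(raw[[i]])
  }
  attr(feats, "raw") <- raw
  attr(feats, "eps") <- eps
  feats
}

#' Regular-stream (U-Net) forward pass
#'
#' @param patch 3D array; side must be divisible by `2^(depth-1)`.
#' @param model A [seg_model()].
#' @return Feature array (patch dims x base_channels); the layer cache is
#'   attached as attribute `cache`.
#' @export
regular_stream_forward <- function(patch, model) {
  cfg <- model$config
  d <- dim(patch)[1:3]
  if (any(d %% 2^(cfg$depth - 1L) != 0L))
    stop("patch side ", paste(d, collapse = "x"),
         " not divisible by 2^(depth-1)")
  p <- model$params
  D <- cfg$depth
  cache <- list(input = as4d(patch))
  x <- cache$input
  skips <- list()
  for (l in seq_len(D)) {
    cache[[paste0("enc", l, "_in")]] <- x
    z <- conv_fwd(x, p[[paste0("enc", l, "_W")]], p[[paste0("enc", l, "_b")]],
                  k = 3L)
    a <- pmax(z, 0)
    cache[[paste0("enc", l, "_z")]] <- z
    skips[[l]] <- a
    if (l < D) {
      pool <- maxpool_fwd(a)
      cache[[paste0("pool", l)]] <- pool
      cache[[paste0("pool", l, "_xdim")]] <- dim(a)
      x <- pool$values
    } else {
      x <- a
    }
  }
  if (D > 1L) {
    for (l in seq(D - 1L, 1L)) {
      up <- upsample2(x)
      cat_in <- concat_ch(list(up, skips[[l]]))
      cache[[paste0("dec", l, "_in")]] <- cat_in
      cache[[paste0("dec", l, "_upch")]] <- dim(as4d(x))[4L]
      z <- conv_fwd(cat_in, p[[paste0("dec", l, "_W")]],
                    p[[paste0("dec", l, "_b")]], k = 3L)
      cache[[paste0("dec", l, "_z")]] <- z
      x <- pmax(z, 0)
    }
  }
  attr(x, "cache") <- cache
  x
}

#' Fuse LoG and regular-stream features into a probability patch
#'
#' Concatenates the feature sets, applies parallel dilated convolutions
#' (rates from the config), sums them, and maps through a ReLU and a final
#' 1x1x1 convolution with sigmoid output.
#'
#' @param log_feats List of LoG-stream feature arrays.
#' @param reg_feats Regular-stream feature array.
#' @param model A [seg_model()].
#' @return Probability array in `[0, 1]` with the input spatial shape;
#'   cache attached as attribute `cache`.
#' @export
aspp_fuse <- function(log_feats, reg_feats, model) {
  p <- model$params
  cfg <- model$config
  cat_in <- concat_ch(c(list(reg_feats), log_feats))
  branches <- list()
  s <- 0
  for (r in cfg$aspp_rates) {
    z <- conv_fwd(cat_in, p[[paste0("aspp", r, "_W")]],
                  p[[paste0("aspp", r, "_b")]], k = 3L, dil = r)
    branches[[as.character(r)]] <- z
    s <- s + z
  }
  h <- pmax(s, 0)
  logits <- conv_fwd(h, p$out_W, p$out_b, k = 1L)
  prob <- sigmoid(logits)
  attr(prob, "cache") <- list(cat_in = cat_in, s = s, h = h,
                              logits = logits)
  prob
}

# full forward: returns prob (n,n,n) plus caches for backward
seg_forward <- function(model, patch, sample = FALSE) {
  lf <- log_stream_forward(patch, model, sample = sample)
  rf <- regular_stream_forward(patch, model)
  prob <- aspp_fuse(lf, rf, model)
  list(prob = prob, log_feats = lf, reg_feats = rf,
       fuse_cache = attr(prob, "cache"),
       reg_cache = attr(rf, "cache"), patch = patch)
}

# reverse mode from d(loss)/d(logits); returns named gradient list matching
# params plus per-level variational gradients vg_mean / vg_log_sd
seg_backward <- function(model, fwd, dlogits) {
  p <- model$params
  cfg <- model$config
  grads <- list()
  fc <- fwd$fuse_cache
  # final 1x1 conv
  grads$out_W <- conv3d_grad_weights_cpp(fc$h, dlogits, 1L, 1L, 0L, 1L)
  grads$out_b <- sum(dlogits)
  dh <- conv3d_grad_input_cpp(dlogits, p$out_W, dim(fc$h), 1L, 1L, 0L)
  ds <- dh * (fc$s > 0)
  dcat <- 0
  for (r in cfg$aspp_rates) {
    grads[[paste0("aspp", r, "_W")]] <-
      conv3d_grad_weights_cpp(fc$cat_in, ds, 3L, as.integer(r), 0L,
                              cfg$base_channels)
    grads[[paste0("aspp", r, "_b")]] <- apply(ds, 4L, sum)
    dcat <- dcat + conv3d_grad_input_cpp(ds, p[[paste0("aspp", r, "_W")]],
                                         dim(fc$cat_in), 3L, as.integer(r),
                                         0L)
  }
  L <- length(cfg$log_sizes)
  parts <- split_ch(dcat, c(cfg$base_channels, rep(1L, L)))
  dreg <- parts[[1L]]
  # LoG stream: through sigmoid into variational kernel gradients
  raw <- attr(fwd$log_feats, "raw")
  eps <- attr(fwd$log_feats, "eps")
  grads$vg_mean <- vector("list", L)
  grads$vg_log_sd <- vector("list", L)
  x4 <- as4d(fwd$patch)
  for (i in seq_len(L)) {
    f <- fwd$log_feats[[i]]
    draw <- parts[[i + 1L]] * f * (1 - f)
    dw <- conv3d_single_gradw_cpp(x4, draw, as.integer(cfg$log_sizes[i]))
    grads$vg_mean[[i]] <- as.vector(dw)
    if (!is.null(eps[[i]])) {
      sd_i <- exp(model$variational[[i]]$log_sd)
      grads$vg_log_sd[[i]] <- as.vector(dw) * eps[[i]] * sd_i
    } else {
      grads$vg_log_sd[[i]] <- numeric(length(dw))
    }
  }
  # regular stream backward
  cache <- fwd$reg_cache
  D <- cfg$depth
  dx <- dreg
  if (D > 1L) {
    for (l in seq(1L, D - 1L)) {
      z <- cache[[paste0("dec", l, "_z")]]
      dz <- dx * (z > 0)
      cat_in <- cache[[paste0("dec", l, "_in")]]
      grads[[paste0("dec", l, "_W")]] <-
        conv3d_grad_weights_cpp(cat_in, dz, 3L, 1L, 0L, dim(z)[4L])
      grads[[paste0("dec", l, "_b")]] <- apply(dz, 4L, sum)
      dcat_in <- conv3d_grad_input_cpp(dz, p[[paste0("dec", l, "_W")]],
                                       dim(cat_in), 3L, 1L, 0L)
      upch <- cache[[paste0("dec", l, "_upch")]]
      sp <- split_ch(dcat_in, c(upch, dim(cat_in)[4L] - upch))
      dskip <- sp[[2L]]
      ddeep <- upsample2_bwd(sp[[1L]])
      # store skip gradient; deeper gradient continues down the decoder
      cache[[paste0("dskip", l)]] <- dskip
      dx <- ddeep
    }
  }
  # encoder backward, deepest first: dx arrives at enc_D activation
  for (l in seq(D, 1L)) {
    da <- dx
    if (l < D) {
      pool <- cache[[paste0("pool", l)]]
      da <- maxpool_bwd(dx, pool$argmax, cache[[paste0("pool", l, "_xdim")]])
    }
    if (l < D) da <- da + cache[[paste0("dskip", l)]]
    z <- cache[[paste0("enc", l, "_z")]]
    dz <- da * (z > 0)
    x_in <- cache[[paste0("enc", l, "_in")]]
    grads[[paste0("enc", l, "_W")]] <-
      conv3d_grad_weights_cpp(x_in, dz, 3L, 1L, 0L, dim(z)[4L])
    grads[[paste0("enc", l, "_b")]] <- apply(dz, 4L, sum)
    if (l > 1L)
      dx <- conv3d_grad_input_cpp(dz, p[[paste0("enc", l, "_W")]],
                                  dim(x_in), 3L, 1L, 0L)
  }
  grads
}

# ---- Adam optimizer ----

adam_init <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(model$params)) {
    st$m[[nm]] <- model$params[[nm]] * 0
    st$v[[nm]] <- model$params[[nm]] * 0
  }
  for (i in seq_along(model$variational)) {
    for (fld in c("mean", "log_sd")) {
      key <- paste0("vg", i, "_", fld)
      st$m[[key]] <- model$variational[[i]][[fld]] * 0
      st$v[[key]] <- st$m[[key]]
    }
  }
  st
}

adam_step <- function(val, g, st, key, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$m[[key]] <- b1 * st$m[[key]] + (1 - b1) * g
  st$v[[key]] <- b2 * st$v[[key]] + (1 - b2) * g^2
  mhat <- st$m[[key]] / (1 - b1^st$t)
  vhat <- st$v[[key]] / (1 - b2^st$t)
  list(val = val - lr * mhat / (sqrt(vhat) + eps), st = st)
}

adam_update <- function(model, grads, st, lr) {
  st$t <- st$t + 1L
  for (nm in names(model$params)) {
    if (is.null(grads[[nm]])) next
    g <- grads[[nm]]
    dim(g) <- dim(model$params[[nm]])
    res <- adam_step(model$params[[nm]], g, st, nm, lr)
    model$params[[nm]] <- res$val
    st <- res$st
  }
  for (i in seq_along(model$variational)) {
    for (fld in c("mean", "log_sd")) {
      key <- paste0("vg", i, "_", fld)
      gkey <- if (fld == "mean") "vg_mean" else "vg_log_sd"
      if (is.null(grads[[gkey]][[i]])) next
      res <- adam_step(model$variational[[i]][[fld]], grads[[gkey]][[i]],
                       st, key, lr)
      model$variational[[i]][[fld]] <- res$val
      st <- res$st
    }
  }
  list(model = model, state = st)
}
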