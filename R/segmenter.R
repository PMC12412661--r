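#' Dice overlap coefficient
#'
#' \deqn{Dice = 2\sum g_i o_i / (\sum g_i^2 + \sum o_i^2)} between a
#' predicted (possibly soft) segmentation and a ground-truth label. For
#' binary masks this is the familiar 2|A∩B|/(|A|+|B|). Two empty masks are
#' defined to agree perfectly (Dice 1).
#'
#' @param pred A [probability_volume()], [label_volume()], or array.
#' @param truth A [label_volume()] or array on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  o <- if (inherits(pred, "scalar_volume")) pred$values else pred
  g <- if (inherits(truth, "scalar_volume")) truth$values else truth
  if (!identical(dim(o), dim(g))) stop("pred and truth grids differ")
  num <- 2 * sum(g * o)
  den <- sum(g^2) + sum(o^2)
  if (den == 0) return(1)
  num / den
}

#' Dice loss (1 - Dice)
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth) 1 - dice_coefficient(pred, truth)

#' Voxel percentage of a feature patch above a threshold
#'
#' The fraction of voxels strictly exceeding `tau`; the gate statistic
#' summarizing how much vessel-edge content a patch carries. For a list of
#' per-level features the element-wise maximum across levels is used.
#'
#' @param feat Array in `[0, 1]`, or list of such arrays.
#' @param tau Threshold (default 0.5).
#' @return Fraction in `[0, 1]`.
#' @export
voxel_percentage <- function(feat, tau = 0.5) {
  if (is.list(feat)) feat <- Reduce(pmax, feat)
  mean(feat > tau)
}

#' Classify a patch as main-vessel or branch by voxel percentage
#'
#' A voxel percentage at or above `beta` (default 15%) indicates a patch
#' dominated by large-vessel content ("main"); below it, small branches or
#' background ("branch").
#'
#' @param vp Voxel percentage in `[0, 1]`.
#' @param beta Class threshold (default 0.15).
#' @return `"main"` or `"branch"`.
#' @export
classify_patch <- function(vp, beta = 0.15) {
  stopifnot(vp >= 0, vp <= 1)
  if (vp >= beta) "main" else "branch"
}

#' Create a balanced-gate state
#'
#' The gate maintains two candidate pools (main / branch). Patches are
#' added to the pool of their class until both pools reach capacity; a
#' training batch then draws an equal number from each, enforcing exact
#' class balance regardless of stream prevalence.
#'
#' @param capacity Pool capacity (default 10).
#' @param draw Patches drawn per class per batch (default 5).
#' @param tau Voxel-percentage threshold on gate features (default 0.5).
#' @param beta Main/branch classification threshold (default 0.15).
#' @return An environment of class `gate_state`.
#' @export
gate_state <- function(capacity = 10L, draw = 5L, tau = 0.5, beta = 0.15) {
  stopifnot(draw <= capacity, beta > 0, beta < 1, tau > 0, tau < 1)
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$draw <- as.integer(draw)
  e$tau <- tau
  e$beta <- beta
  e$main <- list()
  e$branch <- list()
  class(e) <- "gate_state"
  e
}

#' Assemble one exactly class-balanced batch from a patch stream
#'
#' Consumes the stream until both pools are at capacity, then removes
#' `draw` randomly chosen patches per class and returns them as a batch.
#'
#' @param gate A [gate_state()].
#' @param stream A function of no arguments returning the next classified
#'   patch as a list with at least `class` (`"main"`/`"branch"`), or `NULL`
#'   when exhausted.
#' @param seed Optional seed for the within-pool draw.
#' @return List of `2 * draw` patches, alternating is not guaranteed but
#'   counts per class are exactly `draw` each.
#' @export
assemble_balanced_batch <- function(gate, stream, seed = NULL) {
  stopifnot(inherits(gate, "gate_state"))
  while (length(gate$main) < gate$capacity ||
         length(gate$branch) < gate$capacity) {
    item <- stream()
    if (is.null(item))
      stop("patch stream exhausted before pools filled (main ",
           length(gate$main), "/", gate$capacity, ", branch ",
           length(gate$branch), "/", gate$capacity, ")")
    cls <- item$class
    if (is.null(cls)) stop("stream item lacks a class")
    if (cls == "main") {
      if (length(gate$main) < gate$capacity)
        gate$main[[length(gate$main) + 1L]] <- item
    } else {
      if (length(gate$branch) < gate$capacity)
        gate$branch[[length(gate$branch) + 1L]] <- item
    }
  }
  pick <- function(n) {
    if (is.null(seed)) sample.int(n, gate$draw)
    else with_seed(seed, sample.int(n, gate$draw))
  }
  im <- pick(length(gate$main))
  ib <- pick(length(gate$branch))
  batch <- c(gate$main[im], gate$branch[ib])
  gate$main <- gate$main[-im]
  gate$branch <- gate$branch[-ib]
  batch
}

# clamp probabilities away from 0/1 for the Bernoulli log-likelihood
clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# per-batch loss and gradients; batch = list of list(patch, label)
seg_loss_grad <- function(model, batch, sample = TRUE, kl_scale = 0,
                          want_grads = TRUE) {
  nb <- length(batch)
  grads_acc <- NULL
  dice_sum <- 0; loglik_sum <- 0
  for (b in batch) {
    fwd <- seg_forward(model, b$patch, sample = sample)
    p <- fwd$prob
    g <- array(b$label, dim = dim(p))
    pc <- clamp_prob(p)
    N <- length(p)
    loglik <- sum(g * log(pc) + (1 - g) * log(1 - pc)) / N
    sgp <- sum(g * p); den <- sum(g^2) + sum(p^2)
    dice <- if (den == 0) 1 else 2 * sgp / den
    dice_sum <- dice_sum + dice
    loglik_sum <- loglik_sum + loglik
    if (want_grads) {
      ddice_dp <- if (den == 0) 0 else (-2 * g / den + 4 * sgp * p / den^2)
      dlogits <- (ddice_dp * p * (1 - p) + (p - g) / N) / nb
      gr <- seg_backward(model, fwd, dlogits)
      grads_acc <- if (is.null(grads_acc)) gr else
        mapply(function(a, b) if (is.list(a)) mapply(`+`, a, b,
                                                     SIMPLIFY = FALSE)
               else a + b, grads_acc, gr, SIMPLIFY = FALSE)
    }
  }
  kl <- sum(vapply(model$variational, function(v)
    kl_gaussian(v$mean, exp(v$log_sd), v$prior_mean, v$prior_sd), 0))
  if (want_grads && kl_scale > 0) {
    for (i in seq_along(model$variational)) {
      kg <- kl_vg(model$variational[[i]])
      grads_acc$vg_mean[[i]] <- grads_acc$vg_mean[[i]] + kl_scale * kg$d_mean
      grads_acc$vg_log_sd[[i]] <- grads_acc$vg_log_sd[[i]] +
        kl_scale * kg$d_log_sd
    }
  }
  dice_mean <- dice_sum / nb
  loglik_mean <- loglik_sum / nb
  objective <- (1 - dice_mean) - loglik_mean + kl_scale * kl
  list(objective = objective, dice = dice_mean, loglik = loglik_mean,
       kl = kl, grads = grads_acc)
}

#' Evidence lower bound of a batch under the variational posterior
#'
#' Monte-Carlo estimate: mean (over `mc_samples` weight draws and batch
#' patches) of the voxel-averaged Bernoulli log-likelihood, minus
#' `kl_scale` times the KL divergence of the variational kernels from
#' their priors.
#'
#' @param batch List of `list(patch, label)` pairs (arrays in `[0, 1]`).
#' @param model A [seg_model()].
#' @param mc_samples Number of posterior draws (default 1).
#' @param kl_scale Weight of the KL term (default 1).
#' @return Scalar ELBO estimate.
#' @export
elbo <- function(batch, model, mc_samples = 1L, kl_scale = 1) {
  ll <- 0
  for (s in seq_len(mc_samples)) {
    res <- seg_loss_grad(model, batch, sample = TRUE, kl_scale = kl_scale,
                         want_grads = FALSE)
    ll <- ll + res$loglik
  }
  ll / mc_samples - kl_scale * res$kl
}

#' Combined training objective: Dice loss minus ELBO
#'
#' The quantity minimized during training: `(1 - Dice) - ELBO`, i.e.
#' segmentation overlap and variational fit in one scalar.
#'
#' @inheritParams elbo
#' @return Scalar objective value.
#' @export
combined_objective <- function(batch, model, mc_samples = 1L,
                               kl_scale = 1) {
  dice <- 0
  for (s in seq_len(mc_samples)) {
    res <- seg_loss_grad(model, batch, sample = TRUE, kl_scale = kl_scale,
                         want_grads = FALSE)
    dice <- dice + res$dice
  }
  (1 - dice / mc_samples) - elbo(batch, model, mc_samples, kl_scale)
}

#' Train the segmentation model on paired volumes
#'
#' Patch-based stochastic training: at each step random patches are cropped
#' from the (clip-normalized, background-suppressed) training volumes,
#' classified by the balanced gate on LoG-stream features, and an exactly
#' class-balanced batch is optimized with Adam on the combined objective
#' (Dice loss minus ELBO). Fully seeded and deterministic.
#'
#' @param dataset List of cases, each a list with `image`
#'   ([scalar_volume()], raw intensities) and `label` ([label_volume()]).
#' @param config A [seg_config()]; `epochs` is the number of gradient
#'   steps.
#' @param use_gate Assemble batches through the balanced gate (default
#'   `TRUE`); otherwise plain random batches of `batch_size`.
#' @param suppress_bg Zero out background (by the label) before patch
#'   extraction, as done for training samples (default `TRUE`).
#' @return List of class `seg_fit`: `model`, `history` (data.frame with
#'   objective, dice, loglik, kl per step), `config`.
#' @export
train_segmenter <- function(dataset, config = seg_config(),
                            use_gate = TRUE, suppress_bg = TRUE) {
  model <- seg_model_init(config)
  vols <- lapply(dataset, function(case) {
    img <- clip_normalize(case$image)
    if (suppress_bg) img <- suppress_background(img, case$label)
    list(image = img$values, label = case$label$values)
  })
  n_per_step <- if (use_gate) 2L * config$gate_draw else config$batch_size
  kl_scale <- config$kl_scale %||% (1 / (config$epochs * n_per_step))
  st <- adam_init(model)
  gate <- gate_state(config$gate_capacity, config$gate_draw,
                     config$vp_tau, config$gate_beta)
  # classification uses the fixed precomputed LoG bank (the stream's
  # initialization): the gate statistic stays stationary while the
  # Bayesian kernels evolve, so class prevalences cannot collapse
  gate_bank <- log_kernel_bank(config$log_sizes, config$log_sigmas)
  ps <- config$patch_size
  history <- vector("list", config$epochs)
  crop_counter <- 0L
  next_crop <- function() {
    crop_counter <<- crop_counter + 1L
    case <- vols[[sample.int(length(vols), 1L)]]
    d <- dim(case$image)
    if (any(d < ps)) stop("volume smaller than patch size")
    c0 <- sapply(1:3, function(a) sample.int(d[a] - ps + 1L, 1L))
    patch <- case$image[c0[1]:(c0[1] + ps - 1L), c0[2]:(c0[2] + ps - 1L),
                        c0[3]:(c0[3] + ps - 1L)]
    label <- case$label[c0[1]:(c0[1] + ps - 1L), c0[2]:(c0[2] + ps - 1L),
                        c0[3]:(c0[3] + ps - 1L)]
    feats <- log_stream_forward(patch, gate_bank)
    vp <- voxel_percentage(feats, gate$tau)
    list(patch = patch, label = label, vp = vp,
         class = classify_patch(vp, gate$beta))
  }
  with_seed(config$seed + 1L, {
    for (step in seq_len(config$epochs)) {
      batch <- if (use_gate) assemble_balanced_batch(gate, next_crop)
      else replicate(config$batch_size, next_crop(), simplify = FALSE)
      res <- seg_loss_grad(model, batch, sample = TRUE,
                           kl_scale = kl_scale)
      if (!is.finite(res$objective))
        stop("training diverged at step ", step, " (objective ",
             res$objective, ")")
      upd <- adam_update(model, res$grads, st, config$learning_rate)
      model <- upd$model
      st <- upd$state
      history[[step]] <- data.frame(step = step, objective = res$objective,
                                    dice = res$dice, loglik = res$loglik,
                                    kl = res$kl)
    }
  })
  structure(list(model = model, history = do.call(rbind, history),
                 config = config, kl_scale = kl_scale),
            class = "seg_fit")
}

#' Segment a full volume by patchwise inference and stitching
#'
#' Extracts overlapping patches, runs the model forward at the posterior
#' mean, and stitches the per-patch probabilities (mean over overlaps).
#'
#' @param model A [seg_model()] or [train_segmenter()] fit.
#' @param vol A [scalar_volume()] with values already normalized to
#'   `[0, 1]` (see [clip_normalize()]).
#' @param overlap Patch overlap in voxels (default 16).
#' @param sample Use a posterior weight draw instead of the mean.
#' @return A [probability_volume()].
#' @export
predict_volume <- function(model, vol, overlap = 16L, sample = FALSE) {
  if (inherits(model, "seg_fit")) model <- model$model
  if (min(vol$values) < 0 || max(vol$values) > 1)
    stop("volume must be normalized to [0,1] before prediction")
  ps <- model$config$patch_size
  if (overlap >= ps) overlap <- ps %/% 2L
  patches <- extract_patches(vol, size = ps, overlap = overlap)
  for (i in seq_along(patches)) {
    fwd <- seg_forward(model, patches[[i]]$values, sample = sample)
    patches[[i]]$values <- array(fwd$prob, dim(patches[[i]]$values))
  }
  stitch_predictions(patches, vol)
}

#' Posterior-sampling segmentation ensemble with uncertainty maps
#'
#' Draws `n` weight samples from the variational posterior, segments the
#' volume with each, and summarizes the ensemble by its voxelwise mean and
#' SD; members are thresholded at 0.5 into binary labels.
#'
#' @param model A [seg_model()] or fit.
#' @param vol Normalized [scalar_volume()].
#' @param n Number of posterior samples (at least 2).
#' @param seed Integer seed controlling all draws.
#' @param overlap Patch overlap (default 16).
#' @return List with `members` (list of [label_volume()]), `mean`
#'   ([probability_volume()]), `sd` ([scalar_volume()]).
#' @export
sample_segmentations <- function(model, vol, n, seed = 1L, overlap = 16L) {
  if (inherits(model, "seg_fit")) model <- model$model
  stopifnot(n >= 2L)
  probs <- with_seed(seed, lapply(seq_len(n), function(i)
    predict_volume(model, vol, overlap = overlap, sample = TRUE)))
  d <- dim(probs[[1]]$values)
  m <- vapply(probs, function(p) as.vector(p$values),
              numeric(prod(d)))
  mu <- array(rowMeans(m), d)
  sdv <- array(sqrt(rowSums((m - rowMeans(m))^2) / (n - 1)), d)
  members <- lapply(probs, function(p)
    label_volume(array(as.numeric(p$values >= 0.5), dim(p$values)),
                 vol$spacing, vol$origin))
  list(members = members,
       mean = probability_volume(mu, vol$spacing, vol$origin),
       sd = scalar_volume(sdv, vol$spacing, vol$origin))
}
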