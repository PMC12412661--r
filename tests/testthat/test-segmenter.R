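test_that("Dice coefficient follows its defining sums", {
  a <- array(0, c(4, 4, 4)); b <- array(0, c(4, 4, 4))
  a[1:2, 1, 1] <- 1; a[1:2, 2, 1] <- 1          # 4 voxels
  b[1:2, 2, 1] <- 1; b[1:2, 3, 1] <- 1          # 4 voxels, 2 shared
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a, a), 1)
  disjoint <- array(0, c(4, 4, 4)); disjoint[4, 4, 4] <- 1
  expect_equal(dice_coefficient(a, disjoint), 0)
  expect_equal(dice_coefficient(array(0, c(2, 2, 2)),
                                array(0, c(2, 2, 2))), 1)
  # symmetry and permutation invariance for binary masks
  with_seed(2, {
    g <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    o <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    expect_equal(dice_coefficient(g, o), dice_coefficient(o, g))
    perm <- sample(64)
    expect_equal(dice_coefficient(array(g[perm], dim(g)),
                                  array(o[perm], dim(o))),
                 dice_coefficient(g, o))
  })
  expect_equal(dice_loss(a, b), 0.5)
})

test_that("voxel percentage counts strictly-above-threshold voxels", {
  expect_equal(voxel_percentage(array(0.9, c(3, 3, 3)), 0.5), 1)
  expect_equal(voxel_percentage(array(0.1, c(3, 3, 3)), 0.5), 0)
  expect_equal(voxel_percentage(array(0.5, c(3, 3, 3)), 0.5), 0)  # strict
  with_seed(6, {
    f <- array(runif(1000), c(10, 10, 10))
    k <- sum(f > 0.37)
    expect_equal(voxel_percentage(f, 0.37), k / 1000)
  })
})

test_that("patch classification applies the 15% threshold with main ties", {
  expect_equal(classify_patch(0.20, 0.15), "main")
  expect_equal(classify_patch(0.05, 0.15), "branch")
  expect_equal(classify_patch(0.15, 0.15), "main")
  expect_error(classify_patch(1.2), "vp")
})

test_that("balanced gate emits exactly class-balanced batches", {
  # stream with 5% branch prevalence
  make_stream <- function(seed) {
    counter <- 0L
    function() {
      counter <<- counter + 1L
      cls <- if (counter %% 20L == 0L) "branch" else "main"
      list(id = counter, class = cls)
    }
  }
  gate <- gate_state(capacity = 10L, draw = 5L)
  stream <- make_stream(1)
  with_seed(3, {
    batches <- lapply(1:20, function(i) assemble_balanced_batch(gate,
                                                                stream))
  })
  for (b in batches) {
    cls <- vapply(b, function(x) x$class, "")
    expect_equal(sum(cls == "main"), 5L)
    expect_equal(sum(cls == "branch"), 5L)
  }
  # post-draw pool sizes
  expect_equal(length(gate$main), 5L)
  expect_equal(length(gate$branch), 5L)
  # exhausted stream errors with a diagnostic
  finite_stream <- local({
    n <- 0L
    function() {
      n <<- n + 1L
      if (n > 8L) NULL else list(class = "main")
    }
  })
  gate2 <- gate_state()
  expect_error(assemble_balanced_batch(gate2, finite_stream), "exhausted")
})

test_that("forward passes have the right shapes, ranges, and determinism", {
  cfg <- seg_config(patch_size = 16L, base_channels = 4L, depth = 2L,
                    log_sizes = c(3L, 5L), log_sigmas = c(0.5, 1),
                    prior_sds = c(0.5, 1), seed = 2L)
  model <- seg_model_init(cfg)
  with_seed(1, patch <- array(runif(16^3), c(16, 16, 16)))
  f1 <- vesselmesh:::seg_forward(model, patch, sample = FALSE)
  f2 <- vesselmesh:::seg_forward(model, patch, sample = FALSE)
  expect_identical(as.vector(f1$prob), as.vector(f2$prob))
  expect_equal(dim(f1$prob)[1:3], c(16L, 16L, 16L))
  expect_true(all(f1$prob > 0 & f1$prob < 1))
  # constant patch: zero-mean LoG kernel -> raw response 0 -> sigmoid 0.5
  fc <- log_stream_forward(array(0.3, c(16, 16, 16)), model)
  for (f in fc) expect_equal(range(f), c(0.5, 0.5), tolerance = 1e-12)
  # indivisible patch size errors
  expect_error(regular_stream_forward(array(0, c(15, 15, 15)), model),
               "divisible")
  # all-zero final layer weights -> constant 0.5 output
  m0 <- model
  m0$params$out_W[] <- 0
  m0$params$out_b <- 0
  f0 <- vesselmesh:::seg_forward(m0, patch, sample = FALSE)
  expect_equal(range(f0$prob), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("ELBO and the combined objective decompose as stated", {
  cfg <- seg_config(patch_size = 8L, base_channels = 2L, depth = 1L,
                    log_sizes = 3L, log_sigmas = 0.5, prior_sds = 0.5,
                    seed = 5L)
  model <- seg_model_init(cfg)
  with_seed(4, {
    batch <- list(list(patch = array(runif(512), c(8, 8, 8)),
                       label = array(rbinom(512, 1, 0.4), c(8, 8, 8))))
  })
  # deterministic at the mean when posterior sd ~ 0
  m0 <- model
  for (i in seq_along(m0$variational)) m0$variational[[i]]$log_sd[] <- -30
  res <- vesselmesh:::seg_loss_grad(m0, batch, sample = TRUE,
                                    kl_scale = 0.1, want_grads = FALSE)
  e <- elbo(batch, m0, mc_samples = 1, kl_scale = 0.1)
  expect_equal(e, res$loglik - 0.1 * res$kl, tolerance = 1e-10)
  co <- combined_objective(batch, m0, kl_scale = 0.1)
  expect_equal(co, (1 - res$dice) - e, tolerance = 1e-10)
  # increasing kl_scale strictly decreases the ELBO when KL > 0
  expect_gt(res$kl, 0)
  expect_gt(elbo(batch, m0, kl_scale = 0.05),
            elbo(batch, m0, kl_scale = 0.5))
  # single-voxel hand check of the Bernoulli likelihood
  probs <- array(vesselmesh:::seg_forward(m0, batch[[1]]$patch,
                                          sample = FALSE)$prob, c(8, 8, 8))
  hand <- mean(batch[[1]]$label * log(pmin(pmax(probs, 1e-7), 1 - 1e-7)) +
                 (1 - batch[[1]]$label) *
                 log(1 - pmin(pmax(probs, 1e-7), 1 - 1e-7)))
  expect_equal(res$loglik, hand, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences end to end", {
  cfg <- seg_config(patch_size = 8L, base_channels = 4L, depth = 2L,
                    log_sizes = c(3L, 5L), log_sigmas = c(0.5, 1),
                    prior_sds = c(0.5, 1), seed = 9L)
  model <- seg_model_init(cfg)
  with_seed(42, {
    batch <- list(list(patch = array(runif(512), c(8, 8, 8)),
                       label = array(rbinom(512, 1, 0.3), c(8, 8, 8))))
  })
  res <- vesselmesh:::seg_loss_grad(model, batch, sample = FALSE,
                                    kl_scale = 0.01)
  eps <- 1e-6
  checks <- list(c("enc1_W", 5, 2), c("enc2_W", 40, 3), c("dec1_W", 100, 2),
                 c("aspp2_W", 30, 1), c("out_W", 3, 1))
  for (ck in checks) {
    nm <- ck[1]; i <- as.integer(ck[2]); j <- as.integer(ck[3])
    m2 <- model
    m2$params[[nm]][i, j] <- m2$params[[nm]][i, j] + eps
    r2 <- vesselmesh:::seg_loss_grad(m2, batch, sample = FALSE,
                                     kl_scale = 0.01, want_grads = FALSE)
    num <- (r2$objective - res$objective) / eps
    expect_equal(res$grads[[nm]][i, j], num, tolerance = 1e-3, label = nm)
  }
  # variational mean gradient (flows through the LoG stream + KL)
  m2 <- model
  m2$variational[[1]]$mean[14] <- m2$variational[[1]]$mean[14] + eps
  r2 <- vesselmesh:::seg_loss_grad(m2, batch, sample = FALSE,
                                   kl_scale = 0.01, want_grads = FALSE)
  expect_equal(res$grads$vg_mean[[1]][14],
               (r2$objective - res$objective) / eps, tolerance = 1e-3)
})

test_that("LoG response peaks at the level matched to the tube radius", {
  # noise-free tubes of increasing radius; the argmax response level of
  # the bank must be non-decreasing in radius (scale selectivity)
  bank <- log_kernel_bank()
  argmax_level <- function(radius) {
    pts <- cbind(seq(8, 40, length.out = 12), 24, 24)
    spec <- phantom_spec(grid_shape = c(48, 48, 48),
                         centerlines = list(centerline(pts, radius)),
                         blur_sigma = 0.5, noise_sd = 0)
    ph <- make_phantom(spec)
    img <- clip_normalize(ph$image)$values
    # mean absolute raw response inside the lumen per level
    resp <- vapply(seq_along(bank$kernels), function(i) {
      r <- conv3d_raw(img, bank$kernels[[i]], bank$levels$size[i])
      mean(abs(r[ph$label$values == 1]))
    }, 0)
    which.max(resp)
  }
  conv3d_raw <- function(img, kern, size) {
    x <- img; dim(x) <- c(dim(img), 1L)
    vesselmesh:::conv3d_single_cpp(x, as.vector(kern), as.integer(size))
  }
  radii <- c(1.5, 3, 6)
  levels <- vapply(radii, argmax_level, 0L)
  expect_true(all(diff(levels) >= 0))
  expect_gt(levels[3], levels[1])
})

test_that("posterior sampling ensembles behave like the posterior", {
  cfg <- seg_config(patch_size = 16L, base_channels = 2L, depth = 1L,
                    log_sizes = 3L, log_sigmas = 1, prior_sds = 1,
                    seed = 3L)
  model <- seg_model_init(cfg)
  vol <- probability_volume(array(0.5, c(16, 16, 16)))
  vol <- scalar_volume(vol$values)
  # degenerate posterior (sd -> 0): identical members, zero SD
  m0 <- model
  for (i in seq_along(m0$variational)) m0$variational[[i]]$log_sd[] <- -30
  ens0 <- sample_segmentations(m0, vol, n = 3, seed = 5)
  expect_equal(max(ens0$sd$values), 0)
  expect_identical(ens0$members[[1]]$values, ens0$members[[2]]$values)
  # nonzero posterior: SD nonnegative everywhere, seeded determinism
  ens1 <- sample_segmentations(model, vol, n = 3, seed = 5)
  ens2 <- sample_segmentations(model, vol, n = 3, seed = 5)
  expect_true(min(ens1$sd$values) >= 0)
  expect_identical(ens1$mean$values, ens2$mean$values)
  expect_error(sample_segmentations(model, vol, n = 1), "n >= 2")
})
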