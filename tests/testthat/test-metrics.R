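test_that("ASD and Hausdorff match hand computations and oracles", {
  expect_equal(asd(rbind(c(0, 0, 0)), rbind(c(3, 0, 0))), 3)
  a2 <- rbind(c(0, 0, 0), c(10, 0, 0))
  b2 <- rbind(c(0, 0, 0))
  expect_equal(hausdorff(a2, b2), 10)
  expect_equal(hausdorff(b2, a2), 10)   # symmetric
  with_seed(3, {
    A <- matrix(rnorm(150), 50, 3)
    B <- matrix(rnorm(150), 50, 3)
    expect_equal(asd(A, A), 0)
    expect_equal(hausdorff(B, B), 0)
    # brute-force double-loop oracle
    dmat <- as.matrix(stats::dist(rbind(A, B)))[1:50, 51:100]
    o_asd <- (sum(apply(dmat, 1, min)) + sum(apply(dmat, 2, min))) / 100
    o_h <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
    expect_equal(asd(A, B), o_asd, tolerance = 1e-10)
    expect_equal(hausdorff(A, B), o_h, tolerance = 1e-10)
  })
  expect_error(asd(matrix(0, 0, 3), rbind(c(1, 1, 1))), "empty")
})

test_that("SNR follows mean over population SD with clipping and flags", {
  # half 1s and half 3s: mean 2, population SD 1 -> SNR 2
  v <- array(rep(c(1, 3), 500), c(10, 10, 10))
  vol <- scalar_volume(v)
  expect_equal(snr_at_point(vol, c(4.5, 4.5, 4.5), 10L), 2)
  # scale invariance
  expect_equal(snr_at_point(scalar_volume(5 * v), c(4.5, 4.5, 4.5), 10L),
               2)
  # constant window flagged infinite
  cv <- scalar_volume(array(7, c(10, 10, 10)))
  res <- snr_at_point(cv, c(5, 5, 5))
  expect_true(is.infinite(res))
  expect_true(attr(res, "constant_window"))
  # clipped at border with warning
  expect_warning(snr_at_point(vol, c(0, 0, 0)), "clipped")
})

test_that("uncertainty summary handles identical and varied ensembles", {
  ball <- remesh_uniform(sphere_mesh(24, 8), 400L, seed = 1L)
  with_seed(2, img <- scalar_volume(array(rnorm(24^3, 100, 10),
                                          c(24, 24, 24))))
  same <- uq_summary(ball, list(ball, ball, ball), img)
  expect_equal(max(same$sd), 0)
  expect_error(uq_summary(ball, list(ball), img), "at least 2")
  # varied ensemble: SD positive where members differ; rank statistics
  # invariant to a global unit change (mm -> cm)
  members <- lapply(1:4, function(i) {
    m <- ball
    m$vertices <- m$vertices + matrix(with_seed(i, rnorm(
      length(m$vertices), sd = 0.2)), ncol = 3)
    m
  })
  s1 <- uq_summary(ball, members, img)
  expect_gt(min(s1$sd), 0)
  scale_mesh <- function(m) {
    m$vertices <- m$vertices / 10
    m
  }
  img_cm <- scalar_volume(img$values, spacing = img$spacing / 10,
                          origin = img$origin / 10)
  s2 <- uq_summary(scale_mesh(ball), lapply(members, scale_mesh), img_cm)
  # rank statistic: invariant up to floating-point window-rounding flips
  expect_equal(s1$spearman, s2$spearman, tolerance = 0.02)
})

test_that("metrics report aggregates Dice with region breakdown", {
  ph <- default_phantom(seed = 1L)
  pred <- ph$label
  rep1 <- metrics_report(pred, ph$label, region = ph$region)
  expect_equal(rep1$dice, 1)
  expect_equal(rep1$dice_main, 1)
  expect_equal(rep1$dice_branch, 1)
  # degrade the prediction only inside branches
  worse <- ph$label$values
  worse[ph$region > 1L] <- 0
  rep2 <- metrics_report(label_volume(worse, ph$label$spacing,
                                      ph$label$origin), ph$label,
                         region = ph$region)
  expect_equal(rep2$dice_main, 1)
  expect_lt(rep2$dice_branch, 0.1)
  expect_lt(rep2$dice, 1)
})
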