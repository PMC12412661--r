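test_that("volume I/O round-trips values and geometry in both formats", {
  with_seed(1, {
    vol <- scalar_volume(array(rnorm(16^3), c(16, 16, 16)),
                         spacing = c(1, 1, 2), origin = c(10, -3, 0.5))
  })
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    path <- tempfile(fileext = ext)
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(back$values, vol$values, label = ext)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-12)
    expect_equal(back$origin, vol$origin, tolerance = 1e-12)
  }
})

test_that("volume reading rejects non-3D data and unknown formats", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  p <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(64), 8, 8)), p)
  expect_error(read_volume(p), "3D")
  expect_error(volume_format <- vesselmesh:::volume_format("x.txt"),
               "unrecognised")
  expect_error(scalar_volume(array(1, c(4, 4))), "3D")
  expect_error(scalar_volume(array(1, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("index/world maps follow the affine and invert each other", {
  vol <- scalar_volume(array(0, c(8, 8, 8)))
  expect_equal(as.vector(index_to_world(vol, c(3, 4, 5))), c(3, 4, 5))
  vol2 <- scalar_volume(array(0, c(8, 8, 8)), spacing = c(2, 1, 1),
                        origin = c(10, 0, 0))
  expect_equal(as.vector(index_to_world(vol2, c(1, 0, 0))), c(12, 0, 0))
  with_seed(42, {
    p <- matrix(runif(300, -20, 40), 100, 3)
    round_trip <- world_to_index(vol2, index_to_world(vol2, p))
    expect_lt(max(abs(round_trip - p)), 1e-9)
  })
})

test_that("trilinear sampling reproduces affine fields and the 8-corner oracle", {
  d <- c(10, 10, 10)
  g <- expand.grid(i = 0:9, j = 0:9, k = 0:9)
  affine <- array(2 * g$i + 3 * g$j - g$k, d)
  vol <- scalar_volume(affine)
  expect_equal(as.vector(sample_trilinear(vol, c(5, 5, 5))), 5 * 2 + 15 - 5)
  with_seed(7, {
    pts <- matrix(runif(300, 0.5, 8.5), 100, 3)
    vals <- sample_trilinear(vol, pts)
    expect_lt(max(abs(vals - (2 * pts[, 1] + 3 * pts[, 2] - pts[, 3]))),
              1e-10)
  })
  # constant field
  cv <- scalar_volume(array(4.2, d))
  expect_equal(as.vector(sample_trilinear(cv, c(3.3, 7.9, 0.1))), 4.2)
  # brute-force corner-sum oracle on a random volume
  with_seed(8, {
    rv <- scalar_volume(array(rnorm(prod(d)), d))
    pts <- matrix(runif(300, 0, 8.999), 100, 3)
    vals <- sample_trilinear(rv, pts)
    oracle <- vapply(seq_len(100), function(r) {
      p <- pts[r, ]
      i0 <- floor(p)
      f <- p - i0
      acc <- 0
      for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
        w <- (if (di) f[1] else 1 - f[1]) * (if (dj) f[2] else 1 - f[2]) *
          (if (dk) f[3] else 1 - f[3])
        acc <- acc + w * rv$values[i0[1] + di + 1, i0[2] + dj + 1,
                                   i0[3] + dk + 1]
      }
      acc
    }, 0)
    expect_lt(max(abs(vals - oracle)), 1e-12)
  })
})

test_that("out-of-bounds samples are clamped and reported", {
  vol <- scalar_volume(array(1:27 * 1.0, c(3, 3, 3)))
  res <- sample_trilinear(vol, rbind(c(-5, 1, 1), c(1, 1, 1)))
  expect_equal(attr(res, "clamped_fraction"), 0.5)
  expect_equal(res[[1]], vol$values[1, 2, 2])
})

test_that("gradient magnitude matches analytic and brute-force references", {
  d <- c(12, 12, 12)
  # constant -> zero
  expect_equal(max(gradient_magnitude_volume(
    scalar_volume(array(3, d)))$values), 0)
  # ramp a per mm along x with spacing 2: interior magnitude |a|
  g <- expand.grid(i = 0:11, j = 0:11, k = 0:11)
  ramp <- scalar_volume(array(1.5 * g$i * 2, d), spacing = c(2, 1, 1))
  gm <- gradient_magnitude_volume(ramp)
  expect_equal(max(abs(gm$values[2:11, , ] - 1.5)), 0, tolerance = 1e-12)
  # random volume vs direct finite-difference loop
  with_seed(3, {
    rv <- scalar_volume(array(rnorm(prod(d)), d), spacing = c(1, 2, 0.5))
    gm <- gradient_magnitude_volume(rv)
    oracle <- array(0, d)
    v <- rv$values
    for (i in 1:12) for (j in 1:12) for (k in 1:12) {
      dx <- (v[min(i + 1, 12), j, k] - v[max(i - 1, 1), j, k]) /
        (if (i %in% c(1, 12)) 1 else 2) / 1
      dy <- (v[i, min(j + 1, 12), k] - v[i, max(j - 1, 1), k]) /
        (if (j %in% c(1, 12)) 1 else 2) / 2
      dz <- (v[i, j, min(k + 1, 12)] - v[i, j, max(k - 1, 1)]) /
        (if (k %in% c(1, 12)) 1 else 2) / 0.5
      oracle[i, j, k] <- sqrt(dx^2 + dy^2 + dz^2)
    }
    expect_lt(max(abs(gm$values - oracle)), 1e-10)
  })
})

test_that("gradient of an affine field is constant in the interior", {
  g <- expand.grid(i = 0:9, j = 0:9, k = 0:9)
  vol <- scalar_volume(array(1 + 2 * g$i - g$j + 0.5 * g$k, c(10, 10, 10)))
  gm <- gradient_magnitude_volume(vol)$values[2:9, 2:9, 2:9]
  expect_lt(diff(range(gm)), 1e-12)
})
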