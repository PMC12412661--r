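test_that("straight-tube label volume matches the analytic cylinder", {
  # slightly oblique, off-lattice tube so per-slice lattice quantization
  # averages out along the axis
  tpar <- seq(0, 1, length.out = 20)
  pts <- cbind(4 + 55 * tpar, 31.63 + 1.7 * tpar, 31.37 - 1.3 * tpar)
  spec <- phantom_spec(centerlines = list(centerline(pts, 5)),
                       blur_sigma = 0, noise_sd = 0)
  ph <- make_phantom(spec)
  # compare on an interior slab (x in [12, 52]) free of the rounded ends
  slab <- 13:53
  count <- sum(ph$label$values[slab, , ])
  analytic <- pi * 5^2 * length(slab)
  expect_lt(abs(count - analytic) / analytic, 0.02)
  # noise-free, blur-free image has exactly the two stated levels
  expect_setequal(unique(as.vector(ph$image$values)), c(50, 300))
})

test_that("phantom generation is bit-deterministic in the seed", {
  spec <- default_phantom_spec(seed = 3L)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$label$values, b$label$values)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
})

test_that("branches attach to the parent and unions are monotone", {
  spec0 <- default_phantom_spec(seed = 1L, n_branches = 0)
  spec3 <- default_phantom_spec(seed = 1L, n_branches = 3)
  lab0 <- make_phantom(spec0)$label$values
  ph3 <- default_phantom(seed = 1L)
  lab3 <- ph3$label$values
  expect_true(all(lab3 >= lab0))          # union is monotone
  expect_gt(sum(lab3), sum(lab0))
  # attached branches keep one connected component (6-connectivity BFS)
  d <- dim(lab3)
  comp <- array(FALSE, d)
  start <- which(lab3 == 1)[1]
  stack <- start
  comp[start] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    i <- (v - 1) %% d[1] + 1
    j <- ((v - 1) %/% d[1]) %% d[2] + 1
    k <- (v - 1) %/% (d[1] * d[2]) + 1
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 &&
          kk <= d[3] && lab3[ii, jj, kk] == 1 && !comp[ii, jj, kk]) {
        comp[ii, jj, kk] <- TRUE
        stack <- c(stack, ii + d[1] * (jj - 1) + d[1] * d[2] * (kk - 1))
      }
    }
  }
  expect_equal(sum(comp), sum(lab3))
  # region map labels every lumen voxel with its nearest centerline
  expect_setequal(sort(unique(as.vector(ph3$region))), 0:4)
  # branch exiting the grid errors; oversized branch radius warns
  expect_error(add_branch(spec0, takeoff = 0.95, angle = 10,
                          radius = 3, length = 200), "exits the grid")
  expect_warning(add_branch(spec0, takeoff = 0.5, angle = 60,
                            radius = 15, length = 10), "radius")
})

test_that("phantom mesh has one open cap per designated end", {
  ph <- default_phantom(seed = 1L)
  loops <- mesh_boundary_loops(ph$mesh)
  expect_length(loops, 5L)   # 2 main ends + 3 branch tips
  # mesh sits on the label's 0.5 isocontour (within one voxel)
  sv <- sample_trilinear(ph$label, ph$mesh$vertices)
  expect_true(all(sv > 0 & sv < 1))
})

test_that("voxelization classifies by nearest-vertex normal angle", {
  sph <- sphere_mesh(64, 8)
  tmpl <- scalar_volume(array(0, c(64, 64, 64)))
  lab <- voxelize_surface(sph, tmpl)
  ctr <- rep((64 - 1) / 2, 3)
  # interior and far-exterior voxels classify correctly
  expect_equal(lab$values[32, 32, 32], 1)
  expect_equal(lab$values[5, 5, 5], 0)
  # disagreement with the analytic ball confined to a 1-voxel shell
  g <- expand.grid(i = 0:63, j = 0:63, k = 0:63)
  r <- sqrt((g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2)
  analytic <- array(as.numeric(r < 8), c(64, 64, 64))
  wrong <- which(lab$values != analytic)
  if (length(wrong) > 0)
    expect_lt(max(abs(r[wrong] - 8)), 1)
})

test_that("voxelize(label isosurface) round-trips the phantom label", {
  ph <- default_phantom(seed = 1L)
  mesh <- extract_isosurface(ph$label)
  back <- voxelize_surface(mesh, ph$image)
  expect_gte(dice_coefficient(back, ph$label), 0.95)
})
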