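# Shared fixtures. Heavy objects (phantoms, trained models, recovery runs)
# are built once per session and cached so several test files can reuse
# them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

with_seed <- vesselmesh:::with_seed

# small analytic sphere field on an n^3 grid, radius r, centered
sphere_field <- function(n = 32L, r = 10) {
  ctr <- (n - 1) / 2
  ax <- (0:(n - 1)) - ctr
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  array(r - sqrt(r2), c(n, n, n))
}

sphere_mesh <- function(n = 32L, r = 10) {
  extract_isosurface(scalar_volume(sphere_field(n, r)), 0,
                     presmooth_labels = FALSE)
}

# deterministic smooth low-frequency vector field scaled to max amplitude
smooth_vector_field <- function(v, seed, amp = 2) {
  with_seed(seed, {
    out <- matrix(0, nrow(v), 3L)
    for (c in 1:3) {
      fr <- runif(3, 0.02, 0.06)
      ph <- runif(1, 0, 2 * pi)
      out[, c] <- sin(v %*% fr + ph)
    }
    amp * out / max(abs(out))
  })
}

default_phantom <- function(seed = 1L, ...) {
  fixture(paste0("phantom_", seed), function()
    make_phantom(default_phantom_spec(seed = seed, ...)))
}

# the scaled-down study configuration: 2 LoG levels, 8 base channels,
# 32^3 patches, 200 gradient steps on 6 phantoms
tiny_seg_config <- function(epochs = 200L) {
  seg_config(patch_size = 32L, base_channels = 8L, depth = 2L,
             log_sizes = c(3L, 7L), log_sigmas = c(1.0, 2.5),
             prior_sds = c(1.0, 2.5), epochs = epochs,
             learning_rate = 2e-3, init_log_sd = log(0.05),
             gate_draw = 1L, gate_capacity = 2L, seed = 11L)
}

trained_tiny_model <- function() {
  fixture("tiny_fit", function() {
    train_set <- lapply(1:6, function(s)
      make_phantom(default_phantom_spec(seed = s))[c("image", "label")])
    train_segmenter(train_set, tiny_seg_config())
  })
}

# perturbed-surface recovery setup shared by the deformation experiments:
# working ground truth = remeshed phantom surface with caps cut open,
# start = that surface displaced by a smooth random field of amplitude
# 2 voxels wherever the scaling gate allows motion. A longer-vessel
# phantom (72^3, main radius 7, one branch) keeps most of the wall
# outside the gate's frozen inlet/outlet zones.
recovery_setup <- function() {
  fixture("recovery_setup", function() {
    spec <- default_phantom_spec(grid_shape = c(72L, 72L, 72L),
                                 main_radius = 7, n_branches = 1,
                                 seed = 4L)
    ph <- make_phantom(spec)
    iso <- extract_isosurface(ph$label)
    gtw <- cut_phantom_caps(remesh_uniform(iso, 2000L, seed = 1L), spec)
    gate <- compute_scaling_field(gtw)
    pert <- gtw
    pert$vertices <- gtw$vertices +
      gate$alpha * smooth_vector_field(gtw$vertices, seed = 7L, amp = 2)
    list(spec = spec, phantom = ph, gt = gtw, start = pert, gate = gate)
  })
}

recovery_fit <- function() {
  fixture("recovery_fit", function() {
    rs <- recovery_setup()
    cfg <- deform_config(epochs = 300L, learning_rate = 5e-3, seed = 3L)
    optimize_deformation(rs$start, rs$phantom$image, cfg)
  })
}
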