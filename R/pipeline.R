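#' End-to-end pipeline configuration
#'
#' Bundles all stage configurations for the image-to-mesh workflow:
#' segment (patchwise probability + threshold), extract (isosurface),
#' remesh/smooth, deform (LDDMM alignment), metrics.
#'
#' @param input_image,input_label Optional paths to a volume and binary
#'   label; when `NULL` a synthetic phantom provides image and ground
#'   truth.
#' @param phantom A [phantom_spec()] used when no input image is given.
#' @param seg A [seg_config()] for training when no model is supplied.
#' @param model Optional pre-trained [seg_model()]/`seg_fit`.
#' @param train_cases Number of phantoms used to train a model when none
#'   is supplied.
#' @param threshold Probability threshold for the binary segmentation.
#' @param overlap Patch overlap at inference (voxels).
#' @param remesh_target Target vertex count of the initial surface.
#' @param smoothing A [smoothing_weights()].
#' @param deform A [deform_config()].
#' @param out_dir Output directory for artifacts (created if missing);
#'   `NULL` keeps everything in memory.
#' @param seed Global seed; every stochastic stage derives its own seed
#'   from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_image = NULL, input_label = NULL,
                            phantom = default_phantom_spec(),
                            seg = seg_config(), model = NULL,
                            train_cases = 6L, threshold = 0.5,
                            overlap = 16L, remesh_target = 2000L,
                            smoothing = smoothing_weights(iterations = 30L),
                            deform = deform_config(),
                            out_dir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  # stable per-stage seed derived from the global seed (32-bit safe)
  offsets <- c(phantom = 101L, train = 211L, predict = 307L,
               surface = 401L, deform = 503L, uq = 601L)
  (config$seed * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Run the image-to-mesh pipeline
#'
#' Stage order: acquire image (phantom or file) -> segment (train if
#' needed, predict, threshold) -> initial surface (isosurface, remesh,
#' smooth) -> diffeomorphic deformation against the image gradients ->
#' metrics against ground truth (when available). Artifacts and a
#' manifest (configs, seeds, content hashes) are written to `out_dir`
#' when set.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with `probability`,
#'   `segmentation`, `initial_mesh`, `deformed_mesh`, `histories`,
#'   `metrics`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # ---- stage: input ----
  if (!is.null(config$input_image)) {
    if (!file.exists(config$input_image))
      stop("input stage: image file not found: ", config$input_image)
    image <- read_volume(config$input_image)
    truth_label <- NULL
    if (!is.null(config$input_label)) {
      if (!file.exists(config$input_label))
        stop("input stage: label file not found: ", config$input_label)
      lv <- read_volume(config$input_label)
      truth_label <- label_volume(round(lv$values), lv$spacing, lv$origin)
    }
    truth_mesh <- NULL
    phantom_spec_used <- NULL
  } else {
    spec <- config$phantom
    spec$seed <- as.integer(stage_seed(config, "phantom"))
    ph <- make_phantom(spec)
    image <- ph$image
    truth_label <- ph$label
    truth_mesh <- ph$mesh
    phantom_spec_used <- spec
  }
  # ---- stage: segmentation ----
  model <- config$model
  train_history <- NULL
  if (is.null(model)) {
    train_seed <- stage_seed(config, "train")
    train_set <- lapply(seq_len(config$train_cases), function(i) {
      sp <- config$phantom
      sp$seed <- as.integer((train_seed + i) %% 2147483647)
      make_phantom(sp)[c("image", "label")]
    })
    segcfg <- config$seg
    segcfg$seed <- as.integer(train_seed)
    fit <- train_segmenter(train_set, segcfg)
    model <- fit$model
    train_history <- fit$history
  }
  prob <- predict_volume(model, clip_normalize(image),
                         overlap = config$overlap)
  seg_label <- label_volume(
    array(as.numeric(prob$values >= config$threshold), dim(prob$values)),
    prob$spacing, prob$origin)
  if (sum(seg_label$values) == 0)
    stop("segmentation stage: thresholded volume is empty")
  seg_label <- label_largest_component(seg_label)
  # ---- stage: initial surface ----
  surf <- extract_isosurface(seg_label)
  surf <- remesh_uniform(surf, config$remesh_target,
                         seed = stage_seed(config, "surface"))
  surf <- smooth_mesh(surf, config$smoothing)
  if (!is.null(phantom_spec_used))
    surf <- cut_phantom_caps(surf, phantom_spec_used)
  # ---- stage: deformation ----
  defcfg <- config$deform
  defcfg$seed <- as.integer(stage_seed(config, "deform"))
  dfit <- optimize_deformation(surf, image, defcfg)
  # ---- stage: metrics ----
  metrics <- NULL
  if (!is.null(truth_label)) {
    metrics <- metrics_report(seg_label, truth_label,
                              pred_mesh = dfit$mesh,
                              truth_mesh = truth_mesh)
    metrics$asd_initial <- if (!is.null(truth_mesh))
      asd(surf, truth_mesh) else NULL
  }
  result <- structure(
    list(probability = prob, segmentation = seg_label,
         initial_mesh = surf, deformed_mesh = dfit$mesh,
         histories = list(train = train_history, deform = dfit$history),
         metrics = metrics, truth_mesh = truth_mesh,
         truth_label = truth_label, image = image, model = model,
         config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir))
    result$manifest <- write_pipeline_artifacts(result, config$out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wv <- function(vol, name) {
    p <- file.path(out_dir, name)
    write_volume(vol, p)
    paths[[name]] <<- p
  }
  wm <- function(mesh, name) {
    p <- file.path(out_dir, name)
    write_mesh(mesh, p)
    paths[[name]] <<- p
  }
  wv(result$probability, "probability.nii.gz")
  wv(result$segmentation, "segmentation.nii.gz")
  wm(result$initial_mesh, "initial_surface.ply")
  wm(result$deformed_mesh, "deformed_surface.ply")
  if (!is.null(result$histories$deform)) {
    p <- file.path(out_dir, "deform_history.csv")
    write.csv(result$histories$deform, p, row.names = FALSE)
    paths[["deform_history.csv"]] <- p
  }
  if (!is.null(result$histories$train)) {
    p <- file.path(out_dir, "train_history.csv")
    write.csv(result$histories$train, p, row.names = FALSE)
    paths[["train_history.csv"]] <- p
  }
  if (!is.null(result$metrics)) {
    p <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(unclass(result$metrics), p, auto_unbox = TRUE,
                         digits = NA)
    paths[["metrics.json"]] <- p
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("vesselmesh")),
    seed = result$config$seed,
    stage_seeds = sapply(c("phantom", "train", "predict", "surface",
                           "deform"), function(s)
      stage_seed(result$config, s)),
    artifacts = lapply(paths, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Propagate segmentation uncertainty to surface ensembles
#'
#' Draws `n_samples` posterior segmentations, turns each into a smoothed
#' surface and a deformed surface (shared deformation config), and
#' summarizes per-point SD of both ensembles against their mean surfaces
#' along with the image SNR relation.
#'
#' @param config A [pipeline_config()] with a trained `model`.
#' @param n_samples Ensemble size (at least 2).
#' @return List of class `uq_result`: `members` (per-member smoothed and
#'   deformed meshes), `uq_smoothed`, `uq_deformed` (from
#'   [uq_summary()]), `member_seeds`, `image`.
#' @export
run_uq_pipeline <- function(config, n_samples) {
  stopifnot(inherits(config, "pipeline_config"))
  if (n_samples < 2L) stop("need at least 2 ensemble members")
  if (is.null(config$model))
    stop("run_uq_pipeline requires a trained model in config$model")
  spec <- config$phantom
  spec$seed <- as.integer(stage_seed(config, "phantom"))
  ph <- make_phantom(spec)
  image <- ph$image
  norm <- clip_normalize(image)
  uq_seed <- stage_seed(config, "uq")
  ens <- sample_segmentations(config$model, norm, n = n_samples,
                              seed = uq_seed, overlap = config$overlap)
  member_seeds <- uq_seed + seq_len(n_samples)
  smoothed <- list(); deformed <- list()
  for (i in seq_len(n_samples)) {
    # member surface from the thresholded sample (labels smoothed in
    # extract_isosurface), remeshed and regularized like the main path
    surf <- extract_isosurface(label_largest_component(ens$members[[i]]))
    surf <- remesh_uniform(surf, config$remesh_target,
                           seed = stage_seed(config, "surface") + i)
    surf <- smooth_mesh(surf, config$smoothing)
    surf <- cut_phantom_caps(surf, spec)
    smoothed[[i]] <- surf
    defcfg <- config$deform
    defcfg$seed <- as.integer((stage_seed(config, "deform") + i) %%
                                2147483647)
    deformed[[i]] <- optimize_deformation(surf, image, defcfg)$mesh
  }
  # reference (mean) surface from the thresholded ensemble-mean probability
  mean_lab <- label_largest_component(label_volume(
    array(as.numeric(ens$mean$values >= 0.5), dim(ens$mean$values)),
    image$spacing, image$origin))
  mean_surf <- extract_isosurface(mean_lab)
  mean_surf <- remesh_uniform(mean_surf, config$remesh_target,
                              seed = stage_seed(config, "surface"))
  mean_surf <- smooth_mesh(mean_surf, config$smoothing)
  mean_surf <- cut_phantom_caps(mean_surf, spec)
  uq_sm <- uq_summary(mean_surf, smoothed, image)
  uq_df <- uq_summary(mean_surf, deformed, image)
  structure(list(members = list(smoothed = smoothed, deformed = deformed),
                 uq_smoothed = uq_sm, uq_deformed = uq_df,
                 mean_surface = mean_surf,
                 member_seeds = member_seeds, image = image,
                 segmentation_ensemble = ens),
            class = "uq_result")
}

#' Keep only the largest connected component of a binary label
#'
#' 6-connectivity flood fill; removes speckle islands from thresholded
#' segmentations before surface extraction.
#'
#' @param label A [label_volume()].
#' @return A [label_volume()] containing the largest foreground component.
#' @export
label_largest_component <- function(label) {
  if (sum(label$values) == 0) return(label)
  comp <- label_components_cpp(label$values)
  counts <- tabulate(comp[comp > 0L])
  keep <- which.max(counts)
  out <- array(as.numeric(comp == keep), dim(label$values))
  label_volume(out, label$spacing, label$origin)
}
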