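#' Pipeline run configuration
#'
#' One object holding all stage parameters plus a master seed. The master
#' seed expands into named substreams per stage, so every stage is
#' reproducible on its own and artifacts record their provenance in JSON
#' sidecars.
#'
#' @param out_dir output directory.
#' @param grid_shape phantom grid.
#' @param n_networks,rois_per_network,roi_radius atlas parameters.
#' @param n_subjects,n_frames,tr cohort parameters.
#' @param sim a [simulation_spec()].
#' @param samples_per_network,n_rois_range,val_subject_fraction training-set
#'   parameters.
#' @param aug an [augment_params()].
#' @param cnn a [cnn_config()] or `NULL` for the default sized to
#'   `n_networks`.
#' @param sched a [train_schedule()].
#' @param wta_threshold display threshold for the WTA segmentation.
#' @param frame_grid,fraction_grid robustness evaluation grids (`NULL`
#'   skips a protocol).
#' @param rng_seed master seed.
#' @return a `run_config`.
#' @export
run_config <- function(out_dir, grid_shape = c(16, 16, 16), n_networks = 4L,
                       rois_per_network = 3L, roi_radius = 2L, n_subjects = 3L,
                       n_frames = 200L, tr = 2.2, sim = simulation_spec(),
                       samples_per_network = 40L, n_rois_range = c(1L, 3L),
                       val_subject_fraction = 0.34, aug = augment_params(),
                       cnn = NULL, sched = train_schedule(max_epochs = 6L),
                       wta_threshold = 0.2, frame_grid = NULL,
                       fraction_grid = NULL, rng_seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full phantom pipeline
#'
#' simulate -> build samples -> train -> infer -> group statistics ->
#' evaluate, writing every artifact (NIfTI volumes, TSV tables, model
#' checkpoint) with a JSON sidecar recording the seed and stage. Re-running
#' with an identical configuration reproduces all artifacts.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_seed <- function(name) substream_seed(config$rng_seed, name)

  say("[simulate] atlas + %d-subject cohort", config$n_subjects)
  atlas <- make_phantom_atlas(config$grid_shape, config$n_networks,
                              config$rois_per_network, config$roi_radius,
                              rng_seed = stage_seed("atlas"))
  validate_atlas(atlas)
  write_atlas(atlas, file.path(out, "atlas"))
  scans <- simulate_cohort(atlas, config$sim, config$n_subjects,
                           config$n_frames, config$tr,
                           rng_seed = stage_seed("cohort"))
  for (s in scans)
    write_scan(s, file.path(out, paste0(s$subject_id, "_bold.nii.gz")),
               sidecar = list(seed = config$rng_seed, stage = "simulate"))

  say("[build-samples] %d per network", config$samples_per_network)
  tset <- build_training_set(scans, atlas, config$samples_per_network,
                             config$n_rois_range, config$val_subject_fraction,
                             config$aug, rng_seed = stage_seed("samples"))

  say("[train]")
  cnn <- config$cnn %||% cnn_config(n_classes = config$n_networks)
  sched <- config$sched
  sched$rng_seed <- stage_seed("train")
  model <- fit_rsn_classifier(cnn, tset, sched, verbose = verbose)
  save_model(model, file.path(out, "model.rds"))
  export_history(model, file.path(out, "training_history.tsv"))

  say("[infer] voxelwise probability maps")
  pms <- lapply(scans, function(s) voxelwise_probability_maps(model, s))
  for (pm in pms)
    write_probability_maps(pm, file.path(out, pm$subject_id),
                           networks = atlas$networks)

  say("[group-stats]")
  gm <- group_statistics(pms)
  write_probability_maps(gm, file.path(out, "group"),
                         networks = atlas$networks)
  seg <- wta_segmentation(gm, config$wta_threshold)
  write_segmentation(seg, file.path(out, "wta.nii.gz"))
  seg0 <- wta_segmentation(gm, 0)
  summ <- network_summary(gm, seg0)
  summ$network <- atlas$networks[summ$network]
  export_tsv(summ, file.path(out, "network_summary.tsv"))
  export_tsv(suprathreshold_counts(gm), file.path(out, "suprathreshold_counts.tsv"))

  say("[evaluate]")
  if (!is.null(config$frame_grid)) {
    rc <- robustness_frames(model, scans[[1]], frame_grid = config$frame_grid)
    export_tsv(rc, file.path(out, "robustness_frames.tsv"))
  }
  if (!is.null(config$fraction_grid)) {
    rc <- robustness_noise(model, scans[[1]], fraction_grid = config$fraction_grid,
                           rng_seed = stage_seed("noise"))
    export_tsv(rc, file.path(out, "robustness_noise.tsv"))
  }
  export_tsv(softmax_connectivity(pms[[1]], atlas, "roi"),
             file.path(out, "conn_softmax_roi.tsv"))
  export_tsv(timeseries_connectivity(scans[[1]], atlas, "roi"),
             file.path(out, "conn_timeseries_roi.tsv"))
  jsonlite::write_json(list(seed = config$rng_seed,
                            grid = config$grid_shape,
                            n_networks = config$n_networks,
                            n_subjects = config$n_subjects),
                       file.path(out, "run.json"), auto_unbox = TRUE)
  invisible(out)
}

#' Generate a self-contained fixture bundle
#'
#' Writes a small phantom atlas, cohort, and golden similarity map used by
#' oracle tests; regeneration with the same seed is reproducible.
#'
#' @param path output directory.
#' @param size `"tiny"` (6^3 grid) or `"small"` (12^3).
#' @param rng_seed integer seed.
#' @return `path` invisibly.
#' @export
make_fixtures <- function(path, size = c("tiny", "small"), rng_seed = 1L) {
  size <- match.arg(size)
  dims <- if (size == "tiny") c(8, 8, 8) else c(12, 12, 12)
  k <- if (size == "tiny") 2L else 3L
  atlas <- make_phantom_atlas(dims, k, 2L, 1L,
                              rng_seed = substream_seed(rng_seed, "atlas"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_atlas(atlas, file.path(path, "atlas"))
  scans <- simulate_cohort(atlas, simulation_spec(), 2L, 60L, 2.2,
                           rng_seed = substream_seed(rng_seed, "cohort"))
  for (s in scans)
    write_scan(s, file.path(path, paste0(s$subject_id, "_bold.nii.gz")))
  seed_series <- mean_seed_signal(scans[[1]], atlas$rois[[1]]$voxels)
  sm <- similarity_map(scans[[1]], seed_series)
  write_nifti(unclass(sm), file.path(path, "golden_similarity.nii.gz"))
  jsonlite::write_json(list(seed = rng_seed, size = size,
                            seed_roi = atlas$rois[[1]]$roi_id),
                       file.path(path, "fixtures.json"), auto_unbox = TRUE)
  invisible(path)
}
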