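# Shared fixtures, built once per test run (lazy, memoised).

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small 8^3 two-network phantom with a cohort and a clean (noise-free) twin
tiny_atlas <- function() memo("tiny_atlas", function() {
  make_phantom_atlas(c(8, 8, 8), n_networks = 2, rois_per_network = 2,
                     roi_radius = 1, rng_seed = 3)
})

tiny_scans <- function() memo("tiny_scans", function() {
  simulate_cohort(tiny_atlas(), simulation_spec(), n_subjects = 4,
                  n_frames = 80, tr = 2.2, rng_seed = 3)
})

clean_scan <- function() memo("clean_scan", function() {
  simulate_scan(tiny_atlas(), simulation_spec(noise_sd = 0, subject_jitter = 0),
                n_frames = 80, tr = 2.2, subject_id = "clean", rng_seed = 5)
})

# hand-built scan from an explicit T x nvox series matrix on a full mask
scan_from_series <- function(S, dims = NULL, mask = NULL) {
  n <- ncol(S)
  if (is.null(dims)) dims <- c(n, 1, 1)
  if (is.null(mask)) mask <- array(TRUE, dims)
  data <- array(0, c(dims, nrow(S)))
  nv <- prod(dims)
  vox <- which(mask)
  for (t in seq_len(nrow(S))) data[vox + (t - 1) * nv] <- S[t, ]
  structure(list(data = data, tr = 1, mask = mask, subject_id = "manual"),
            class = "bold_scan")
}

# probability_maps built directly from an in-mask probability matrix
pm_from_matrix <- function(P, mask) {
  dims <- dim(mask)
  nv <- prod(dims)
  K <- ncol(P)
  probs <- array(0, c(dims, K))
  vox <- which(mask)
  for (k in seq_len(K)) probs[vox + (k - 1) * nv] <- P[, k]
  structure(list(probs = probs, mask = mask, subject_id = "manual",
                 n_networks = K),
            class = "probability_maps")
}

# an untrained (randomly initialized) model for contract tests
tiny_model <- function() memo("tiny_model", function() {
  set.seed(7)
  build_model(cnn_config(n_classes = 2, n_dense_blocks = 2, units_per_block = 1,
                         growth = 4, stem_channels = 4, block_kernels = c(3, 3),
                         dropout = 0.2),
              c(8, 8, 8))
})

# a quickly trained model on a separable (noise-free-ish) tiny phantom
tiny_trained <- function() memo("tiny_trained", function() {
  atlas <- tiny_atlas()
  scans <- simulate_cohort(atlas, simulation_spec(noise_sd = 0.3),
                           n_subjects = 4, n_frames = 80, rng_seed = 9)
  tset <- build_training_set(scans, atlas, samples_per_network = 40,
                             n_rois_range = c(1, 2),
                             val_subject_fraction = 0.25, rng_seed = 9)
  model <- fit_rsn_classifier(
    cnn_config(n_classes = 2, n_dense_blocks = 2, units_per_block = 1,
               growth = 4, stem_channels = 4, block_kernels = c(3, 3)),
    tset, train_schedule(max_epochs = 30, batch_size = 8,
                         learning_rate = 3e-3, validation_interval = 3,
                         rng_seed = 9))
  list(model = model, tset = tset, atlas = atlas, scans = scans)
})
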