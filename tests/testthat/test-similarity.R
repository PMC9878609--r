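test_that("mean seed signal is the framewise mean over voxels", {
  S <- cbind(c(1, 2), c(3, 4))
  scan <- scan_from_series(S)
  expect_equal(mean_seed_signal(scan, 1:2), c(2, 3))
  expect_equal(mean_seed_signal(scan, 1), S[, 1])       # single voxel: identity
  scan2 <- scan_from_series(cbind(c(1, 5, 2), c(1, 5, 2)))
  expect_equal(mean_seed_signal(scan2, 1:2), c(1, 5, 2))  # identical series
  expect_error(mean_seed_signal(scan, integer(0)), class = "empty_voxel_set")
  mask <- array(c(TRUE, FALSE), c(2, 1, 1))
  scan3 <- scan_from_series(matrix(c(1, 2), 2, 1), dims = c(2, 1, 1), mask = mask)
  expect_error(mean_seed_signal(scan3, 2), class = "out_of_mask")
})

test_that("similarity map honors the hand-computed arithmetic examples", {
  # voxel series: itself, its negation (after centering), and [3,2,1]
  S <- cbind(c(1, 2, 3), c(3, 2, 1), c(10, 20, 30))
  scan <- scan_from_series(S)
  sm <- similarity_map(scan, c(1, 2, 3))
  expect_equal(sm[1, 1, 1, 1], 1)
  expect_equal(sm[1, 1, 1, 2], 0)
  expect_equal(sm[2, 1, 1, 1], -1)
  expect_equal(sm[2, 1, 1, 2], sqrt(8) / sqrt(3), tolerance = 1e-12)  # z +/-1
  expect_equal(sm[3, 1, 1, 1], 1)        # linear rescaling preserves r
  expect_error(similarity_map(scan, c(2, 2, 2)), class = "degenerate_seed")
})

test_that("zero-variance voxels get r = 0 and the zero-vector distance", {
  S <- cbind(c(1, 2, 3, 4), rep(5, 4))
  scan <- scan_from_series(S)
  sm <- similarity_map(scan, c(1, 3, 2, 4))
  expect_equal(sm[2, 1, 1, 1], 0)
  Tn <- 4
  expect_equal(sm[2, 1, 1, 2], sqrt(Tn - 1) / sqrt(Tn))
})

test_that("channel 0 equals brute-force per-voxel Pearson on a small phantom", {
  atlas <- make_phantom_atlas(c(8, 8, 8), 2, 2, 1, rng_seed = 1)
  scan <- simulate_scan(atlas, simulation_spec(), 50, rng_seed = 1)
  seed_series <- mean_seed_signal(scan, atlas$rois[[1]]$voxels)
  sm <- similarity_map(scan, seed_series)
  in_mask <- which(atlas$mask)
  nv <- prod(dim(scan$data)[1:3])
  for (v in in_mask) {
    series <- scan$data[v + (seq_len(50) - 1) * nv]
    expect_equal(sm[v], cor(seed_series, series), tolerance = 1e-10)
  }
  # distance channel against its definition
  zs <- (seed_series - mean(seed_series)) / sd(seed_series)
  v <- in_mask[5]
  series <- scan$data[v + (seq_len(50) - 1) * nv]
  zv <- (series - mean(series)) / sd(series)
  expect_equal(sm[v + nv], sqrt(sum((zs - zv)^2)) / sqrt(50), tolerance = 1e-10)
  # zero outside mask
  out <- which(!atlas$mask)
  expect_true(all(sm[out] == 0) && all(sm[out + nv] == 0))
})

test_that("label confirmation returns the planted network and errors on ties", {
  atlas <- tiny_atlas()
  scan <- clean_scan()
  ni <- vapply(atlas$rois, `[[`, integer(1), "network_index")
  for (k in 1:2) {
    seed_series <- mean_seed_signal(scan, atlas$rois[[which(ni == k)[1]]]$voxels)
    expect_identical(confirm_label(scan, seed_series, atlas), k)
  }
  # seed equal to a network's full mean signal
  vox1 <- unlist(lapply(atlas$rois[ni == 1], `[[`, "voxels"))
  expect_identical(confirm_label(scan, mean_seed_signal(scan, vox1), atlas), 1L)
  # identical network signals make the argmax an exact tie
  tie_scan <- scan
  s <- rnorm(80)
  nv <- prod(atlas$grid_shape)
  for (roi in atlas$rois)
    for (v in roi$voxels)
      tie_scan$data[v + (seq_len(80) - 1) * nv] <- s
  seed_series <- mean_seed_signal(tie_scan, atlas$rois[[1]]$voxels)
  expect_error(confirm_label(tie_scan, seed_series, atlas), class = "label_tie")
})

test_that("ROI subsampling is deterministic and bounded", {
  atlas <- make_phantom_atlas(c(10, 10, 10), 2, 3, 1, rng_seed = 5)
  full <- subsample_network_rois(atlas, 1, 3, rng_seed = 1)
  expect_length(full, 3)
  expect_true(all(vapply(full, `[[`, integer(1), "network_index") == 1))
  expect_error(subsample_network_rois(atlas, 1, 4), class = "roi_subsample_error")
  expect_identical(subsample_network_rois(atlas, 2, 2, rng_seed = 4),
                   subsample_network_rois(atlas, 2, 2, rng_seed = 4))
})

test_that("augmentation with zero bounds is the identity and preserves labels", {
  atlas <- tiny_atlas()
  scan <- tiny_scans()[[1]]
  seed_series <- mean_seed_signal(scan, atlas$rois[[1]]$voxels)
  s <- rsnmap:::new_similarity_sample(similarity_map(scan, seed_series), 1L, "sub-01")
  id_params <- augment_params(rot_deg = 0, trans_vox = 0, shear_deg = 0,
                              intensity_range = c(1, 1), gauss_sd = 0)
  expect_equal(augment_sample(s, id_params, rng_seed = 1)$channels, s$channels)
  aug <- augment_sample(s, augment_params(), rng_seed = 2)
  expect_identical(aug$label, s$label)
  expect_identical(aug$subject_id, s$subject_id)
  expect_true(all(aug$channels[, , , 1] >= -1 & aug$channels[, , , 1] <= 1))
  expect_identical(augment_sample(s, augment_params(), rng_seed = 2)$channels,
                   aug$channels)
})

test_that("augmentation draws respect their bounds over many samples", {
  p <- augment_params(rot_deg = 5, trans_vox = 3, shear_deg = 3)
  set.seed(11)
  draws <- replicate(1000, rsnmap:::draw_augmentation(p), simplify = FALSE)
  expect_true(all(vapply(draws, function(d) max(abs(d$rot)), numeric(1)) <= 5))
  expect_true(all(vapply(draws, function(d) max(abs(d$trans)), numeric(1)) <= 3))
  expect_true(all(vapply(draws, function(d) max(abs(d$shear)), numeric(1)) <= 3))
  sc <- vapply(draws, `[[`, numeric(1), "scale")
  expect_true(all(sc >= 0.9 & sc <= 1.1))
})

test_that("training sets are balanced, subject-disjoint, and deterministic", {
  atlas <- tiny_atlas()
  scans <- tiny_scans()
  tset <- build_training_set(scans, atlas, samples_per_network = 16,
                             n_rois_range = c(1, 2), val_subject_fraction = 0.25,
                             rng_seed = 13)
  expect_length(tset$samples, 32)
  expect_equal(tset$class_counts, c(16L, 16L))
  expect_equal(tset$class_weights, c(1, 1))
  labels <- vapply(tset$samples, `[[`, integer(1), "label")
  subj <- vapply(tset$samples, `[[`, character(1), "subject_id")
  expect_length(intersect(subj[tset$split == "train"], subj[tset$split == "val"]), 0)
  expect_length(tset$val_subjects, 1)     # 25% of 4 subjects
  expect_setequal(unique(labels[tset$split == "train"]), 1:2)
  expect_setequal(unique(labels[tset$split == "val"]), 1:2)
  expect_lt(tset$discard_rate, 0.5)
  for (s in tset$samples) expect_silent(validate_sample(s, atlas$mask, 2))
  tset2 <- build_training_set(scans, atlas, samples_per_network = 16,
                              n_rois_range = c(1, 2), val_subject_fraction = 0.25,
                              rng_seed = 13)
  expect_identical(tset$samples[[5]]$channels, tset2$samples[[5]]$channels)
})

test_that("class weights satisfy the balance identity", {
  expect_equal(compute_class_weights(c(10, 10, 10)), c(1, 1, 1))
  expect_equal(compute_class_weights(c(100, 50)), c(0.75, 1.5))
  expect_equal(compute_class_weights(c(100, 50)) * c(100, 50), c(75, 75))
  set.seed(1)
  for (i in 1:20) {
    counts <- sample(1:500, sample(2:13, 1))
    w <- compute_class_weights(counts)
    expect_equal(var(w * counts), 0)
    expect_equal(sum(w * counts) / sum(counts), 1)
  }
  expect_error(compute_class_weights(c(5, 0)), class = "zero_class_count")
})
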