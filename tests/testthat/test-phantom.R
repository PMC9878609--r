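test_that("phantom atlas satisfies its invariants and is deterministic", {
  a1 <- make_phantom_atlas(c(16, 16, 16), n_networks = 4, rois_per_network = 3,
                           roi_radius = 1, rng_seed = 7)
  expect_silent(validate_atlas(a1))
  expect_length(a1$rois, 12)
  # a radius-1 sphere contains at most 7 voxels (center + 6 faces)
  expect_true(all(lengths(lapply(a1$rois, `[[`, "voxels")) <= 7))

  a2 <- make_phantom_atlas(c(16, 16, 16), n_networks = 4, rois_per_network = 3,
                           roi_radius = 1, rng_seed = 7)
  expect_identical(a1$rois, a2$rois)
  expect_identical(a1$mask, a2$mask)

  a3 <- make_phantom_atlas(c(16, 16, 16), n_networks = 4, rois_per_network = 3,
                           roi_radius = 1, rng_seed = 8)
  expect_false(identical(a1$rois, a3$rois))
})

test_that("impossible ROI placement raises a placement error", {
  expect_error(make_phantom_atlas(c(4, 4, 4), n_networks = 13,
                                  rois_per_network = 23, roi_radius = 2),
               class = "placement_failure")
})

test_that("simulated scans are mean-centered, masked, and valid", {
  scan <- tiny_scans()[[1]]
  expect_silent(validate_scan(scan))
  in_mask <- which(scan$mask)
  S <- rsnmap:::series_matrix(scan, in_mask)
  expect_lt(max(abs(colMeans(S))), 1e-10)
  out <- which(!scan$mask)
  expect_true(all(scan$data[out] == 0))
})

test_that("noise-free identity-correlation phantom separates networks exactly", {
  atlas <- tiny_atlas()
  scan <- clean_scan()
  ni <- vapply(atlas$rois, `[[`, integer(1), "network_index")
  v1 <- atlas$rois[[which(ni == 1)[1]]]$voxels[1]
  v1b <- atlas$rois[[which(ni == 1)[2]]]$voxels[1]
  v2 <- atlas$rois[[which(ni == 2)[1]]]$voxels[1]
  s <- rsnmap:::series_matrix(scan, c(v1, v1b, v2))
  expect_equal(cor(s[, 1], s[, 2]), 1, tolerance = 1e-10)
  expect_lt(abs(cor(s[, 1], s[, 3])), 0.3)   # independent latents, finite T
})

test_that("planted structure: within-network correlation exceeds between", {
  atlas <- make_phantom_atlas(c(12, 12, 12), n_networks = 3,
                              rois_per_network = 2, roi_radius = 1, rng_seed = 2)
  scan <- simulate_scan(atlas, simulation_spec(), n_frames = 400, rng_seed = 2)
  ni <- vapply(atlas$rois, `[[`, integer(1), "network_index")
  vox <- unlist(lapply(atlas$rois, `[[`, "voxels"))
  net <- rep(ni, lengths(lapply(atlas$rois, `[[`, "voxels")))
  # brute-force mean pairwise correlations over all ROI voxel pairs
  R <- cor(rsnmap:::series_matrix(scan, vox))
  same <- outer(net, net, "=="); diag(same) <- NA
  within <- mean(R[which(same)])
  between <- mean(R[which(!same)])
  expect_gt(within, between)
  expect_gt(within, 0.2)
  expect_lt(abs(between), 0.2)
})

test_that("voxel noise has a 1/f spectrum (log-log slope near -1)", {
  atlas <- tiny_atlas()
  scan <- simulate_scan(atlas, simulation_spec(within_network_weight = 0,
                                               subject_jitter = 0),
                        n_frames = 2048, rng_seed = 4)
  vox <- which(atlas$mask)[1:40]
  S <- rsnmap:::series_matrix(scan, vox)
  n <- nrow(S)
  P <- abs(stats::mvfft(S))^2 / n
  f <- seq_len(n %/% 2 - 1) / n
  mid <- f >= 0.01 & f <= 0.2
  pw <- rowMeans(P[1 + seq_len(n %/% 2 - 1), ])   # mean periodogram over voxels
  fit <- stats::lm(log(pw[mid]) ~ log(f[mid]))
  expect_gt(coef(fit)[2], -1.2)
  expect_lt(coef(fit)[2], -0.8)
})

test_that("cohorts are reproducible with distinct per-subject draws", {
  scans <- tiny_scans()
  expect_length(scans, 4)
  expect_identical(unique(vapply(scans, `[[`, character(1), "subject_id")) |> length(), 4L)
  expect_false(identical(scans[[1]]$data, scans[[2]]$data))
  expect_true(all(vapply(scans, function(s) identical(dim(s$data), dim(scans[[1]]$data)),
                         logical(1))))
  again <- simulate_cohort(tiny_atlas(), simulation_spec(), 4, 80, 2.2, rng_seed = 3)
  expect_identical(scans[[2]]$data, again[[2]]$data)
  # subject substreams: subject i unchanged when the cohort grows
  bigger <- simulate_cohort(tiny_atlas(), simulation_spec(), 5, 80, 2.2, rng_seed = 3)
  expect_identical(scans[[3]]$data, bigger[[3]]$data)
})

test_that("group-mean within-network correlation matches the single-subject level", {
  atlas <- tiny_atlas()
  scans <- simulate_cohort(atlas, simulation_spec(subject_jitter = 0), 10, 200,
                           rng_seed = 21)
  ni <- vapply(atlas$rois, `[[`, integer(1), "network_index")
  vox <- unlist(lapply(atlas$rois, `[[`, "voxels"))
  net <- rep(ni, lengths(lapply(atlas$rois, `[[`, "voxels")))
  same <- outer(net, net, "=="); diag(same) <- NA
  within_mean <- vapply(scans, function(s) {
    R <- cor(rsnmap:::series_matrix(s, vox))
    mean(R[which(same)])
  }, numeric(1))
  ref <- mean(cor(rsnmap:::series_matrix(
    simulate_scan(atlas, simulation_spec(subject_jitter = 0), 200, rng_seed = 99),
    vox))[which(same)])
  expect_lt(abs(mean(within_mean) - ref), 0.1)
})

test_that("invalid cross-network correlation matrices are rejected", {
  expect_error(simulation_spec(cross_network_corr = matrix(c(1, 2, 2, 1), 2)),
               class = "invalid_spec")
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)  # non-PSD
  expect_error(simulation_spec(cross_network_corr = bad), class = "invalid_spec")
})
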