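test_that("pink noise is zero-mean, seeded, and 1/f-sloped", {
  x <- pink_noise_series(4096, rng_seed = 1)
  expect_lt(abs(mean(x)), 1e-10)
  expect_identical(x, pink_noise_series(4096, rng_seed = 1))
  expect_false(identical(x, pink_noise_series(4096, rng_seed = 2)))
  # periodogram + least-squares slope oracle
  n <- length(x)
  P <- abs(fft(x))^2 / n
  f <- seq_len(n %/% 2 - 1) / n
  pw <- P[1 + seq_len(n %/% 2 - 1)]
  fit <- lm(log(pw) ~ log(f))
  expect_gt(coef(fit)[2], -1.2)
  expect_lt(coef(fit)[2], -0.8)
})

test_that("noise injection hits the exact signal and noise intervals", {
  scan <- tiny_scans()[[1]]
  f <- 0.1
  noisy <- inject_noise(scan, noise_spec(f), rng_seed = 7)
  in_mask <- which(scan$mask)
  S <- rsnmap:::series_matrix(scan, in_mask)
  O <- rsnmap:::series_matrix(noisy, in_mask)
  # independent oracle for the signal rescaling: min -> -(1-f), max -> +(1-f)
  for (v in sample(ncol(S), 20)) {
    x <- S[, v]
    resc <- (x - min(x)) / (max(x) - min(x)) * 2 * (1 - f) - (1 - f)
    expect_equal(range(resc), c(-0.9, 0.9), tolerance = 1e-12)
    noise_part <- O[, v] - resc
    expect_equal(range(noise_part), c(-0.1, 0.1), tolerance = 1e-12)
  }
  expect_lte(max(abs(O)), 1)
})

test_that("zero-fraction injection returns the rescaled signal unchanged", {
  scan <- tiny_scans()[[2]]
  out <- inject_noise(scan, noise_spec(0), rng_seed = 1)
  in_mask <- which(scan$mask)
  S <- rsnmap:::series_matrix(scan, in_mask)
  O <- rsnmap:::series_matrix(out, in_mask)
  expect_equal(unname(apply(O, 2, min)), rep(-1, ncol(O)), tolerance = 1e-12)
  expect_equal(unname(apply(O, 2, max)), rep(1, ncol(O)), tolerance = 1e-12)
  # rescaling is per-voxel affine, so correlations are preserved
  expect_equal(cor(S[, 1], S[, 2]), cor(O[, 1], O[, 2]), tolerance = 1e-12)
})

test_that("injected noise is independent across voxels", {
  scan <- simulate_scan(tiny_atlas(), simulation_spec(within_network_weight = 0,
                                                      subject_jitter = 0),
                        n_frames = 600, rng_seed = 3)
  clean <- inject_noise(scan, noise_spec(0), rng_seed = 5)
  noisy <- inject_noise(scan, noise_spec(0.5), rng_seed = 5)
  in_mask <- which(scan$mask)
  idx <- seq(1, length(in_mask), length.out = 12)
  N <- rsnmap:::series_matrix(noisy, in_mask[idx]) -
    0.5 * rsnmap:::series_matrix(clean, in_mask[idx])
  R <- cor(N)
  off <- abs(R[upper.tri(R)])
  expect_lt(mean(off), 0.1)
})

test_that("truncation keeps the leading frames and is capped at T", {
  scan <- tiny_scans()[[3]]
  Tn <- dim(scan$data)[4]
  expect_identical(truncate_scan(scan, Tn)$data, scan$data)
  expect_identical(truncate_scan(scan, Tn + 50)$data, scan$data)
  tr <- truncate_scan(scan, 10)
  expect_identical(dim(tr$data)[4], 10L)
  expect_identical(tr$data[, , , 1], scan$data[, , , 1])
  # 150 frames at TR 2.2 s is 5 min 30 s of scan time
  expect_equal(150 * 2.2, 330)
})
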