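test_that("time-series connectivity matches brute-force ROI correlation", {
  atlas <- tiny_atlas()
  scan <- tiny_scans()[[1]]
  cm <- timeseries_connectivity(scan, atlas, level = "roi")
  expect_equal(diag(cm$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(unname(cm$matrix), tol = 1e-10))
  # brute force: correlate ROI-mean series directly, in network order
  ord <- order(vapply(atlas$rois, `[[`, integer(1), "network_index"))
  M <- vapply(atlas$rois[ord], function(r)
    rowMeans(rsnmap:::series_matrix(scan, r$voxels)),
    numeric(dim(scan$data)[4]))
  expect_equal(unname(cm$matrix), unname(cor(M)), tolerance = 1e-10)
  # zero-sum fluctuations put negative entries in the off-diagonal blocks
  off <- cm$matrix[cm$node_network[row(cm$matrix)] !=
                     cm$node_network[col(cm$matrix)]]
  expect_true(any(off < 0))
})

test_that("voxel-level connectivity orders nodes by network", {
  atlas <- tiny_atlas()
  scan <- tiny_scans()[[2]]
  cm <- timeseries_connectivity(scan, atlas, level = "voxel")
  expect_true(!is.unsorted(cm$node_network))
  expect_identical(nrow(cm$matrix),
                   sum(atlas$network_volume > 0))
  bm <- block_means(cm)
  expect_gt(bm$within, bm$between)
})

test_that("softmax connectivity separates planted networks", {
  atlas <- tiny_atlas()
  mask <- atlas$mask
  n <- sum(mask)
  net <- atlas$network_volume[which(mask)]
  # synthetic membership probabilities: sharp at planted ROIs, noisy elsewhere
  set.seed(8)
  P <- matrix(runif(n * 2, 0.2, 0.8), n, 2)
  P[net == 1, 1] <- runif(sum(net == 1), 2, 3)
  P[net == 2, 2] <- runif(sum(net == 2), 2, 3)
  P <- P / rowSums(P)
  pm <- pm_from_matrix(P, mask)
  cm <- softmax_connectivity(pm, atlas, level = "roi")
  expect_equal(diag(cm$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(unname(cm$matrix), tol = 1e-10))
  bm <- block_means(cm)
  expect_gt(bm$within, bm$between)
  cmv <- softmax_connectivity(pm, atlas, level = "voxel")
  expect_gt(block_means(cmv)$within, block_means(cmv)$between)
})

test_that("constant probability vectors are flagged as degenerate", {
  atlas <- tiny_atlas()
  P <- matrix(0.5, sum(atlas$mask), 2)
  pm <- pm_from_matrix(P, atlas$mask)
  expect_error(softmax_connectivity(pm, atlas, level = "roi"),
               class = "degenerate_node")
})
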