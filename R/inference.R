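#' Voxelwise RSN membership probability maps
#'
#' Every in-mask voxel acts as its own seed: its two-channel similarity map
#' against the whole scan is classified and the final-head softmax vector is
#' stored at that voxel. Voxels with zero-variance series receive the uniform
#' vector 1/K. Out-of-mask voxels are zero for every network.
#'
#' The per-voxel similarity maps are assembled from the in-mask voxel
#' correlation matrix (equivalent to calling [similarity_map()] with each
#' voxel's series, exploiting that for sample-z-scored series the distance
#' channel is `sqrt(2 (T-1) (1-r)) / sqrt(T)`), then classified in
#' minibatches.
#'
#' @param model a `trained_rsn_cnn`.
#' @param scan a `bold_scan`.
#' @param mask optional logical mask overriding `scan$mask`.
#' @param batch_size inference minibatch size.
#' @return a `probability_maps`: list with 4D `probs` (X,Y,Z,K), `mask`,
#'   `subject_id`, `networks` count K.
#' @export
voxelwise_probability_maps <- function(model, scan, mask = NULL,
                                       batch_size = 64L) {
  mask <- mask %||% scan$mask
  dims <- dim(scan$data)[1:3]
  Tn <- dim(scan$data)[4]
  K <- model$config$n_classes
  in_mask <- which(mask)
  n <- length(in_mask)
  nv <- prod(dims)

  S <- series_matrix(scan, in_mask)
  sm <- colMeans(S)
  ss <- sqrt(colSums(sweep(S, 2, sm)^2) / (Tn - 1))
  ok <- ss > 0
  Z <- sweep(S, 2, sm)
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, ss[ok], "/")
  Z[, !ok] <- 0
  R <- crossprod(Z) / (Tn - 1)                  # n x n voxel correlations
  R[, !ok] <- 0; R[!ok, ] <- 0
  R <- pmin(pmax(R, -1), 1)
  D <- sqrt(pmax(2 * (Tn - 1) * (1 - R), 0)) / sqrt(Tn)
  # distance convention for zero-variance partners: z-series vs zero vector
  if (any(!ok)) {
    d0 <- sqrt(Tn - 1) / sqrt(Tn)
    D[, !ok] <- d0; D[!ok, ] <- d0
    D[cbind(which(!ok), which(!ok))] <- 0
  }
  diag(D) <- 0

  seeds <- which(ok)
  mats <- lapply(seeds, function(v) {
    m <- matrix(0, nv, 2)
    m[in_mask, 1] <- R[, v]
    m[in_mask, 2] <- D[, v]
    m
  })
  P <- matrix(1 / K, n, K)
  if (length(seeds))
    P[seeds, ] <- predict_matrix_batch(model, mats, batch_size)

  probs <- array(0, dim = c(dims, K))
  offs <- (seq_len(K) - 1L) * nv
  for (k in seq_len(K)) probs[in_mask + offs[k]] <- P[, k]
  structure(list(probs = probs, mask = mask, subject_id = scan$subject_id,
                 n_networks = K),
            class = "probability_maps")
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("probability_maps %s: %s grid, %d networks, %d mask voxels\n",
              x$subject_id %||% "?", paste(dim(x$probs)[1:3], collapse = "x"),
              x$n_networks, sum(x$mask)))
  invisible(x)
}

#' Validate probability maps
#' @param pm a `probability_maps`.
#' @param tol tolerance on the per-voxel sum-to-one check.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_probability_maps <- function(pm, tol = 1e-4) {
  stopifnot(inherits(pm, "probability_maps"))
  dims <- dim(pm$probs)[1:3]
  nv <- prod(dims)
  K <- pm$n_networks
  in_mask <- which(pm$mask)
  M <- vapply(seq_len(K), function(k) pm$probs[in_mask + (k - 1L) * nv],
              numeric(length(in_mask)))
  if (any(M < -1e-12 | M > 1 + 1e-12)) stop("probability out of [0,1]")
  if (any(abs(rowSums(M) - 1) > tol)) stop("probabilities do not sum to 1")
  out <- which(!pm$mask)
  for (k in seq_len(K))
    if (any(pm$probs[out + (k - 1L) * nv] != 0)) stop("nonzero outside mask")
  invisible(TRUE)
}

# in-mask probability matrix (n_voxels x K)
prob_matrix <- function(pm) {
  nv <- prod(dim(pm$probs)[1:3])
  in_mask <- which(pm$mask)
  M <- vapply(seq_len(pm$n_networks),
              function(k) pm$probs[in_mask + (k - 1L) * nv],
              numeric(length(in_mask)))
  matrix(M, nrow = length(in_mask), ncol = pm$n_networks)
}

#' Winner-take-all segmentation
#'
#' Per voxel: label = argmax over networks of the membership probability
#' (plus 1-offset-free 1..K labeling) if the maximum reaches `threshold`,
#' else 0 (unassigned). Exact ties break to the lowest network index.
#'
#' @param pm a `probability_maps` or a `group_maps` (whose mean is used).
#' @param threshold probability threshold in [0, 1].
#' @return a `segmentation_volume`: list with integer `labels` array
#'   (0 = unassigned), `threshold`, `mask`.
#' @export
wta_segmentation <- function(pm, threshold = 0.2) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (inherits(pm, "group_maps"))
    pm <- structure(list(probs = pm$mean, mask = pm$mask,
                         n_networks = dim(pm$mean)[4]),
                    class = "probability_maps")
  M <- prob_matrix(pm)
  lab <- max.col(M, ties.method = "first")
  mx <- M[cbind(seq_len(nrow(M)), lab)]
  lab[mx < threshold] <- 0L
  labels <- array(0L, dim = dim(pm$probs)[1:3])
  labels[which(pm$mask)] <- lab
  structure(list(labels = labels, threshold = threshold, mask = pm$mask,
                 n_networks = pm$n_networks),
            class = "segmentation_volume")
}

#' Group-level probability statistics
#'
#' Voxelwise mean, sample standard deviation (n-1 denominator), and
#' mean/STD across subjects, per network. Where the STD is zero the
#' mean/STD ratio is defined as 0 (and counted in `n_zero_std`).
#'
#' @param pms list of `probability_maps` with identical shapes (>= 2).
#' @return a `group_maps`: list with 4D `mean`, `std`, `snr`, `mask`,
#'   `n_subjects`, `n_zero_std`.
#' @export
group_statistics <- function(pms) {
  if (length(pms) < 2) stop_rsn("single_subject", "need at least 2 subjects")
  d <- dim(pms[[1]]$probs)
  for (pm in pms)
    if (!identical(dim(pm$probs), d))
      stop_rsn("shape_error", "probability map shapes differ")
  n <- length(pms)
  mean_ <- array(0, dim = d)
  for (pm in pms) mean_ <- mean_ + pm$probs
  mean_ <- mean_ / n
  ss <- array(0, dim = d)
  for (pm in pms) ss <- ss + (pm$probs - mean_)^2
  std_ <- sqrt(ss / (n - 1))
  snr <- array(0, dim = d)
  nz <- std_ > 0
  snr[nz] <- mean_[nz] / std_[nz]
  structure(list(mean = mean_, std = std_, snr = snr, mask = pms[[1]]$mask,
                 n_subjects = n, n_zero_std = sum(!nz)),
            class = "group_maps")
}

#' Per-network summary measures over WTA regions
#'
#' For each network k: the mean of the group-mean probability over the
#' voxels `{seg == k}`, the mean of the mean/STD map over the same region,
#' and the area fraction `|{seg == k}| / |mask|`. Networks with empty WTA
#' regions get `NA` summaries (with a warning).
#'
#' @param gm a `group_maps`.
#' @param seg a `segmentation_volume` on the same grid.
#' @param mask logical mask (defaults to `gm$mask`).
#' @return data.frame with columns `network`, `mean_prob`, `mean_over_std`,
#'   `area_fraction`, `n_voxels`.
#' @export
network_summary <- function(gm, seg, mask = gm$mask) {
  K <- dim(gm$mean)[4]
  nv <- prod(dim(gm$mean)[1:3])
  n_mask <- sum(mask)
  res <- data.frame(network = seq_len(K), mean_prob = NA_real_,
                    mean_over_std = NA_real_, area_fraction = 0,
                    n_voxels = 0L)
  for (k in seq_len(K)) {
    reg <- which(seg$labels == k & mask)
    res$n_voxels[k] <- length(reg)
    res$area_fraction[k] <- length(reg) / n_mask
    if (length(reg)) {
      res$mean_prob[k] <- mean(gm$mean[reg + (k - 1L) * nv])
      res$mean_over_std[k] <- mean(gm$snr[reg + (k - 1L) * nv])
    } else {
      warning(sprintf("network %d has an empty WTA region; summary undefined", k))
    }
  }
  res
}

#' Suprathreshold voxel counts per network
#'
#' Number of in-mask voxels whose membership probability reaches each
#' threshold, per network; non-increasing in the threshold.
#'
#' @param pm a `probability_maps` or `group_maps` (mean used).
#' @param thresholds numeric vector in [0, 1].
#' @return data.frame with columns `network`, `threshold`, `count`.
#' @export
suprathreshold_counts <- function(pm, thresholds = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  if (inherits(pm, "group_maps"))
    pm <- structure(list(probs = pm$mean, mask = pm$mask,
                         n_networks = dim(pm$mean)[4]),
                    class = "probability_maps")
  M <- prob_matrix(pm)
  K <- ncol(M)
  out <- expand.grid(network = seq_len(K), threshold = thresholds)
  out$count <- mapply(function(k, t) sum(M[, k] >= t), out$network, out$threshold)
  out[order(out$network, out$threshold), , drop = FALSE]
}

#' Dice overlap between a segmentation and planted atlas labels
#'
#' Per network: `2 |A_k ∩ B_k| / (|A_k| + |B_k|)` where `B_k` is the
#' atlas's planted ROI voxel set of network k and `A_k` the segmentation's
#' network-k region. With `within = "labeled"` (default) the segmentation
#' is restricted to the atlas-labeled voxels before scoring: recovery of
#' planted labels is only defined where a planted label exists, and
#' background (unlabeled) voxels have no ground truth to recover. With
#' `within = "mask"` the full in-mask WTA region is scored, so confidently
#' segmented background voxels count against the overlap.
#'
#' @param seg a `segmentation_volume`.
#' @param atlas a `phantom_atlas`.
#' @param within scoring universe, `"labeled"` or `"mask"`.
#' @return named numeric vector of per-network Dice coefficients.
#' @export
dice_vs_atlas <- function(seg, atlas, within = c("labeled", "mask")) {
  within <- match.arg(within)
  K <- length(atlas$networks)
  universe <- if (within == "labeled") atlas$network_volume > 0 else atlas$mask
  vapply(seq_len(K), function(k) {
    a <- seg$labels == k & universe
    b <- atlas$network_volume == k
    denom <- sum(a) + sum(b)
    if (denom == 0) return(NA_real_)
    2 * sum(a & b) / denom
  }, numeric(1)) |> stats::setNames(atlas$networks)
}
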