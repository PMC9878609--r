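#' Subsample ROIs of one network
#'
#' Draws `n_rois` distinct ROIs belonging to the given network, uniformly
#' without replacement; deterministic given `rng_seed`.
#'
#' @param atlas a `phantom_atlas`.
#' @param network_index network (1..K).
#' @param n_rois number of ROIs to draw.
#' @param rng_seed integer seed.
#' @return list of ROI entries (subset of `atlas$rois`).
#' @export
subsample_network_rois <- function(atlas, network_index, n_rois, rng_seed = 1L) {
  idx <- which(vapply(atlas$rois, `[[`, integer(1), "network_index") == network_index)
  if (n_rois < 1 || n_rois > length(idx))
    stop_rsn("roi_subsample_error", "requested %d ROIs but network %d has %d",
             n_rois, network_index, length(idx))
  pick <- with_seed(rng_seed, sort(idx[sample.int(length(idx), n_rois)]))
  atlas$rois[pick]
}

#' Mean seed signal over a voxel set
#'
#' Framewise arithmetic mean of the BOLD series of the given voxels.
#'
#' @param scan a `bold_scan`.
#' @param voxels linear voxel indices (non-empty, inside the scan mask).
#' @return numeric vector of length T.
#' @export
mean_seed_signal <- function(scan, voxels) {
  if (length(voxels) == 0) stop_rsn("empty_voxel_set", "empty voxel set")
  if (!all(scan$mask[voxels])) stop_rsn("out_of_mask", "seed voxel outside mask")
  rowMeans(series_matrix(scan, voxels))
}

# z-score with the sample (n-1) standard deviation; zero-variance series
# return all zeros (flagged via attribute).
zscore <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(structure(rep(0, length(x)), zero_var = TRUE))
  (x - m) / s
}

#' Two-channel seed similarity map
#'
#' For every in-mask voxel, channel 1 holds the Pearson correlation between
#' the voxel's series and the seed series; channel 2 holds the Euclidean
#' distance between the z-scored voxel and z-scored seed series divided by
#' sqrt(T) (so its scale does not depend on scan length). Both channels are
#' exactly zero outside the mask. Zero-variance voxel series yield r = 0 and
#' a distance computed against the zero vector.
#'
#' @param scan a `bold_scan`.
#' @param seed_series numeric vector of length T with nonzero variance.
#' @return `similarity_channels`: 4D array (X, Y, Z, 2).
#' @export
similarity_map <- function(scan, seed_series) {
  Tn <- dim(scan$data)[4]
  if (length(seed_series) != Tn) stop("seed_series length must equal T")
  if (stats::sd(seed_series) == 0)
    stop_rsn("degenerate_seed", "seed series has zero variance")
  in_mask <- which(scan$mask)
  S <- series_matrix(scan, in_mask)                     # T x n
  sm <- colMeans(S); ss <- sqrt(colSums(sweep(S, 2, sm)^2) / (Tn - 1))
  zs <- zscore(seed_series)
  Z <- sweep(S, 2, sm)
  ok <- ss > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, ss[ok], "/")
  Z[, !ok] <- 0
  r <- as.vector(crossprod(Z, zs)) / (Tn - 1)
  r[!ok] <- 0
  dist <- sqrt(pmax(colSums((Z - zs)^2), 0)) / sqrt(Tn)

  dims <- dim(scan$data)[1:3]
  ch <- array(0, dim = c(dims, 2L))
  nv <- prod(dims)
  ch[in_mask] <- pmin(pmax(r, -1), 1)
  ch[in_mask + nv] <- dist
  structure(ch, class = c("similarity_channels", class(ch)))
}

#' Confirm the network label of a seed
#'
#' Correlates the seed series with each network's mean signal (average over
#' all of that network's ROI voxels) and returns the argmax network index.
#' An exact tie between the top networks is an error: the label cannot be
#' confirmed.
#'
#' @param scan a `bold_scan`.
#' @param seed_series numeric length-T vector, nonconstant.
#' @param atlas a `phantom_atlas`.
#' @return integer network index in 1..K.
#' @export
confirm_label <- function(scan, seed_series, atlas) {
  if (stats::sd(seed_series) == 0) stop_rsn("degenerate_seed", "constant seed series")
  K <- length(atlas$networks)
  ni <- vapply(atlas$rois, `[[`, integer(1), "network_index")
  rs <- vapply(seq_len(K), function(k) {
    vox <- unlist(lapply(atlas$rois[ni == k], `[[`, "voxels"))
    stats::cor(seed_series, rowMeans(series_matrix(scan, vox)))
  }, numeric(1))
  top <- max(rs)
  if (sum(rs == top) > 1L)
    stop_rsn("label_tie", "two networks share the maximal correlation (%.6f)", top)
  which.max(rs)
}

#' Augmentation parameters
#'
#' Bounds for random 3D affine augmentation of similarity samples: rotation,
#' translation and shear drawn uniformly within +/- the bound, multiplicative
#' intensity scaling, and additive Gaussian noise.
#'
#' @param rot_deg max absolute rotation per axis (degrees).
#' @param trans_vox max absolute translation per axis (voxels).
#' @param shear_deg max absolute shear (degrees).
#' @param intensity_range multiplicative interval containing 1.
#' @param gauss_sd additive Gaussian noise SD.
#' @return an `augment_params` list.
#' @export
augment_params <- function(rot_deg = 5, trans_vox = 3, shear_deg = 3,
                           intensity_range = c(0.9, 1.1), gauss_sd = 0.01) {
  stopifnot(rot_deg >= 0, trans_vox >= 0, shear_deg >= 0, gauss_sd >= 0,
            length(intensity_range) == 2,
            intensity_range[1] <= 1, intensity_range[2] >= 1)
  structure(list(rot_deg = rot_deg, trans_vox = trans_vox,
                 shear_deg = shear_deg, intensity_range = intensity_range,
                 gauss_sd = gauss_sd), class = "augment_params")
}

# Draw one affine augmentation (rotations, shears, translation, intensity,
# noise SD) uniformly within the parameter bounds. Exposed internally so the
# sampler itself can be property-tested.
draw_augmentation <- function(params) {
  list(rot = stats::runif(3, -params$rot_deg, params$rot_deg),
       shear = stats::runif(3, -params$shear_deg, params$shear_deg),
       trans = stats::runif(3, -params$trans_vox, params$trans_vox),
       scale = stats::runif(1, params$intensity_range[1], params$intensity_range[2]))
}

# rotation (deg) about each axis composed Rz %*% Ry %*% Rx, plus shear terms
affine_matrix <- function(rot, shear) {
  r <- rot * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  s <- tan(shear * pi / 180)
  Sh <- rbind(c(1, s[1], s[2]), c(0, 1, s[3]), c(0, 0, 1))
  Rz %*% Ry %*% Rx %*% Sh
}

# centered voxel coordinate grids, cached per volume shape
.grid_cache <- new.env(parent = emptyenv())

centered_grid <- function(dims) {
  key <- paste(dims, collapse = "x")
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    ctr <- (dims + 1) / 2
    gg <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                      k = seq_len(dims[3]))
    g <- t(cbind(gg$i - ctr[1], gg$j - ctr[2], gg$k - ctr[3]))
    .grid_cache[[key]] <- g
  }
  g
}

# Trilinear resampling of a 3D volume under an affine map about the volume
# center; out-of-volume samples are filled with 0.
affine_resample <- function(vol, A, trans) {
  dims <- dim(vol)
  ctr <- (dims + 1) / 2
  tgt <- centered_grid(dims)
  src <- solve(A, tgt - trans) + ctr          # inverse map, then re-center
  x <- src[1, ]; y <- src[2, ]; z <- src[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(length(x))
  vol_at <- function(i, j, k) {
    ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] & k >= 1 & k <= dims[3]
    v <- numeric(length(i))
    v[ok] <- vol[cbind(i[ok], j[ok], k[ok])]
    v
  }
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz))
      val[nz] <- val[nz] + w[nz] * vol_at(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
  }
  array(val, dim = dims)
}

#' Augment a similarity sample
#'
#' Applies one random 3D affine transformation (rotation, translation, shear
#' within the parameter bounds), multiplicative intensity scaling, and
#' additive Gaussian noise to both channels. Interpolation is trilinear with
#' zero fill outside the volume. The label and subject are preserved; the
#' correlation channel is re-clipped to [-1, 1]. Deterministic given
#' `rng_seed`.
#'
#' @param sample a `similarity_sample` (see [build_training_set()]).
#' @param params an [augment_params()].
#' @param rng_seed integer seed.
#' @return augmented `similarity_sample`.
#' @export
augment_sample <- function(sample, params, rng_seed = 1L) {
  with_seed(rng_seed, augment_sample_(sample, params))
}

# RNG-stateful core, used on-the-fly during training
augment_sample_ <- function(sample, params) {
  draw <- draw_augmentation(params)
  A <- affine_matrix(draw$rot, draw$shear)
  ch <- sample$channels
  identity_affine <- all(draw$rot == 0) && all(draw$shear == 0) &&
    all(draw$trans == 0)
  for (c_i in 1:2) {
    v <- ch[, , , c_i]
    if (!identity_affine) v <- affine_resample(v, A, draw$trans)
    v <- v * draw$scale
    if (params$gauss_sd > 0)
      v <- v + stats::rnorm(length(v), 0, params$gauss_sd)
    ch[, , , c_i] <- v
  }
  ch[, , , 1] <- pmin(pmax(ch[, , , 1], -1), 1)
  ch[, , , 2] <- pmax(ch[, , , 2], 0)
  sample$channels <- ch
  sample
}

new_similarity_sample <- function(channels, label, subject_id) {
  structure(list(channels = channels, label = as.integer(label),
                 subject_id = subject_id), class = "similarity_sample")
}

#' Validate a similarity sample
#' @param sample a `similarity_sample`.
#' @param mask optional logical mask; when given, both channels must be zero
#'   outside it.
#' @param n_networks optional K for label range checking.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_sample <- function(sample, mask = NULL, n_networks = NULL) {
  stopifnot(inherits(sample, "similarity_sample"))
  ch <- sample$channels
  if (length(dim(ch)) != 4 || dim(ch)[4] != 2) stop("channels must be X,Y,Z,2")
  if (!is.null(mask)) {
    out <- which(!mask)
    nv <- prod(dim(mask))
    if (any(ch[out] != 0) || any(ch[out + nv] != 0)) stop("nonzero outside mask")
    r_in <- ch[which(mask)]
    if (any(r_in < -1 - 1e-12 | r_in > 1 + 1e-12)) stop("r channel out of [-1,1]")
  }
  if (any(ch[, , , 2] < 0)) stop("distance channel negative")
  if (!is.null(n_networks) && (sample$label < 1 || sample$label > n_networks))
    stop("label out of range")
  invisible(TRUE)
}

#' Per-class loss weights for balanced training
#'
#' `weights[c] = N / (K * counts[c])`, so that `weights[c] * counts[c]` is
#' the same for every class and each class contributes equally to the loss.
#'
#' @param class_counts positive integer vector of per-class sample counts.
#' @return numeric weight vector.
#' @export
compute_class_weights <- function(class_counts) {
  if (any(class_counts <= 0)) stop_rsn("zero_class_count", "all class counts must be > 0")
  n <- sum(class_counts)
  k <- length(class_counts)
  n / (k * class_counts)
}

#' Build a labeled training set of similarity samples
#'
#' For each network, repeatedly: pick a subject, subsample that network's
#' ROIs (count uniform in `n_rois_range`), draw a random voxel subset within
#' those ROIs (size uniform from one voxel up to the full set), average the
#' BOLD signal over the drawn voxels, compute the two-channel similarity
#' map, and keep the sample only if
#' [confirm_label()] agrees with the sampled network (discard-and-redraw with
#' a bounded retry budget). Whole subjects are assigned to the validation
#' split; training samples are drawn only from training subjects and
#' validation samples only from validation subjects, so the splits share no
#' subject. Augmentation parameters are stored with the set and applied
#' on-the-fly to training samples during [train_model()].
#'
#' @param scans list of `bold_scan` (>= 2 subjects).
#' @param atlas a `phantom_atlas`.
#' @param samples_per_network confirmed-label samples per network.
#' @param n_rois_range integer range (lo, hi) of ROIs to subsample.
#' @param val_subject_fraction fraction of subjects held out for validation.
#' @param aug an [augment_params()] (stored; applied during training).
#' @param rng_seed integer seed.
#' @param max_redraw_factor retry budget as a multiple of the sample count.
#' @return a `training_set`: list with `samples`, `split` ("train"/"val"),
#'   `class_counts`, `class_weights`, `mask`, `n_networks`, `aug`,
#'   `val_subjects`, `discard_rate`.
#' @export
build_training_set <- function(scans, atlas, samples_per_network = 150L,
                               n_rois_range = c(1L, 3L),
                               val_subject_fraction = 0.25,
                               aug = augment_params(), rng_seed = 1L,
                               max_redraw_factor = 20L) {
  stopifnot(length(scans) >= 2)
  K <- length(atlas$networks)
  subj <- vapply(scans, `[[`, character(1), "subject_id")
  stopifnot(!anyDuplicated(subj))
  ni <- vapply(atlas$rois, `[[`, integer(1), "network_index")

  with_seed(rng_seed, {
    n_val <- max(1L, round(val_subject_fraction * length(scans)))
    if (n_val >= length(scans)) stop("val_subject_fraction leaves no training subjects")
    val_idx <- sort(sample(length(scans), n_val))
    samples <- list(); split <- character(0)
    n_discard <- 0L; n_drawn <- 0L
    budget <- max_redraw_factor * samples_per_network * K

    draw_one <- function(k, subject_pool) {
      scan <- scans[[subject_pool[sample.int(length(subject_pool), 1L)]]]
      roi_ids <- which(ni == k)
      n_avail <- length(roi_ids)
      lo <- min(n_rois_range[1], n_avail); hi <- min(n_rois_range[2], n_avail)
      n_r <- if (hi > lo) sample(lo:hi, 1L) else lo
      rois <- atlas$rois[roi_ids[sample.int(n_avail, n_r)]]
      vox_pool <- unlist(lapply(rois, `[[`, "voxels"))
      # seeds average a random voxel subset of the chosen ROIs; sizes are
      # log-uniform from a single voxel to the full set so inference-time
      # voxel seeding stays in-distribution
      n_vox <- max(1L, min(length(vox_pool),
                           round(length(vox_pool)^stats::runif(1))))
      vox <- vox_pool[sample.int(length(vox_pool), n_vox)]
      seed_series <- mean_seed_signal(scan, vox)
      lab <- tryCatch(confirm_label(scan, seed_series, atlas),
                      rsnmap_error = function(e) NA_integer_)
      if (is.na(lab) || lab != k) return(NULL)
      new_similarity_sample(similarity_map(scan, seed_series), k, scan$subject_id)
    }

    for (k in seq_len(K)) {
      n_val_k <- max(1L, round(samples_per_network * val_subject_fraction))
      n_train_k <- samples_per_network - n_val_k
      for (part in c("train", "val")) {
        pool <- if (part == "train") setdiff(seq_along(scans), val_idx) else val_idx
        need <- if (part == "train") n_train_k else n_val_k
        got <- 0L
        while (got < need) {
          n_drawn <- n_drawn + 1L
          if (n_drawn > budget)
            stop_rsn("redraw_exhausted",
                     "label-confirmation redraw budget exhausted (phantom may be unlearnable)")
          s <- draw_one(k, pool)
          if (is.null(s)) { n_discard <- n_discard + 1L; next }
          samples[[length(samples) + 1L]] <- s
          split <- c(split, part)
          got <- got + 1L
        }
      }
    }
  })

  labels <- vapply(samples, `[[`, integer(1), "label")
  counts <- tabulate(labels, nbins = K)
  structure(list(samples = samples, split = split, class_counts = counts,
                 class_weights = compute_class_weights(counts),
                 mask = atlas$mask, n_networks = K, aug = aug,
                 val_subjects = subj[val_idx],
                 discard_rate = n_discard / n_drawn),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d samples (%d train / %d val), %d networks, discard rate %.1f%%\n",
              length(x$samples), sum(x$split == "train"), sum(x$split == "val"),
              x$n_networks, 100 * x$discard_rate))
  invisible(x)
}

#' Save / load a training set bundle
#'
#' Persists samples as a directory bundle: one 4D NIfTI per sample
#' (two-channel volume) plus a TSV manifest (`sample`, `label`, `subject_id`,
#' `split`) and a JSON sidecar with class counts/weights.
#'
#' @param tset a `training_set`.
#' @param path directory to create.
#' @return `path`, invisibly (`save_training_set`); a `training_set`
#'   (`load_training_set`).
#' @export
save_training_set <- function(tset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    sample = sprintf("sample-%05d.nii.gz", seq_along(tset$samples)),
    label = vapply(tset$samples, `[[`, integer(1), "label"),
    subject_id = vapply(tset$samples, `[[`, character(1), "subject_id"),
    split = tset$split)
  utils::write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (i in seq_along(tset$samples))
    RNifti::writeNifti(tset$samples[[i]]$channels, file.path(path, manifest$sample[i]))
  RNifti::writeNifti(array(as.integer(tset$mask), dim = dim(tset$mask)),
                     file.path(path, "mask.nii.gz"))
  jsonlite::write_json(list(n_networks = tset$n_networks,
                            class_counts = tset$class_counts,
                            class_weights = tset$class_weights,
                            val_subjects = tset$val_subjects,
                            discard_rate = tset$discard_rate,
                            aug = unclass(tset$aug)),
                       file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_training_set
#' @param path directory written by `save_training_set`.
#' @export
load_training_set <- function(path) {
  manifest <- utils::read.delim(file.path(path, "manifest.tsv"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  mask_vol <- read_nifti(file.path(path, "mask.nii.gz"))$data
  mask <- array(mask_vol > 0, dim = dim(mask_vol))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    ch <- read_nifti(file.path(path, manifest$sample[i]))$data
    new_similarity_sample(ch, manifest$label[i], manifest$subject_id[i])
  })
  aug <- do.call(augment_params, meta$aug)
  structure(list(samples = samples, split = manifest$split,
                 class_counts = meta$class_counts,
                 class_weights = meta$class_weights, mask = mask,
                 n_networks = meta$n_networks, aug = aug,
                 val_subjects = meta$val_subjects,
                 discard_rate = meta$discard_rate),
            class = "training_set")
}
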