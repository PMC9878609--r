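#' Construct a phantom network atlas
#'
#' Builds a synthetic gray-matter analog: a spherical mask on a regular grid
#' containing disjoint spherical ROIs, each assigned to one of `n_networks`
#' resting-state networks. The phantom stands in for a volumetric ROI atlas
#' (ROI label volume plus ROI-to-network table); a real atlas can be supplied
#' through the same NIfTI + TSV interface (see [write_atlas()]).
#'
#' ROI centers are drawn on a jittered lattice restricted to positions where
#' the full sphere fits inside the mask, then accepted only if the sphere is
#' voxel-disjoint from all previously placed ROIs. Placement is deterministic
#' given `rng_seed`.
#'
#' @param grid_shape integer(3), voxel grid dimensions.
#' @param n_networks number of networks K (default 13).
#' @param rois_per_network ROIs assigned to each network.
#' @param roi_radius sphere radius in voxels.
#' @param rng_seed integer seed controlling placement.
#' @param networks optional character vector of K network names.
#' @param max_attempts rejection-sampling budget per ROI before failing.
#' @return A `phantom_atlas`: list with `grid_shape`, logical `mask`,
#'   `networks`, `rois` (list of `roi_id`, `network_index`, `voxels` linear
#'   indices), integer `roi_volume` and `network_volume` label arrays.
#' @export
make_phantom_atlas <- function(grid_shape, n_networks = 13L, rois_per_network = 3L,
                               roi_radius = 2L, rng_seed = 1L,
                               networks = NULL, max_attempts = 500L) {
  grid_shape <- as.integer(grid_shape)
  n_networks <- as.integer(n_networks)
  rois_per_network <- as.integer(rois_per_network)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 3),
            n_networks >= 1, rois_per_network >= 1, roi_radius >= 1)
  networks <- networks %||% default_network_names(n_networks)
  stopifnot(length(networks) == n_networks)

  ctr <- (grid_shape + 1) / 2
  mask_r <- min(grid_shape) / 2 - 0.5
  cc <- expand.grid(i = seq_len(grid_shape[1]), j = seq_len(grid_shape[2]),
                    k = seq_len(grid_shape[3]))
  d2 <- (cc$i - ctr[1])^2 + (cc$j - ctr[2])^2 + (cc$k - ctr[3])^2
  mask <- array(d2 <= mask_r^2, dim = grid_shape)

  # sphere offsets around a center
  off <- as.matrix(expand.grid(-roi_radius:roi_radius, -roi_radius:roi_radius,
                               -roi_radius:roi_radius))
  off <- off[rowSums(off^2) <= roi_radius^2, , drop = FALSE]

  # candidate centers: sphere entirely within mask
  inside <- d2 <= (mask_r - roi_radius)^2
  cand <- which(inside)
  n_rois <- n_networks * rois_per_network
  if (length(cand) < n_rois)
    stop_rsn("placement_failure",
             "grid %s cannot host %d ROIs of radius %d inside the mask",
             paste(grid_shape, collapse = "x"), n_rois, roi_radius)

  occupied <- array(FALSE, dim = grid_shape)
  rois <- vector("list", n_rois)
  with_seed(rng_seed, {
    for (r in seq_len(n_rois)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        center <- cand[sample.int(length(cand), 1L)]
        cxyz <- vox_coords(center, grid_shape)
        vox_xyz <- sweep(off, 2, as.numeric(cxyz), "+")
        vidx <- vox_index(vox_xyz, grid_shape)
        if (!any(occupied[vidx])) {
          occupied[vidx] <- TRUE
          rois[[r]] <- list(roi_id = r,
                            network_index = ((r - 1L) %% n_networks) + 1L,
                            voxels = sort(vidx))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_rsn("placement_failure",
                 "could not place ROI %d of %d (radius %d) after %d attempts",
                 r, n_rois, roi_radius, max_attempts)
    }
  })

  roi_volume <- array(0L, dim = grid_shape)
  network_volume <- array(0L, dim = grid_shape)
  for (roi in rois) {
    roi_volume[roi$voxels] <- roi$roi_id
    network_volume[roi$voxels] <- roi$network_index
  }
  structure(list(grid_shape = grid_shape, mask = mask, networks = networks,
                 rois = rois, roi_volume = roi_volume,
                 network_volume = network_volume, roi_radius = roi_radius),
            class = "phantom_atlas")
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf("phantom_atlas: %s grid, %d mask voxels, %d networks, %d ROIs\n",
              paste(x$grid_shape, collapse = "x"), sum(x$mask),
              length(x$networks), length(x$rois)))
  invisible(x)
}

#' Validate a phantom atlas
#'
#' Checks ROI disjointness, mask containment, network coverage, and index
#' ranges. Used by tests and by pipeline entry points.
#' @param atlas a `phantom_atlas`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  all_vox <- unlist(lapply(atlas$rois, `[[`, "voxels"))
  if (anyDuplicated(all_vox)) stop("ROI voxel sets overlap")
  if (!all(atlas$mask[all_vox])) stop("ROI voxel outside mask")
  ni <- vapply(atlas$rois, `[[`, integer(1), "network_index")
  if (!all(ni %in% seq_along(atlas$networks))) stop("network_index out of range")
  if (!setequal(unique(ni), seq_along(atlas$networks)))
    stop("some network owns no ROI")
  invisible(TRUE)
}

#' Simulation settings for phantom BOLD scans
#'
#' Collects the generative parameters of the phantom cohort: the amplitude of
#' the shared per-network latent signal, latent cross-network correlations,
#' voxelwise 1/f noise, the low-pass band of the emulated preprocessing, and
#' per-subject amplitude variability.
#'
#' @param within_network_weight amplitude of the shared network latent
#'   (unitless; signal-to-noise is `within_network_weight / noise_sd`).
#' @param cross_network_corr K x K symmetric positive-semidefinite matrix of
#'   latent correlations with unit diagonal, or `NULL` for identity.
#' @param noise_sd standard deviation of additive per-voxel pink noise.
#' @param lowpass_hz hard spectral cutoff applied to latents (Hz), emulating
#'   low-pass filtered preprocessed BOLD.
#' @param subject_jitter relative SD of the per-subject amplitude multiplier.
#' @param pink_exponent spectral exponent of the voxel noise (1 = pink).
#' @param background_weight relative amplitude of latent mixtures assigned to
#'   in-mask non-ROI voxels (background gray matter is never signal-free).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(within_network_weight = 1, cross_network_corr = NULL,
                            noise_sd = 1, lowpass_hz = 0.1, subject_jitter = 0.1,
                            pink_exponent = 1, background_weight = 0.3) {
  stopifnot(noise_sd >= 0, lowpass_hz > 0, subject_jitter >= 0,
            within_network_weight >= 0, background_weight >= 0)
  if (!is.null(cross_network_corr)) {
    C <- cross_network_corr
    if (!isSymmetric(unname(C), tol = 1e-8)) stop_rsn("invalid_spec", "cross_network_corr must be symmetric")
    if (any(abs(diag(C) - 1) > 1e-8)) stop_rsn("invalid_spec", "cross_network_corr diagonal must be 1")
    if (any(C < -1 - 1e-12 | C > 1 + 1e-12)) stop_rsn("invalid_spec", "correlations must lie in [-1, 1]")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop_rsn("invalid_spec", "cross_network_corr must be positive semidefinite")
  }
  structure(list(within_network_weight = within_network_weight,
                 cross_network_corr = cross_network_corr,
                 noise_sd = noise_sd, lowpass_hz = lowpass_hz,
                 subject_jitter = subject_jitter,
                 pink_exponent = pink_exponent,
                 background_weight = background_weight),
            class = "simulation_spec")
}

# Spectrally shaped 1/f^alpha noise, one column per series, standardized to
# zero mean / unit SD. Uses the current RNG state.
pink_noise_matrix <- function(n_frames, n_series, exponent = 1) {
  w <- matrix(stats::rnorm(n_frames * n_series), n_frames, n_series)
  f <- pmin(seq_len(n_frames) - 1L, n_frames - (seq_len(n_frames) - 1L)) / n_frames
  amp <- c(0, f[-1]^(-exponent / 2))
  sp <- stats::mvfft(w) * amp
  x <- Re(stats::mvfft(sp, inverse = TRUE)) / n_frames
  x <- sweep(x, 2, colMeans(x), "-")
  sdv <- sqrt(colMeans(x^2))
  sdv[sdv == 0] <- 1
  sweep(x, 2, sdv, "/")
}

#' Generate a pink-noise time series
#'
#' Zero-mean series whose expected power spectrum is proportional to
#' 1/frequency, generated by spectral shaping of white Gaussian noise
#' (spectrum multiplied by f^(-1/2), inverse transformed, standardized).
#'
#' @param n_frames series length (>= 2).
#' @param rng_seed integer seed.
#' @param exponent spectral exponent (default 1).
#' @return numeric vector of length `n_frames`.
#' @export
pink_noise_series <- function(n_frames, rng_seed, exponent = 1) {
  stopifnot(n_frames >= 2)
  with_seed(rng_seed, pink_noise_matrix(n_frames, 1L, exponent)[, 1])
}

# Hard low-pass in the frequency domain: zero all bins at/above cutoff_hz.
lowpass_filter <- function(x, tr, cutoff_hz) {
  n <- nrow(x)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) / (n * tr)
  keep <- as.numeric(f < cutoff_hz)
  if (sum(keep) <= 1) stop("low-pass cutoff removes the whole band; increase n_frames or tr")
  sp <- stats::mvfft(x) * keep
  Re(stats::mvfft(sp, inverse = TRUE)) / n
}

#' Simulate one phantom BOLD scan
#'
#' Produces a preprocessed-equivalent 4D BOLD volume with planted network
#' structure. Each network has one latent series (correlated across networks
#' per `spec$cross_network_corr`, low-pass filtered below `spec$lowpass_hz`,
#' standardized). ROI voxels receive `within_network_weight` times their
#' network latent plus pink noise; in-mask non-ROI voxels receive weak random
#' mixtures of the latents (at `background_weight` relative amplitude) plus
#' pink noise. Every voxel series is mean-centered; out-of-mask voxels are
#' exactly zero.
#'
#' @param atlas a [make_phantom_atlas()] result.
#' @param spec a [simulation_spec()].
#' @param n_frames number of time points (>= 2).
#' @param tr repetition time in seconds.
#' @param subject_id character identifier.
#' @param rng_seed integer seed.
#' @return A `bold_scan`: list with 4D `data` (X,Y,Z,T), `tr`, `mask`,
#'   `subject_id`.
#' @export
simulate_scan <- function(atlas, spec, n_frames, tr = 2.2, subject_id = "sub-01",
                          rng_seed = 1L) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(spec, "simulation_spec"),
            n_frames >= 2, tr > 0)
  K <- length(atlas$networks)
  C <- spec$cross_network_corr %||% diag(K)
  stopifnot(nrow(C) == K)

  dims <- atlas$grid_shape
  nvox <- prod(dims)
  in_mask <- which(atlas$mask)
  net_of <- atlas$network_volume[in_mask]          # 0 = background

  with_seed(rng_seed, {
    # correlated latents, low-passed, re-standardized (scaling preserves corr)
    ch <- chol(C + diag(1e-10, K))
    L <- matrix(stats::rnorm(n_frames * K), n_frames, K) %*% ch
    L <- lowpass_filter(L, tr, spec$lowpass_hz)
    L <- sweep(L, 2, colMeans(L), "-")
    sdv <- sqrt(colMeans(L^2)); sdv[sdv == 0] <- 1
    L <- sweep(L, 2, sdv, "/")

    amp <- spec$within_network_weight *
      max(0, 1 + spec$subject_jitter * stats::rnorm(1))

    sig <- matrix(0, n_frames, length(in_mask))
    roi_cols <- which(net_of > 0)
    if (length(roi_cols)) sig[, roi_cols] <- amp * L[, net_of[roi_cols]]
    bg_cols <- which(net_of == 0)
    if (length(bg_cols)) {
      W <- matrix(stats::runif(K * length(bg_cols)), K, length(bg_cols))
      W <- sweep(W, 2, colSums(W), "/")
      sig[, bg_cols] <- spec$background_weight * amp * (L %*% W)
    }
    if (spec$noise_sd > 0)
      sig <- sig + spec$noise_sd *
        pink_noise_matrix(n_frames, length(in_mask), spec$pink_exponent)
    sig <- sweep(sig, 2, colMeans(sig), "-")
  })

  data <- array(0, dim = c(dims, n_frames))
  frame_offsets <- (seq_len(n_frames) - 1L) * nvox
  for (t in seq_len(n_frames)) data[in_mask + frame_offsets[t]] <- sig[t, ]

  structure(list(data = data, tr = tr, mask = atlas$mask,
                 subject_id = subject_id),
            class = "bold_scan")
}

#' @export
print.bold_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_scan %s: %s grid, %d frames, TR %.2fs, %d mask voxels\n",
              x$subject_id, paste(d[1:3], collapse = "x"), d[4], x$tr,
              sum(x$mask)))
  invisible(x)
}

#' Validate a BOLD scan container
#' @param scan a `bold_scan`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_scan <- function(scan) {
  stopifnot(inherits(scan, "bold_scan"))
  d <- dim(scan$data)
  if (length(d) != 4 || d[4] < 2) stop("data must be 4D with T >= 2")
  if (!identical(d[1:3], dim(scan$mask))) stop("mask shape mismatch")
  if (!all(is.finite(scan$data))) stop("non-finite data")
  out <- which(!scan$mask)
  if (length(out)) {
    nvox <- prod(d[1:3])
    for (t in seq_len(d[4]))
      if (any(scan$data[out + (t - 1) * nvox] != 0))
        stop("nonzero data outside mask")
  }
  invisible(TRUE)
}

#' Simulate a phantom cohort
#'
#' One scan per subject with independent noise draws and per-subject
#' amplitude jitter. A single master seed expands into named per-subject
#' substreams, so subject `i`'s scan is unchanged when `n_subjects` changes.
#'
#' @inheritParams simulate_scan
#' @param n_subjects number of subjects (>= 1).
#' @return list of `bold_scan` with unique `subject_id`s.
#' @export
simulate_cohort <- function(atlas, spec, n_subjects, n_frames, tr = 2.2,
                            rng_seed = 1L) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    simulate_scan(atlas, spec, n_frames, tr,
                  subject_id = sprintf("sub-%02d", i),
                  rng_seed = substream_seed(rng_seed, paste0("subject", i)))
  })
}

# time series matrix (T x n) for the given linear voxel indices
series_matrix <- function(scan, voxels) {
  d <- dim(scan$data)
  nvox <- prod(d[1:3])
  m <- matrix(scan$data, nvox, d[4])
  t(m[voxels, , drop = FALSE])
}
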