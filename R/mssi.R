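#' Multiscale structural similarity settings
#'
#' Downsampling factors with Gaussian scale weights peaked at the middle
#' factor, the Gaussian local-statistics window, and the two stability
#' constants of the standard SSIM construction.
#'
#' @param scale_factors strictly increasing downsampling factors; factor 1
#'   means no downsampling (single-scale SSIM).
#' @param scale_weights optional nonnegative weights summing to 1; default is
#'   a Gaussian over the factor index centered at the middle factor with
#'   SD = 1 index, normalized.
#' @param window_size local window width in voxels (clipped to the volume).
#' @param window_sd Gaussian window SD in voxels.
#' @param k1,k2 stability constants relative to the dynamic range
#'   (`c1 = (k1 L)^2`, `c2 = (k2 L)^2`).
#' @return an `mssi_spec`.
#' @export
mssi_spec <- function(scale_factors = c(2, 4, 8, 16, 32), scale_weights = NULL,
                      window_size = 7L, window_sd = 1.5, k1 = 0.01, k2 = 0.03) {
  stopifnot(all(diff(scale_factors) > 0), all(scale_factors >= 1),
            window_size >= 1, window_sd > 0, k1 > 0, k2 > 0)
  m <- length(scale_factors)
  if (is.null(scale_weights)) {
    center <- (m + 1) / 2
    w <- exp(-0.5 * ((seq_len(m) - center) / 1)^2)
    scale_weights <- w / sum(w)
  }
  stopifnot(length(scale_weights) == m, all(scale_weights >= 0),
            abs(sum(scale_weights) - 1) < 1e-8)
  structure(list(scale_factors = as.integer(scale_factors),
                 scale_weights = scale_weights,
                 window_size = as.integer(window_size), window_sd = window_sd,
                 k1 = k1, k2 = k2),
            class = "mssi_spec")
}

# box-average decimation by an integer factor (dims cropped to multiples)
box_downsample <- function(vol, factor) {
  if (factor == 1) return(vol)
  d <- dim(vol)
  nd <- d %/% factor
  vol <- vol[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
             seq_len(nd[3] * factor), drop = FALSE]
  a <- array(vol, dim = c(factor, nd[1], factor, nd[2], factor, nd[3]))
  apply(a, c(2, 4, 6), mean)
}

# separable 'valid' convolution of a 3D array with a 1D kernel per axis
separable_filter_valid <- function(vol, kern) {
  w <- length(kern)
  for (ax in 1:3) {
    d <- dim(vol)
    nd <- d[ax] - w + 1L
    out_dim <- d; out_dim[ax] <- nd
    out <- array(0, dim = out_dim)
    for (t in seq_len(w)) {
      idx <- lapply(seq_len(3), function(a) {
        if (a == ax) seq_len(nd) + t - 1L else seq_len(d[a])
      })
      out <- out + kern[t] * vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    vol <- out
  }
  vol
}

gaussian_kernel_1d <- function(size, sd) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

# mean windowed SSIM of two equally shaped volumes at one scale
ssim_volume <- function(a, b, window_size, window_sd, c1, c2) {
  w <- min(window_size, min(dim(a)))
  kern <- gaussian_kernel_1d(w, window_sd)
  mu_a <- separable_filter_valid(a, kern)
  mu_b <- separable_filter_valid(b, kern)
  e_aa <- separable_filter_valid(a * a, kern)
  e_bb <- separable_filter_valid(b * b, kern)
  e_ab <- separable_filter_valid(a * b, kern)
  var_a <- e_aa - mu_a^2
  var_b <- e_bb - mu_b^2
  cov_ab <- e_ab - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2)
  mean(num / den)
}

#' 3D multiscale structural similarity index
#'
#' Both volumes are box-average downsampled at each scale factor; at each
#' scale the mean Gaussian-windowed SSIM (luminance, contrast, structure
#' with stability constants c1, c2) is computed; per-scale scores are
#' combined by the Gaussian scale weights (a weighted arithmetic mean).
#' Identical volumes score 1; the index is symmetric in its arguments and
#' invariant to a common affine intensity rescaling of both volumes because
#' the stability constants derive from the joint dynamic range.
#'
#' @param vol_a,vol_b equally shaped 3D arrays; every spatial dimension must
#'   be at least the largest scale factor.
#' @param spec an [mssi_spec()].
#' @return similarity score (<= 1).
#' @export
mssi <- function(vol_a, vol_b, spec = mssi_spec()) {
  if (!identical(dim(vol_a), dim(vol_b)))
    stop_rsn("shape_error", "volumes must have identical shapes")
  maxf <- max(spec$scale_factors)
  if (any(dim(vol_a) < maxf))
    stop_rsn("volume_too_small",
             "volume %s is smaller than the largest scale factor %d; drop large factors",
             paste(dim(vol_a), collapse = "x"), maxf)
  rng <- range(c(vol_a, vol_b))
  L <- diff(rng)
  if (L == 0) L <- 1          # both volumes constant; SSIM reduces to luminance
  c1 <- (spec$k1 * L)^2
  c2 <- (spec$k2 * L)^2
  scores <- vapply(spec$scale_factors, function(f) {
    ssim_volume(box_downsample(vol_a, f), box_downsample(vol_b, f),
                spec$window_size, spec$window_sd, c1, c2)
  }, numeric(1))
  sum(spec$scale_weights * scores)
}

#' Scale factors that fit a grid
#'
#' Subset of the requested factors not exceeding the smallest volume
#' dimension, for use on small (phantom) grids.
#' @param dims integer(3) volume dimensions.
#' @param factors candidate factors.
#' @return integer vector.
#' @export
fitting_scale_factors <- function(dims, factors = c(2, 4, 8, 16, 32)) {
  f <- factors[factors <= min(dims)]
  if (!length(f)) stop_rsn("volume_too_small", "no scale factor fits %s",
                           paste(dims, collapse = "x"))
  as.integer(f)
}

#' Network-averaged MSSI between two probability map sets
#'
#' MSSI computed per network between the corresponding probability volumes,
#' then averaged; the per-network scores are attached as an attribute.
#'
#' @param pm_a,pm_b `probability_maps` on the same grid.
#' @param spec an [mssi_spec()].
#' @return mean MSSI with attribute `per_network`.
#' @export
mssi_probability_maps <- function(pm_a, pm_b,
                                  spec = mssi_spec(fitting_scale_factors(dim(pm_a$probs)[1:3]))) {
  stopifnot(identical(dim(pm_a$probs), dim(pm_b$probs)))
  K <- dim(pm_a$probs)[4]
  per <- vapply(seq_len(K), function(k)
    mssi(pm_a$probs[, , , k], pm_b$probs[, , , k], spec), numeric(1))
  structure(mean(per), per_network = per)
}
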