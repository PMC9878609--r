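#' Pink-noise injection settings
#'
#' @param fraction noise share f in [0, 1): the signal is rescaled to
#'   `[-(1-f), (1-f)]` and the noise to `[-f, f]` before summation.
#' @param exponent spectral exponent of the noise (1 = pink).
#' @param per_voxel generate an independent noise series for each voxel.
#' @return a `noise_spec`.
#' @export
noise_spec <- function(fraction, exponent = 1, per_voxel = TRUE) {
  stopifnot(fraction >= 0, fraction < 1)
  structure(list(fraction = fraction, exponent = exponent,
                 per_voxel = isTRUE(per_voxel)),
            class = "noise_spec")
}

# affine rescale of x so min -> -a and max -> +a; constant series map to 0
rescale_interval <- function(x, a) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo) * 2 * a - a
}

#' Inject scaled pink noise into a scan
#'
#' Per in-mask voxel: the BOLD series is affinely rescaled so its extremes
#' hit +/-(1 - f); an independently generated pink-noise series is rescaled
#' to +/- f; the two are summed. With `f = 0` the rescaled original is
#' returned unchanged. All output values lie in [-1, 1]. Constant voxel
#' series rescale to zero and carry noise only.
#'
#' @param scan a `bold_scan`.
#' @param spec a [noise_spec()] (or a bare fraction).
#' @param rng_seed integer seed; each voxel gets its own substream draw.
#' @return a `bold_scan` with the mixed data.
#' @export
inject_noise <- function(scan, spec, rng_seed = 1L) {
  if (is.numeric(spec)) spec <- noise_spec(spec)
  f <- spec$fraction
  d <- dim(scan$data)
  in_mask <- which(scan$mask)
  S <- series_matrix(scan, in_mask)           # T x n
  Tn <- d[4]
  out <- apply(S, 2, rescale_interval, a = 1 - f)
  if (f > 0) {
    noise <- with_seed(rng_seed,
                       pink_noise_matrix(Tn, length(in_mask), spec$exponent))
    noise <- apply(noise, 2, rescale_interval, a = f)
    out <- out + noise
  }
  data <- array(0, dim = d)
  nv <- prod(d[1:3])
  for (t in seq_len(Tn)) data[in_mask + (t - 1L) * nv] <- out[t, ]
  scan$data <- data
  scan
}

#' Truncate a scan to its first frames
#'
#' Keeps the first `n_frames` time points; a request at or beyond the scan
#' length returns the scan unchanged.
#'
#' @param scan a `bold_scan`.
#' @param n_frames frames to keep (>= 2).
#' @return a `bold_scan`.
#' @export
truncate_scan <- function(scan, n_frames) {
  stopifnot(n_frames >= 2)
  Tn <- dim(scan$data)[4]
  if (n_frames >= Tn) return(scan)
  scan$data <- scan$data[, , , seq_len(n_frames), drop = FALSE]
  scan
}
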