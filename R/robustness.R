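#' Frame-truncation robustness curve
#'
#' Probability maps are inferred from the full scan (the reference) and from
#' truncations to each frame count; at each level the network-averaged MSSI
#' between the truncated-scan maps and the reference maps is recorded.
#'
#' @param model a `trained_rsn_cnn`.
#' @param scan a `bold_scan`.
#' @param mask optional logical mask.
#' @param frame_grid frame counts to evaluate (each <= T).
#' @param spec an [mssi_spec()]; defaults to the factors fitting the grid.
#' @return a `robustness_curve`: data.frame with `level`, `mssi`, and
#'   per-network columns; attribute `kind = "frames"`.
#' @export
robustness_frames <- function(model, scan, mask = NULL, frame_grid,
                              spec = NULL) {
  Tn <- dim(scan$data)[4]
  stopifnot(max(frame_grid) <= Tn, all(frame_grid >= 2))
  spec <- spec %||% mssi_spec(fitting_scale_factors(dim(scan$data)[1:3]))
  ref <- voxelwise_probability_maps(model, scan, mask)
  rows <- lapply(frame_grid, function(n) {
    pm <- voxelwise_probability_maps(model, truncate_scan(scan, n), mask)
    s <- mssi_probability_maps(pm, ref, spec)
    c(level = n, mssi = as.numeric(s), attr(s, "per_network"))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out)[-(1:2)] <- paste0("net", seq_len(ncol(out) - 2))
  attr(out, "kind") <- "frames"
  class(out) <- c("robustness_curve", class(out))
  out
}

#' Pink-noise robustness curve
#'
#' Probability maps from the clean scan are the reference; at each noise
#' fraction, maps inferred from [inject_noise()] output are compared to the
#' reference by network-averaged MSSI.
#'
#' @inheritParams robustness_frames
#' @param fraction_grid noise fractions in [0, 1).
#' @param rng_seed integer seed; each fraction gets its own substream.
#' @return a `robustness_curve` with attribute `kind = "noise"`.
#' @export
robustness_noise <- function(model, scan, mask = NULL, fraction_grid,
                             rng_seed = 1L, spec = NULL) {
  stopifnot(all(fraction_grid >= 0 & fraction_grid < 1))
  spec <- spec %||% mssi_spec(fitting_scale_factors(dim(scan$data)[1:3]))
  ref <- voxelwise_probability_maps(model, scan, mask)
  rows <- lapply(fraction_grid, function(f) {
    noisy <- inject_noise(scan, noise_spec(f),
                          rng_seed = substream_seed(rng_seed, sprintf("f%.4f", f)))
    pm <- voxelwise_probability_maps(model, noisy, mask)
    s <- mssi_probability_maps(pm, ref, spec)
    c(level = f, mssi = as.numeric(s), attr(s, "per_network"))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out)[-(1:2)] <- paste0("net", seq_len(ncol(out) - 2))
  attr(out, "kind") <- "noise"
  class(out) <- c("robustness_curve", class(out))
  out
}

#' Plot a robustness curve
#' @param x a `robustness_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.robustness_curve <- function(x, ...) {
  kind <- attr(x, "kind") %||% "level"
  graphics::plot(x$level, x$mssi, type = "b", pch = 16,
                 xlab = if (kind == "frames") "frames retained" else "noise fraction",
                 ylab = "network-averaged MSSI", ylim = c(min(x$mssi, 0.5), 1), ...)
  graphics::abline(h = 0.9, lty = 2, col = "gray50")
  invisible(x)
}
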