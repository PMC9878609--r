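#' Configuration of the 3D dense-residual classifier
#'
#' Parameterized template of the volumetric classifier: a stem convolution
#' followed by `n_dense_blocks` densely connected blocks whose units each
#' contain a 1x1x1 bottleneck convolution and a spatial convolution with a
#' residual identity skip; combined max+average 2x2x2/stride-2 pooling
#' between blocks; batch normalization before every convolution and leaky
#' rectification after; a classification head (global average pooling,
#' dropout, linear softmax) on every dense block plus the final output. The
#' default desk-scale instantiation uses 3 blocks of 2 units with growth 8
#' and spatial kernels (3, 3, 7): the three kernel sizes 1, 3, and 7 all
#' appear, with the 7x7x7 kernel in the deepest (coarsest-grid) block.
#'
#' @param n_classes number of networks K (>= 2).
#' @param in_channels input channels (2: correlation and distance).
#' @param n_dense_blocks number of dense blocks (>= 1).
#' @param units_per_block dense units per block (recycled to length
#'   `n_dense_blocks`).
#' @param growth feature maps added by each dense unit.
#' @param stem_channels channels produced by the stem convolution.
#' @param block_kernels spatial kernel size per block (odd; recycled).
#' @param stem_kernel stem kernel size (odd).
#' @param leaky_slope negative-region slope of the activations.
#' @param dropout dropout probability in the classification heads.
#' @param aux_heads if `TRUE`, every dense block contributes a deep-
#'   supervision head in addition to the final head.
#' @return a `cnn_config`.
#' @export
cnn_config <- function(n_classes, in_channels = 2L, n_dense_blocks = 3L,
                       units_per_block = 2L, growth = 8L, stem_channels = 8L,
                       block_kernels = c(3L, 3L, 7L), stem_kernel = 3L,
                       leaky_slope = 0.01, dropout = 0.2, aux_heads = TRUE) {
  stopifnot(n_classes >= 2, n_dense_blocks >= 1, dropout >= 0, dropout < 1,
            leaky_slope > 0, all(block_kernels %% 2 == 1), stem_kernel %% 2 == 1)
  structure(list(n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 n_dense_blocks = as.integer(n_dense_blocks),
                 units_per_block = rep_len(as.integer(units_per_block), n_dense_blocks),
                 growth = as.integer(growth),
                 stem_channels = as.integer(stem_channels),
                 block_kernels = rep_len(as.integer(block_kernels), n_dense_blocks),
                 stem_kernel = as.integer(stem_kernel),
                 leaky_slope = leaky_slope, dropout = dropout,
                 aux_heads = isTRUE(aux_heads)),
            class = "cnn_config")
}

#' Training schedule
#'
#' @param max_epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param validation_interval epochs between validations.
#' @param patience consecutive non-improving validations before stopping.
#' @param weight_decay decoupled weight decay on convolution/linear weights
#'   (0 disables; regularization option, off by default).
#' @param rng_seed integer seed controlling initialization, shuffling,
#'   dropout, and augmentation.
#' @return a `train_schedule`.
#' @export
train_schedule <- function(max_epochs = 40L, batch_size = 32L,
                           learning_rate = 1e-3, validation_interval = 1L,
                           patience = 3L, weight_decay = 0, rng_seed = 1L) {
  stopifnot(patience >= 1, validation_interval >= 1, max_epochs >= 1,
            batch_size >= 1, learning_rate > 0, weight_decay >= 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_interval = as.integer(validation_interval),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 rng_seed = as.integer(rng_seed)),
            class = "train_schedule")
}

#' Build the 3D dense-residual classifier
#'
#' Instantiates the architecture described in [cnn_config()] for a fixed
#' input grid. Uses the RNG state for weight initialization; wrap in
#' `set.seed()` (or use [train_model()], which seeds) for reproducibility.
#'
#' @param config a [cnn_config()].
#' @param input_shape integer(3) spatial grid of the input samples.
#' @return an `rsn_cnn` model object.
#' @export
build_model <- function(config, input_shape) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 3)
  input_shape <- as.integer(input_shape)
  nb <- config$n_dense_blocks
  dims <- input_shape
  for (b in seq_len(nb - 1)) {
    if (any(dims %% 2 != 0) || any(dims %/% 2 < 1))
      stop_rsn("shape_error",
               "input grid %s cannot survive %d poolings",
               paste(input_shape, collapse = "x"), nb - 1)
    dims <- dims %/% 2L
  }

  g <- config$growth
  layers <- list()
  add <- function(ly) { layers[[length(layers) + 1L]] <<- ly; length(layers) }

  dims <- input_shape
  stem <- list(bn = add(layer_bn(config$in_channels)),
               conv = add(layer_conv(dims, config$stem_kernel,
                                     config$in_channels, config$stem_channels)))
  cin <- config$stem_channels
  blocks <- list()
  for (b in seq_len(nb)) {
    units <- list()
    for (u in seq_len(config$units_per_block[b])) {
      units[[u]] <- list(
        bn1 = add(layer_bn(cin)),
        conv1 = add(layer_conv(dims, 1L, cin, g)),
        bn2 = add(layer_bn(g)),
        conv2 = add(layer_conv(dims, config$block_kernels[b], g, g)))
      cin <- cin + g
    }
    head <- if (config$aux_heads || b == nb)
      list(linear = add(layer_linear(cin, config$n_classes))) else NULL
    pool <- NULL
    if (b < nb) {
      pool <- add(layer_pool(dims))
      dims <- dims %/% 2L
    }
    blocks[[b]] <- list(units = units, head = head, pool = pool,
                        dims_in = if (b == 1) input_shape else dims * (if (is.null(pool)) 1L else 2L))
  }
  final <- list(bn = add(layer_bn(cin)),
                linear = add(layer_linear(cin, config$n_classes)))

  structure(list(config = config, input_shape = input_shape,
                 layers = layers, stem = stem, blocks = blocks, final = final),
            class = "rsn_cnn")
}

#' @export
print.rsn_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(ly)
    sum(vapply(ly$params, function(p) length(get(p, envir = ly)), numeric(1))),
    numeric(1)))
  cat(sprintf("rsn_cnn: %d dense blocks, input %s, %d classes, %d parameters, %d heads\n",
              x$config$n_dense_blocks, paste(x$input_shape, collapse = "x"),
              x$config$n_classes,
              as.integer(np), n_heads(x)))
  invisible(x)
}

n_heads <- function(model) {
  sum(vapply(model$blocks, function(b) !is.null(b$head), logical(1))) + 1L
}

# forward pass; X is (nvox*B) x in_channels; returns list of per-head logits
# (each B x K) plus caches needed for backward
cnn_forward <- function(model, X, B, train = FALSE) {
  cfg <- model$config
  L <- model$layers
  slope <- cfg$leaky_slope
  cache <- list()

  x <- bn_forward(L[[model$stem$bn]], X, train)
  x <- conv_forward(L[[model$stem$conv]], x, B)
  x <- leaky_forward(x, slope)
  cache$stem_out <- x

  head_logits <- list()
  head_drop <- list()
  block_caches <- list()
  dims <- model$input_shape
  for (b in seq_along(model$blocks)) {
    blk <- model$blocks[[b]]
    nvox <- prod(dims)
    ucaches <- list()
    for (u in seq_along(blk$units)) {
      un <- blk$units[[u]]
      h <- bn_forward(L[[un$bn1]], x, train)
      h <- conv_forward(L[[un$conv1]], h, B)
      h <- leaky_forward(h, slope)
      v <- bn_forward(L[[un$bn2]], h, train)
      v <- conv_forward(L[[un$conv2]], v, B)
      v <- leaky_forward(v, slope)
      out <- v + h                       # residual identity skip
      ucaches[[u]] <- list(h = h, v = v, x_ncol = ncol(x))
      x <- cbind(x, out)                 # dense connectivity
    }
    hd <- NULL
    if (!is.null(blk$head)) {
      pooled <- gap_forward(x, nvox, B)
      dp <- dropout_forward(pooled, cfg$dropout, train)
      head_logits[[length(head_logits) + 1L]] <-
        linear_forward(L[[blk$head$linear]], dp$Y)
      hd <- dp$mask
      head_drop[[length(head_logits)]] <- hd
    }
    block_caches[[b]] <- list(ucaches = ucaches, nvox = nvox,
                              x_block_out = if (!is.null(blk$pool)) NULL else x,
                              head_mask = hd)
    if (!is.null(blk$pool)) {
      block_caches[[b]]$x_prepool_ncol <- ncol(x)
      x <- pool_forward(L[[blk$pool]], x, B)
      dims <- dims %/% 2L
    }
  }

  # final head: BN -> leaky -> GAP -> dropout -> linear
  nvox <- prod(dims)
  xf <- bn_forward(L[[model$final$bn]], x, train)
  xf <- leaky_forward(xf, slope)
  pooled <- gap_forward(xf, nvox, B)
  dp <- dropout_forward(pooled, cfg$dropout, train)
  head_logits[[length(head_logits) + 1L]] <- linear_forward(L[[model$final$linear]], dp$Y)

  list(logits = head_logits,
       cache = list(stem_out = cache$stem_out, blocks = block_caches,
                    final_x = xf, final_nvox = nvox,
                    final_mask = dp$mask, head_drop = head_drop, B = B))
}

dropout_forward <- function(Y, p, train) {
  if (!train || p <= 0) return(list(Y = Y, mask = NULL))
  mask <- matrix(stats::rbinom(length(Y), 1, 1 - p), nrow(Y), ncol(Y)) / (1 - p)
  list(Y = Y * mask, mask = mask)
}

# backward pass: dlogits is a list matching cnn_forward()$logits
cnn_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  L <- model$layers
  slope <- cfg$leaky_slope
  B <- fw$cache$B

  # final head
  dp <- linear_backward(L[[model$final$linear]], dlogits[[length(dlogits)]])
  if (!is.null(fw$cache$final_mask)) dp <- dp * fw$cache$final_mask
  dx <- gap_backward(dp, fw$cache$final_nvox, B)
  dx <- leaky_backward(fw$cache$final_x, dx, slope)
  dx <- bn_backward(L[[model$final$bn]], dx)

  hi <- length(dlogits) - 1L              # next head gradient to consume
  for (b in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[b]]
    bc <- fw$cache$blocks[[b]]
    if (!is.null(blk$pool)) dx <- pool_backward(L[[blk$pool]], dx, B)
    if (!is.null(blk$head)) {
      dph <- linear_backward(L[[blk$head$linear]], dlogits[[hi]])
      if (!is.null(bc$head_mask)) dph <- dph * bc$head_mask
      dx <- dx + gap_backward(dph, bc$nvox, B)
      hi <- hi - 1L
    }
    for (u in rev(seq_along(blk$units))) {
      un <- blk$units[[u]]
      uc <- bc$ucaches[[u]]
      ncx <- uc$x_ncol
      d_out <- dx[, (ncx + 1L):ncol(dx), drop = FALSE]
      dx <- dx[, seq_len(ncx), drop = FALSE]
      dv <- leaky_backward(uc$v, d_out, slope)
      dv <- conv_backward(L[[un$conv2]], dv, B)
      dv <- bn_backward(L[[un$bn2]], dv)
      dh <- d_out + dv                     # residual: d_out flows to h directly
      dh <- leaky_backward(uc$h, dh, slope)
      dh <- conv_backward(L[[un$conv1]], dh, B)
      dh <- bn_backward(L[[un$bn1]], dh)
      dx <- dx + dh
    }
  }
  dx <- leaky_backward(fw$cache$stem_out, dx, slope)
  dx <- conv_backward(L[[model$stem$conv]], dx, B)
  bn_backward(L[[model$stem$bn]], dx)
  invisible(NULL)
}
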