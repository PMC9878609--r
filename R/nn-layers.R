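# Minimal 3D convolutional network machinery.
#
# Feature maps are stored as matrices of shape (nvox * B) x C with the B
# samples stacked in contiguous row blocks (voxel index fastest), where nvox
# is the number of voxels of the layer's spatial grid. Convolutions are
# computed by gathering im2col patch matrices and multiplying through BLAS;
# backward passes are hand-written. Each layer is an environment holding its
# parameters, Adam state, and a cache from the last forward pass.

# im2col index table: rows = output voxels, cols = kernel taps; entries are
# linear indices into the input grid, with nvox + 1 denoting the zero pad.
conv_index_table <- function(dims, k) {
  half <- (k - 1L) %/% 2L
  nvox <- prod(dims)
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3]))
  offs <- expand.grid(di = -half:half, dj = -half:half, dk = -half:half)
  idx <- matrix(nvox + 1L, nvox, nrow(offs))
  for (t in seq_len(nrow(offs))) {
    ii <- g$i + offs$di[t]; jj <- g$j + offs$dj[t]; kk <- g$k + offs$dk[t]
    ok <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2] & kk >= 1 & kk <= dims[3]
    idx[ok, t] <- (kk[ok] - 1L) * dims[1] * dims[2] + (jj[ok] - 1L) * dims[1] + ii[ok]
  }
  idx
}

# 2x2x2 stride-2 pooling index table: rows = output voxels, 8 cols of
# disjoint input voxel indices (dims must be even).
pool_index_table <- function(dims) {
  stopifnot(all(dims %% 2 == 0))
  od <- dims %/% 2L
  g <- expand.grid(i = seq_len(od[1]), j = seq_len(od[2]), k = seq_len(od[3]))
  offs <- expand.grid(di = 0:1, dj = 0:1, dk = 0:1)
  idx <- matrix(0L, prod(od), 8L)
  for (t in 1:8) {
    ii <- 2L * g$i - 1L + offs$di[t]
    jj <- 2L * g$j - 1L + offs$dj[t]
    kk <- 2L * g$k - 1L + offs$dk[t]
    idx[, t] <- (kk - 1L) * dims[1] * dims[2] + (jj - 1L) * dims[1] + ii
  }
  idx
}

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

layer_conv <- function(dims, k, cin, cout) {
  fan_in <- k^3 * cin
  ly <- new_layer("conv", dims = dims, k = k, cin = cin, cout = cout,
                  idx = conv_index_table(dims, k),
                  W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                             fan_in, cout),
                  b = rep(0, cout))
  ly$params <- c("W", "b")
  ly
}

# rowwise affine maps through the compiled kernel
add_rowwise <- function(X, v) row_scale_shift(X, rep(1, ncol(X)), v)
mul_rowwise <- function(X, v) row_scale_shift(X, v, rep(0, ncol(X)))

conv_forward <- function(ly, X, B) {
  ly$cache <- X
  if (ly$k == 1L) {                    # 1x1x1: plain channel mixing
    return(add_rowwise(X %*% ly$W, ly$b))
  }
  conv3d_fwd(X, ly$idx, ly$W, ly$b, as.integer(B))
}

conv_backward <- function(ly, dY, B) {
  if (ly$k == 1L) {
    ly$gW <- crossprod(ly$cache, dY)
    ly$gb <- colSums(dY)
    ly$cache <- NULL
    return(tcrossprod(dY, ly$W))
  }
  res <- conv3d_bwd(ly$cache, ly$idx, ly$W, dY, as.integer(B))
  ly$gW <- res$dW
  ly$gb <- res$db
  ly$cache <- NULL
  res$dX
}

layer_bn <- function(cin, momentum = 0.1, eps = 1e-5) {
  ly <- new_layer("bn", cin = cin, momentum = momentum, eps = eps,
                  gamma = rep(1, cin), beta = rep(0, cin),
                  run_mean = rep(0, cin), run_var = rep(1, cin))
  ly$params <- c("gamma", "beta")
  ly
}

bn_forward <- function(ly, X, train) {
  if (train) {
    m <- colMeans(X)
    Xc <- add_rowwise(X, -m)
    v <- colMeans(Xc * Xc)
    ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * m
    ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * v
    inv <- 1 / sqrt(v + ly$eps)
    Xh <- mul_rowwise(Xc, inv)
    ly$cache <- list(Xh = Xh, inv = inv)
    add_rowwise(mul_rowwise(Xh, ly$gamma), ly$beta)
  } else {
    scale <- ly$gamma / sqrt(ly$run_var + ly$eps)
    row_scale_shift(X, scale, ly$beta - ly$run_mean * scale)
  }
}

bn_backward <- function(ly, dY) {
  Xh <- ly$cache$Xh; inv <- ly$cache$inv
  ly$ggamma <- colSums(dY * Xh)
  ly$gbeta <- colSums(dY)
  dXh <- mul_rowwise(dY, ly$gamma)
  # standard batchnorm gradient
  t1 <- add_rowwise(dXh, -colMeans(dXh))
  t2 <- mul_rowwise(Xh, colMeans(dXh * Xh))
  dX <- mul_rowwise(t1 - t2, inv)
  ly$cache <- NULL
  dX
}

leaky_forward <- function(X, slope) leaky_fwd(X, slope)

# slope > 0 preserves sign, so the forward output identifies the region
leaky_backward <- function(X_out, dY, slope) leaky_bwd(X_out, dY, slope)

layer_pool <- function(dims) {
  new_layer("pool", dims = dims, odims = dims %/% 2L,
            idx = pool_index_table(dims), params = character(0))
}

pool_forward <- function(ly, X, B) {
  nvox <- prod(ly$dims); novox <- prod(ly$odims)
  C <- ncol(X)
  Y <- matrix(0, novox * B, C)
  am <- matrix(1L, novox * B, C)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * nvox + 1L):(b * nvox)
    orows <- ((b - 1L) * novox + 1L):(b * novox)
    Xb <- X[rows, , drop = FALSE]
    mx <- Xb[ly$idx[, 1], , drop = FALSE]
    av <- mx
    amb <- matrix(1L, novox, C)
    for (t in 2:8) {
      slab <- Xb[ly$idx[, t], , drop = FALSE]
      upd <- slab > mx
      amb[upd] <- t
      mx[upd] <- slab[upd]
      av <- av + slab
    }
    Y[orows, ] <- 0.5 * (mx + av / 8)
    am[orows, ] <- amb
  }
  ly$cache <- am
  Y
}

pool_backward <- function(ly, dY, B) {
  nvox <- prod(ly$dims); novox <- prod(ly$odims)
  C <- ncol(dY)
  am <- ly$cache
  dX <- matrix(0, nvox * B, C)
  for (b in seq_len(B)) {
    rows0 <- (b - 1L) * nvox
    orows <- ((b - 1L) * novox + 1L):(b * novox)
    dYb <- dY[orows, , drop = FALSE]
    amb <- am[orows, , drop = FALSE]
    for (t in 1:8) {
      contrib <- dYb * (1 / 16 + 0.5 * (amb == t))
      dX[rows0 + ly$idx[, t], ] <- contrib   # blocks are disjoint across taps
    }
  }
  ly$cache <- NULL
  dX
}

# global average pooling: (nvox*B) x C -> B x C
gap_forward <- function(X, nvox, B) {
  C <- ncol(X)
  Y <- matrix(0, B, C)
  for (b in seq_len(B))
    Y[b, ] <- colMeans(X[((b - 1L) * nvox + 1L):(b * nvox), , drop = FALSE])
  Y
}

gap_backward <- function(dY, nvox, B) {
  C <- ncol(dY)
  dX <- matrix(0, nvox * B, C)
  for (b in seq_len(B))
    dX[((b - 1L) * nvox + 1L):(b * nvox), ] <-
      matrix(dY[b, ] / nvox, nvox, C, byrow = TRUE)
  dX
}

layer_linear <- function(cin, cout) {
  ly <- new_layer("linear", cin = cin, cout = cout,
                  W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
                  b = rep(0, cout))
  ly$params <- c("W", "b")
  ly
}

linear_forward <- function(ly, X) {
  ly$cache <- X
  sweep(X %*% ly$W, 2, ly$b, "+")
}

linear_backward <- function(ly, dY) {
  ly$gW <- crossprod(ly$cache, dY)
  ly$gb <- colSums(dY)
  dX <- tcrossprod(dY, ly$W)
  ly$cache <- NULL
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# class-weighted cross entropy; returns loss and gradient wrt logits
weighted_ce <- function(logits, labels, class_weights) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  wi <- class_weights[labels]
  pick <- cbind(seq_len(n), labels)
  loss <- -mean(wi * log(pmax(P[pick], 1e-12)))
  G <- P
  G[pick] <- G[pick] - 1
  G <- G * (wi / n)
  list(loss = loss, grad = G)
}

# Adam step over all params of a list of layers, with decoupled weight
# decay on convolution/linear weights (never on biases or BN parameters)
adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (ly in layers) {
    for (p in ly$params) {
      decay <- if (weight_decay > 0 && p == "W") weight_decay else 0
      g <- get(paste0("g", p), envir = ly)
      mk <- paste0("m_", p); vk <- paste0("v_", p); tk <- paste0("t_", p)
      if (!exists(mk, envir = ly)) {
        assign(mk, g * 0, envir = ly); assign(vk, g * 0, envir = ly)
        assign(tk, 0L, envir = ly)
      }
      t_ <- get(tk, envir = ly) + 1L
      m <- beta1 * get(mk, envir = ly) + (1 - beta1) * g
      v <- beta2 * get(vk, envir = ly) + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t_)
      vhat <- v / (1 - beta2^t_)
      cur <- get(p, envir = ly)
      assign(p, cur - lr * (mhat / (sqrt(vhat) + eps) + decay * cur),
             envir = ly)
      assign(mk, m, envir = ly); assign(vk, v, envir = ly)
      assign(tk, t_, envir = ly)
    }
  }
}

snapshot_params <- function(layers) {
  lapply(layers, function(ly) {
    s <- lapply(ly$params, function(p) get(p, envir = ly))
    names(s) <- ly$params
    if (ly$type == "bn") {
      s$run_mean <- ly$run_mean
      s$run_var <- ly$run_var
    }
    s
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (nm in names(snap[[i]])) assign(nm, snap[[i]][[nm]], envir = layers[[i]])
  }
  invisible(NULL)
}
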