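# sample channels (X,Y,Z,2) -> (nvox x 2) matrix
sample_matrix <- function(sample) {
  ch <- sample$channels
  nv <- prod(dim(ch)[1:3])
  matrix(ch, nv, dim(ch)[4])
}

stack_batch <- function(samples) {
  do.call(rbind, lapply(samples, sample_matrix))
}

#' Early-stopping rule
#'
#' Given the sequence of validation accuracies, returns the index of the
#' validation after which training stops: the first validation at which the
#' running count of consecutive non-improving validations (strict improvement
#' over the running best) reaches `patience`. `NA` if training never stops.
#'
#' @param val_acc numeric vector of validation accuracies in order.
#' @param patience consecutive non-improving validations tolerated.
#' @return integer index or `NA`.
#' @export
early_stop_after <- function(val_acc, patience) {
  best <- -Inf; since <- 0L
  for (i in seq_along(val_acc)) {
    if (val_acc[i] > best) { best <- val_acc[i]; since <- 0L }
    else {
      since <- since + 1L
      if (since >= patience) return(i)
    }
  }
  NA_integer_
}

#' Train the classifier
#'
#' Minibatch training with Adam on the deep-supervision loss: the unweighted
#' sum over all heads of class-weighted cross entropy. Training-split samples
#' are augmented on the fly with the training set's [augment_params()];
#' validation samples are never augmented. Validation runs every
#' `validation_interval` epochs; training stops at `max_epochs` or once
#' validation accuracy (final head) has not strictly improved for `patience`
#' consecutive validations. The returned model carries the parameters of the
#' best validation checkpoint.
#'
#' Randomness (shuffling, dropout, augmentation) draws from the RNG seeded
#' with `sched$rng_seed`; for end-to-end reproducibility including weight
#' initialization use [fit_rsn_classifier()].
#'
#' @param model an [build_model()] result.
#' @param tset a [build_training_set()] result with both splits populated.
#' @param sched a [train_schedule()].
#' @param augment apply on-the-fly augmentation to training samples.
#' @param verbose print per-validation progress.
#' @return a `trained_rsn_cnn` (the model plus `history`, `best_validation`).
#' @export
train_model <- function(model, tset, sched = train_schedule(), augment = TRUE,
                        verbose = FALSE) {
  stopifnot(inherits(model, "rsn_cnn"), inherits(tset, "training_set"))
  train_idx <- which(tset$split == "train")
  val_idx <- which(tset$split == "val")
  if (!length(train_idx) || !length(val_idx))
    stop("training set must have both train and validation samples")
  cw <- tset$class_weights
  labels <- vapply(tset$samples, `[[`, integer(1), "label")
  val_X <- stack_batch(tset$samples[val_idx])
  val_y <- labels[val_idx]

  set.seed(sched$rng_seed)
  history <- list()
  best_acc <- -Inf; best_snap <- NULL; since_best <- 0L; n_val <- 0L
  stopped <- FALSE

  for (epoch in seq_len(sched$max_epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = sched$batch_size)) {
      bidx <- ord[start:min(start + sched$batch_size - 1L, length(ord))]
      B <- length(bidx)
      batch_samples <- tset$samples[bidx]
      if (augment)
        batch_samples <- lapply(batch_samples, augment_sample_, params = tset$aug)
      X <- stack_batch(batch_samples)
      y <- labels[bidx]
      fw <- cnn_forward(model, X, B, train = TRUE)
      losses <- lapply(fw$logits, weighted_ce, labels = y, class_weights = cw)
      loss <- sum(vapply(losses, `[[`, numeric(1), "loss"))
      if (!is.finite(loss)) stop_rsn("divergence", "training loss became non-finite")
      cnn_backward(model, fw, lapply(losses, `[[`, "grad"))
      adam_step(model$layers, sched$learning_rate,
                weight_decay = sched$weight_decay %||% 0)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }

    if (epoch %% sched$validation_interval == 0L) {
      n_val <- n_val + 1L
      ev <- evaluate_logits(model, val_X, length(val_idx), sched$batch_size)
      val_acc <- mean(max.col(ev, ties.method = "first") == val_y)
      val_loss <- weighted_ce(ev, val_y, cw)$loss
      history[[n_val]] <- data.frame(validation = n_val, epoch = epoch,
                                     train_loss = ep_loss / nb,
                                     val_loss = val_loss, val_acc = val_acc)
      if (verbose)
        message(sprintf("validation %d (epoch %d): acc %.3f loss %.4f",
                        n_val, epoch, val_acc, val_loss))
      if (val_acc > best_acc) {
        best_acc <- val_acc; since_best <- 0L
        best_snap <- snapshot_params(model$layers)
      } else {
        since_best <- since_best + 1L
        if (since_best >= sched$patience) { stopped <- TRUE; break }
      }
    }
  }
  if (!is.null(best_snap)) restore_params(model$layers, best_snap)
  history <- do.call(rbind, history)
  model$history <- history
  model$best_validation <- which.max(history$val_acc)
  model$schedule <- sched
  model$early_stopped <- stopped
  class(model) <- c("trained_rsn_cnn", class(model))
  model
}

#' Build and train in one reproducible step
#'
#' Seeds the RNG with `sched$rng_seed` before weight initialization, so two
#' calls with identical inputs produce identical models and histories.
#'
#' @inheritParams train_model
#' @param config a [cnn_config()]; `n_classes` must match the training set.
#' @param input_shape spatial grid of the samples.
#' @return a `trained_rsn_cnn`.
#' @export
fit_rsn_classifier <- function(config, tset, sched = train_schedule(),
                               input_shape = dim(tset$samples[[1]]$channels)[1:3],
                               augment = TRUE, verbose = FALSE) {
  set.seed(sched$rng_seed)
  model <- build_model(config, input_shape)
  train_model(model, tset, sched, augment = augment, verbose = verbose)
}

# final-head logits for stacked eval-mode inputs, in minibatches
evaluate_logits <- function(model, X, n, batch_size = 64L) {
  nvox <- nrow(X) / n
  out <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    rows <- ((take[1] - 1L) * nvox + 1L):(take[length(take)] * nvox)
    fw <- cnn_forward(model, X[rows, , drop = FALSE], length(take), train = FALSE)
    out[take, ] <- fw$logits[[length(fw$logits)]]
  }
  out
}

#' Classify one similarity sample
#'
#' Final-head softmax probability vector; auxiliary heads are ignored at
#' inference and dropout is disabled, so repeated calls are identical.
#'
#' @param model a trained (or at least built) `rsn_cnn`.
#' @param sample a `similarity_sample` with the model's spatial shape.
#' @return numeric length-K probability vector summing to 1.
#' @export
predict_sample <- function(model, sample) {
  ch_dim <- dim(sample$channels)[1:3]
  if (!identical(as.integer(ch_dim), model$input_shape))
    stop_rsn("shape_error", "sample shape %s does not match model input %s",
             paste(ch_dim, collapse = "x"),
             paste(model$input_shape, collapse = "x"))
  fw <- cnn_forward(model, sample_matrix(sample), 1L, train = FALSE)
  p <- softmax_rows(fw$logits[[length(fw$logits)]])[1, ]
  names(p) <- NULL
  p
}

# batched softmax probabilities for a list of (nvox x 2) matrices
predict_matrix_batch <- function(model, mats, batch_size = 64L) {
  n <- length(mats)
  out <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    X <- do.call(rbind, mats[take])
    fw <- cnn_forward(model, X, length(take), train = FALSE)
    out[take, ] <- softmax_rows(fw$logits[[length(fw$logits)]])
  }
  out
}

#' Classification accuracy over labeled samples
#'
#' Fraction of samples whose final-head argmax equals the label.
#'
#' @param model a trained `rsn_cnn`.
#' @param samples list of `similarity_sample`.
#' @param labels integer labels, same length as `samples`.
#' @return accuracy in [0, 1].
#' @export
evaluate_accuracy <- function(model, samples, labels) {
  if (length(samples) != length(labels) || !length(samples))
    stop_rsn("length_mismatch", "samples and labels must have equal positive length")
  X <- stack_batch(samples)
  logits <- evaluate_logits(model, X, length(samples))
  mean(max.col(logits, ties.method = "first") == labels)
}

#' Save / load a model checkpoint
#'
#' One file holding the architecture configuration (as JSON text), learned
#' parameters, and training history.
#'
#' @param model a `trained_rsn_cnn` (or `rsn_cnn`).
#' @param path file path.
#' @return `path` invisibly (`save_model`); a model (`load_model`).
#' @export
save_model <- function(model, path) {
  obj <- list(config_json = jsonlite::toJSON(unclass(model$config),
                                             auto_unbox = TRUE, digits = NA),
              input_shape = model$input_shape,
              params = snapshot_params(model$layers),
              history = model$history,
              best_validation = model$best_validation,
              early_stopped = model$early_stopped)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- jsonlite::fromJSON(obj$config_json)
  config <- do.call(cnn_config, cfg[setdiff(names(cfg), character(0))])
  model <- build_model(config, obj$input_shape)
  restore_params(model$layers, obj$params)
  model$history <- obj$history
  model$best_validation <- obj$best_validation
  model$early_stopped <- obj$early_stopped
  if (!is.null(model$history)) class(model) <- c("trained_rsn_cnn", class(model))
  model
}

#' Export training history as TSV
#' @param model a `trained_rsn_cnn`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
export_history <- function(model, path) {
  utils::write.table(model$history, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
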