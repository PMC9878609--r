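test_that("every classification head emits a softmax distribution", {
  model <- tiny_model()
  set.seed(1)
  for (i in 1:3) {
    X <- matrix(rnorm(512 * 2), 512, 2)
    fw <- rsnmap:::cnn_forward(model, X, 1L, train = FALSE)
    expect_length(fw$logits, 3)           # 2 block heads + final
    for (lg in fw$logits) {
      p <- rsnmap:::softmax_rows(lg)
      expect_equal(sum(p), 1, tolerance = 1e-6)
      expect_true(all(p >= 0 & p <= 1))
    }
  }
})

test_that("grids that cannot survive the poolings are rejected", {
  cfg <- cnn_config(n_classes = 4)        # 3 blocks = 2 poolings
  expect_s3_class(build_model(cfg, c(4, 4, 4)), "rsn_cnn")
  expect_error(build_model(cfg, c(2, 2, 2)), class = "shape_error")
})

test_that("inference is deterministic (dropout disabled)", {
  model <- tiny_model()
  ch <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  s <- rsnmap:::new_similarity_sample(ch, 1L, "x")
  p1 <- predict_sample(model, s)
  p2 <- predict_sample(model, s)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  bad <- rsnmap:::new_similarity_sample(array(0, c(4, 4, 4, 2)), 1L, "x")
  expect_error(predict_sample(model, bad), class = "shape_error")
})

test_that("early stopping fires after exactly `patience` non-improvements", {
  expect_identical(early_stop_after(c(0.5, 0.9, 0.9, 0.9, 0.9), 3), 5L)
  expect_identical(early_stop_after(c(0.5, 0.6, 0.7), 3), NA_integer_)
  expect_identical(early_stop_after(c(0.9, 0.8, 0.8, 0.8), 3), 4L)
  # equal accuracy is not a strict improvement
  expect_identical(early_stop_after(c(0.9, 0.9, 0.9, 0.9), 3), 4L)
  set.seed(2)
  for (i in 1:50) {
    acc <- round(runif(sample(4:12, 1)), 2)
    stop_at <- early_stop_after(acc, 2)
    if (!is.na(stop_at)) {
      best <- which.max(acc[seq_len(stop_at)])
      # never more than `patience` validations after the running best
      expect_lte(stop_at - best, 2)
    }
  }
})

test_that("training learns a separable phantom and stops early", {
  fit <- tiny_trained()
  model <- fit$model
  expect_s3_class(model, "trained_rsn_cnn")
  expect_gt(nrow(model$history), 0)
  expect_identical(model$best_validation,
                   which.max(model$history$val_acc))
  expect_gte(max(model$history$val_acc), 0.95)
  # no more than `patience` validations after the best one
  expect_lte(nrow(model$history) - model$best_validation, 3)
})

test_that("training histories are reproducible under a fixed seed", {
  fit <- tiny_trained()
  model2 <- fit_rsn_classifier(
    cnn_config(n_classes = 2, n_dense_blocks = 2, units_per_block = 1,
               growth = 4, stem_channels = 4, block_kernels = c(3, 3)),
    fit$tset, train_schedule(max_epochs = 30, batch_size = 8,
                             learning_rate = 3e-3, validation_interval = 3,
                             rng_seed = 9))
  expect_equal(fit$model$history, model2$history)
})

test_that("accuracy is the fraction of correct final-head argmaxes", {
  model <- tiny_model()
  set.seed(3)
  samples <- lapply(1:4, function(i)
    rsnmap:::new_similarity_sample(array(rnorm(1024), c(8, 8, 8, 2)), 1L, "x"))
  pred <- vapply(samples, function(s) which.max(predict_sample(model, s)),
                 integer(1))
  labels <- pred
  labels[4] <- if (pred[4] == 1L) 2L else 1L   # force exactly 3 of 4 correct
  expect_equal(evaluate_accuracy(model, samples, labels), 0.75)
  expect_error(evaluate_accuracy(model, samples, labels[1:2]),
               class = "length_mismatch")
})

test_that("checkpoints round-trip through save_model / load_model", {
  fit <- tiny_trained()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit$model, path)
  re <- load_model(path)
  ch <- fit$tset$samples[[1]]$channels
  s <- rsnmap:::new_similarity_sample(ch, 1L, "x")
  expect_equal(predict_sample(re, s), predict_sample(fit$model, s),
               tolerance = 1e-12)
  expect_equal(re$history, fit$model$history)
})
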