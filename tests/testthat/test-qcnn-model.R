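test_that("the default architecture traces to the printed head sizes", {
  cfg <- model_config()
  tr <- trace_shapes(cfg)
  expect_equal(tr$flatten, 512)
  expect_equal(cfg$flatten_size, 512)
  model <- build_model(cfg)
  # dense head: 512 -> 100 -> 4
  dense <- Filter(function(l) l$type == "dense", model$layers)
  expect_equal(dim(dense[[1]]$params$W), c(512L, 100L))
  expect_equal(dim(dense[[2]]$params$W), c(100L, 4L))
  # a forward pass at batch 1 actually produces 4 logits
  lg <- forward_model(model, matrix(rnorm(2048), 1))$logits
  expect_equal(dim(lg), c(1L, 4L))
})

test_that("the builder rejects flatten mismatches naming both sizes", {
  cfg <- model_config()
  cfg$input_length <- 1024L   # traced flatten would be 256, declared 512
  expect_error(build_model(cfg), "512")
  expect_error(build_model(cfg), "256")
})

test_that("the full quadratic network starts exactly at its linear twin", {
  cfg <- tiny_cfg(seed = 4)
  qm <- build_model(cfg, quadratic = TRUE)
  lm <- build_model(cfg, quadratic = FALSE)
  lm$layers[[1]]$params$W <- qm$layers[[1]]$params$Wr
  X <- matrix(rnorm(6 * 64), 6)
  expect_equal(forward_model(qm, X)$logits, forward_model(lm, X)$logits,
               tolerance = 1e-12)
})

test_that("training reduces the loss and is seed-deterministic", {
  set <- separable_set(n_per_class = 10, seed = 2)
  cfg <- tiny_cfg(seed = 5, epochs = 2, batch_size = 8)
  m1 <- train_model(build_model(cfg), set)
  expect_lte(m1$curves$train_loss[2], m1$curves$train_loss[1])
  m2 <- train_model(build_model(cfg), set)
  expect_identical(quadspec:::flatten_params(m1),
                   quadspec:::flatten_params(m2))
  expect_identical(m1$curves, m2$curves)

  expect_error(train_model(build_model(cfg),
                           list(x = matrix(rnorm(64 * 3), 3), y = c(2, 2, 2))),
               "single class")
})

test_that("a small model learns a noise-free separable fixture", {
  set <- separable_set(n_per_class = 10, seed = 6)
  cfg <- tiny_cfg(seed = 6, epochs = 60, batch_size = 10, lr = 3e-2)
  model <- train_model(build_model(cfg), set)
  pred <- predict_grade(model, set$spectra)
  expect_gt(mean(pred$level == set$labels), 0.9)
  # training duplicates keep their labels on the separable fixture
  expect_equal(pred$level[1], set$labels[1])
})

test_that("predict_grade returns proper probabilities and batches consistently", {
  set <- separable_set(n_per_class = 3, seed = 9)
  model <- build_model(tiny_cfg(seed = 2))
  pred <- predict_grade(model, set$spectra)
  expect_equal(rowSums(as.matrix(pred[, -1])), rep(1, nrow(pred)),
               tolerance = 1e-6)
  single <- do.call(rbind, lapply(seq_len(4), function(i)
    predict_grade(model, set$spectra[i, ])))
  expect_equal(single, pred[seq_len(4), ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(predict_grade(model, rnorm(100)), "length")
})

test_that("evaluate_model and the metric arithmetic are exact", {
  # perfect prediction: identity confusion, all scores 1
  m <- classification_metrics(diag(c(5L, 5L, 5L, 5L)))
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)

  # hand-computed 2-class example
  m2 <- classification_metrics(matrix(c(1, 0, 1, 2), 2))
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$macro_recall, (0.5 + 1) / 2)
  expect_equal(m2$macro_f1, (2 / 3 + 4 / 5) / 2)

  set <- separable_set(n_per_class = 3, seed = 10)
  model <- build_model(tiny_cfg(seed = 3))
  res <- evaluate_model(model, set)
  expect_equal(sum(res$confusion), 12)
  expect_error(evaluate_model(model, list(x = set$spectra,
                                          y = rep(9L, 12))), "unseen|outside")
})

test_that("model checkpoints round-trip through JSON", {
  set <- separable_set(n_per_class = 4, seed = 11)
  cfg <- tiny_cfg(seed = 7, epochs = 2, batch_size = 8)
  model <- train_model(build_model(cfg), set)
  path <- file.path(tempdir(), "ckpt.json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(quadspec:::flatten_params(back),
               quadspec:::flatten_params(model), tolerance = 1e-12)
  X <- set$spectra
  expect_equal(predict_grade(back, X), predict_grade(model, X),
               tolerance = 1e-9)
})
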