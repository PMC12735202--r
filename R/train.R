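# Rectified Adam (RAdam). The variance rectification term keeps early
# updates SGD-like until the second-moment estimate is reliable. L2
# weight decay is added to the gradients of weight matrices only (not
# biases or batch-norm parameters), the common convention.

radam_state <- function() list(t = 0L, m = list(), v = list())

radam_step <- function(state, params_flat, grads_flat, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rho_inf <- 2 / (1 - beta2) - 1
  rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
  for (key in names(params_flat)) {
    g <- grads_flat[[key]]
    if (is.null(g)) next
    if (weight_decay > 0 && grepl("/W", key, fixed = TRUE))
      g <- g + weight_decay * params_flat[[key]]
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g * 0
      state$v[[key]] <- g * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    m_hat <- state$m[[key]] / (1 - beta1^t)
    if (rho_t > 4) {
      v_hat <- sqrt(state$v[[key]] / (1 - beta2^t))
      r_t <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                    ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      params_flat[[key]] <- params_flat[[key]] -
        lr * r_t * m_hat / (v_hat + eps)
    } else {
      params_flat[[key]] <- params_flat[[key]] - lr * m_hat
    }
  }
  list(state = state, params = params_flat)
}

# flatten / restore model parameters as a named list "layer<i>/<name>";
# weight matrices keep a "/W" prefix convention for decay filtering
flatten_params <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    p <- model$layers[[i]]$params
    for (nm in names(p)) {
      tag <- if (nm %in% c("W", "Wr", "Wg", "Wb")) paste0("W.", nm) else nm
      out[[sprintf("layer%02d/%s", i, tag)]] <- p[[nm]]
    }
  }
  out
}

restore_params <- function(model, flat) {
  for (i in seq_along(model$layers)) {
    p <- model$layers[[i]]$params
    for (nm in names(p)) {
      tag <- if (nm %in% c("W", "Wr", "Wg", "Wb")) paste0("W.", nm) else nm
      model$layers[[i]]$params[[nm]] <- flat[[sprintf("layer%02d/%s", i, tag)]]
    }
  }
  model
}

flatten_grads <- function(model, grads) {
  out <- list()
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    for (nm in names(g)) {
      tag <- if (nm %in% c("W", "Wr", "Wg", "Wb")) paste0("W.", nm) else nm
      out[[sprintf("layer%02d/%s", i, tag)]] <- g[[nm]]
    }
  }
  out
}

as_xy <- function(data, input_length) {
  if (inherits(data, "spectra_set")) {
    if (is.null(data$labels)) stop("training/evaluation set has no labels")
    X <- data$spectra
    y <- data$labels
  } else {
    X <- data$x
    y <- data$y
  }
  X <- as.matrix(X)
  if (ncol(X) != input_length)
    X <- resample_to_length(X, input_length)
  list(X = X, y = as.integer(y))
}

# forward in evaluation mode, chunked to bound memory
predict_logits <- function(model, X, chunk = 256L) {
  n <- nrow(X)
  out <- matrix(0, n, model$cfg$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- forward_model(model, X[s:e, , drop = FALSE],
                                training = FALSE)$logits
  }
  out
}

#' Train a 1DQCNN / 1DCNN classifier
#'
#' Minimizes softmax cross-entropy with the optimizer named in the model
#' configuration (RAdam by default). All randomness (shuffling, dropout)
#' derives from `cfg$seed`, so identical configurations reproduce
#' identical weights and curves. When a test set is supplied the weights
#' with the best test accuracy are checkpointed and restored at the end,
#' and per-epoch train/test loss and accuracy curves are recorded.
#'
#' @param model A [build_model()] result.
#' @param train_set [spectra_set()] with labels (or `list(x, y)`).
#'   Spectra are resampled to the configured input length if needed.
#' @param test_set Optional held-out set monitored each epoch.
#' @param epochs,batch_size,lr,weight_decay Override the corresponding
#'   `model$cfg` values when non-`NULL`.
#' @param verbose Print a line per epoch.
#' @return The trained `qcnn_model`; element `curves` holds the
#'   per-epoch metrics data.frame.
#' @export
train_model <- function(model, train_set, test_set = NULL, epochs = NULL,
                        batch_size = NULL, lr = NULL, weight_decay = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "qcnn_model"))
  cfg <- model$cfg
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  lr <- if (is.null(lr)) cfg$lr else lr
  weight_decay <- if (is.null(weight_decay)) cfg$weight_decay else weight_decay
  tr <- as_xy(train_set, cfg$input_length)
  n <- nrow(tr$X)
  if (n == 0L) stop("train_model: empty training set")
  if (length(unique(tr$y)) < 2L)
    stop("train_model: training set has a single class")
  if (any(tr$y < 1L | tr$y > cfg$n_classes))
    stop("train_model: labels outside 1..n_classes")
  te <- if (!is.null(test_set)) as_xy(test_set, cfg$input_length)

  set.seed(cfg$seed + 1L)       # training RNG (shuffling, dropout)
  opt <- radam_state()
  curves <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       train_acc = numeric(0), test_loss = numeric(0),
                       test_acc = numeric(0))
  best_acc <- -Inf
  best_params <- NULL
  best_layers <- NULL
  sched <- if (is.null(cfg$lr_schedule)) "cosine" else cfg$lr_schedule
  for (ep in seq_len(epochs)) {
    lr_ep <- if (sched == "cosine" && epochs > 1)
      lr * (0.1 + 0.45 * (1 + cos(pi * (ep - 1) / (epochs - 1))))
    else lr
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(n, s + batch_size - 1L)]
      fw <- forward_model(model, tr$X[idx, , drop = FALSE], training = TRUE)
      # fold refreshed BN running stats back into the layers
      for (i in seq_along(fw$running)) {
        if (!is.null(fw$running[[i]])) {
          model$layers[[i]]$running_mean <- fw$running[[i]]$mean
          model$layers[[i]]$running_var <- fw$running[[i]]$var
        }
      }
      ls <- softmax_xent(fw$logits, tr$y[idx])
      ep_loss <- ep_loss + ls$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(ls$prob, ties.method = "first") == tr$y[idx])
      grads <- backward_model(model, fw$caches, ls$dlogits)
      step <- radam_step(opt, flatten_params(model), flatten_grads(model, grads),
                         lr_ep, weight_decay)
      opt <- step$state
      model <- restore_params(model, step$params)
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                      train_acc = ep_correct / n,
                      test_loss = NA_real_, test_acc = NA_real_)
    if (!is.null(te)) {
      lg <- predict_logits(model, te$X)
      ls <- softmax_xent(lg, te$y)
      row$test_loss <- ls$loss
      row$test_acc <- mean(max.col(ls$prob, ties.method = "first") == te$y)
      if (row$test_acc > best_acc) {
        best_acc <- row$test_acc
        best_params <- flatten_params(model)
        best_layers <- lapply(model$layers, function(l)
          l[c("running_mean", "running_var")])
      }
    }
    curves <- rbind(curves, row)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  test %.3f",
                      ep, row$train_loss, row$train_acc,
                      if (is.na(row$test_acc)) NA else row$test_acc))
  }
  if (!is.null(best_params)) {      # restore best-test-accuracy checkpoint
    model <- restore_params(model, best_params)
    for (i in seq_along(model$layers)) {
      if (!is.null(best_layers[[i]]$running_mean)) {
        model$layers[[i]]$running_mean <- best_layers[[i]]$running_mean
        model$layers[[i]]$running_var <- best_layers[[i]]$running_var
      }
    }
  }
  model$trained <- TRUE
  model$curves <- curves
  model
}

#' Confusion matrix with true grades as rows
#'
#' @param truth,pred Integer grade vectors in 1..n_classes.
#' @param n_classes Number of classes (default 4).
#' @return `n_classes x n_classes` count matrix, rows = true.
#' @export
confusion_matrix <- function(truth, pred, n_classes = 4) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (any(truth < 1L | truth > n_classes) || any(pred < 1L | pred > n_classes))
    stop("confusion_matrix: labels outside 1..n_classes")
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 1:n_classes, pred = 1:n_classes))
  for (i in seq_along(truth))
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, recall and F1 (0 when the denominator is 0),
#' plus accuracy, macro-F1 and macro-recall.
#'
#' @param confusion Square count matrix, rows = true classes.
#' @return List of class `grade_metrics`.
#' @export
#' @examples
#' classification_metrics(matrix(c(1, 0, 1, 2), 2))$accuracy # 0.75
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(confusion = confusion, n = n,
                 accuracy = sum(tp) / n,
                 precision = prec, recall = rec, f1 = f1,
                 macro_f1 = mean(f1), macro_recall = mean(rec)),
            class = "grade_metrics")
}

#' @export
print.grade_metrics <- function(x, ...) {
  cat(sprintf("<grade_metrics> n=%d accuracy=%.4f macro-F1=%.4f macro-recall=%.4f\n",
              x$n, x$accuracy, x$macro_f1, x$macro_recall))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a trained model on a labelled set
#'
#' @param model Trained `qcnn_model`.
#' @param test_set [spectra_set()] with labels (or `list(x, y)`).
#' @return A `grade_metrics` object.
#' @export
evaluate_model <- function(model, test_set) {
  te <- as_xy(test_set, model$cfg$input_length)
  if (nrow(te$X) == 0L) stop("evaluate_model: empty test set")
  if (any(te$y < 1L | te$y > model$cfg$n_classes))
    stop("evaluate_model: unseen label values outside 1..n_classes")
  lg <- predict_logits(model, te$X)
  pred <- max.col(softmax(lg), ties.method = "first")
  classification_metrics(confusion_matrix(te$y, pred, model$cfg$n_classes))
}

#' Predict grade levels and class probabilities for spectra
#'
#' @param model Trained `qcnn_model`.
#' @param x Numeric vector (one spectrum of the training grid length or
#'   the network input length), matrix of spectra, or [spectra_set()].
#' @return data.frame with `level` and probability columns `p1..pK`.
#' @export
predict_grade <- function(model, x) {
  if (inherits(x, "spectra_set")) x <- x$spectra
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  L <- model$cfg$input_length
  if (ncol(x) != L) {
    if (ncol(x) == 701L) x <- resample_to_length(x, L)
    else stop(sprintf(
      "predict_grade: spectrum length %d matches neither the input length %d nor the 701-band grid",
      ncol(x), L))
  }
  prob <- softmax(predict_logits(model, x))
  out <- data.frame(level = max.col(prob, ties.method = "first"))
  colnames(prob) <- paste0("p", seq_len(ncol(prob)))
  cbind(out, as.data.frame(prob))
}

#' Serialize a model (with its configuration) to a JSON checkpoint
#'
#' @param model A `qcnn_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  layers <- lapply(model$layers, function(l) {
    keep <- l[setdiff(names(l), "params")]
    keep$params <- lapply(l$params, function(p)
      list(dim = dim(p), data = as.numeric(p)))
    keep
  })
  obj <- list(package = "quadspec", format = 1L,
              cfg = unclass(model$cfg), quadratic = model$quadratic,
              trained = model$trained, flatten = model$flatten,
              layers = layers, curves = model$curves)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return A `qcnn_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$package, "quadspec"))
    stop("load_model: not a quadspec checkpoint: ", path)
  cfgl <- obj$cfg
  num <- function(x) if (is.null(x)) NULL else unlist(x)
  cfg <- model_config(
    input_length = num(cfgl$input_length), n_classes = num(cfgl$n_classes),
    channels = num(cfgl$channels), kernels = num(cfgl$kernels),
    strides = num(cfgl$strides), pool_after = num(cfgl$pool_after),
    hidden = num(cfgl$hidden),
    flatten_size = if (is.null(cfgl$flatten_size)) NA else cfgl$flatten_size,
    dropout = num(cfgl$dropout), batch_size = num(cfgl$batch_size),
    epochs = num(cfgl$epochs), lr = num(cfgl$lr),
    weight_decay = num(cfgl$weight_decay), optimizer = num(cfgl$optimizer),
    seed = num(cfgl$seed),
    lr_schedule = if (is.null(cfgl$lr_schedule)) "cosine" else cfgl$lr_schedule,
    profile = "default")
  cfg$lr <- num(cfgl$lr); cfg$epochs <- as.integer(num(cfgl$epochs))
  if (!is.null(cfgl$profile)) cfg$profile <- cfgl$profile
  model <- build_model(cfg, quadratic = isTRUE(obj$quadratic))
  for (i in seq_along(model$layers)) {
    li <- obj$layers[[i]]
    for (nm in names(model$layers[[i]]$params)) {
      p <- li$params[[nm]]
      v <- as.numeric(unlist(p$data))
      if (!is.null(p$dim) && length(p$dim)) dim(v) <- unlist(p$dim)
      model$layers[[i]]$params[[nm]] <- v
    }
    if (!is.null(li$running_mean))
      model$layers[[i]]$running_mean <- as.numeric(unlist(li$running_mean))
    if (!is.null(li$running_var))
      model$layers[[i]]$running_var <- as.numeric(unlist(li$running_var))
  }
  model$trained <- isTRUE(obj$trained)
  if (!is.null(obj$curves) && length(obj$curves))
    model$curves <- do.call(rbind, lapply(obj$curves, function(r)
      as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x))))
  model
}
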