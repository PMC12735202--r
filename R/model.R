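#' Configuration of the 1-D (quadratic) CNN classifier
#'
#' The default architecture is: a wide first convolution (kernel 64,
#' stride 8, 16 output channels) followed by batch normalization, ReLU
#' and 2/2 max pooling; a local convolution (kernel 3, stride 1, 16
#' channels) with BN + ReLU and a second 2/2 pooling; a channel-reducing
#' convolution (kernel 3, stride 1, 16 to 8 channels) with BN + ReLU;
#' then flatten, a 100-unit dense layer with ReLU and dropout, and the
#' classification layer. With the canonical input length 2048 (reached by
#' [resample_to_length()] from the 701-band instrument grid) the flatten
#' width is exactly 512: 2048 -> 256 (stride 8) -> 128 (pool) -> 128 ->
#' 64 (pool) -> 64 x 8 channels.
#'
#' Two training profiles are provided. `"default"` uses RAdam at
#' learning rate 1e-3; `"paper"` mirrors the published protocol
#' (learning rate 0.5, 500 epochs), which sits far outside typical RAdam
#' ranges and is retained for documentation rather than recommended use.
#'
#' @param input_length Canonical network input length (default 2048).
#' @param n_classes Number of grade levels (default 4).
#' @param channels,kernels,strides,pool_after Per-conv-layer settings.
#' @param hidden Width of the first dense layer (default 100).
#' @param flatten_size Declared flatten width; the builder verifies it
#'   against the traced shape and rejects mismatches. `NA` accepts the
#'   traced value.
#' @param dropout Dropout rate on the dense layer (default 0.5).
#' @param batch_size,epochs,lr,weight_decay,optimizer Training
#'   hyperparameters (defaults: 32, 100, 1e-3, 1e-4, "radam").
#' @param lr_schedule `"cosine"` (default) anneals the learning rate by
#'   a cosine from `lr` to `lr / 10` over the epochs, damping
#'   late-training oscillation; `"constant"` keeps it fixed.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param profile `"default"` or `"paper"` (see Details).
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_length = 2048, n_classes = 4,
                         channels = c(16, 16, 8), kernels = c(64, 3, 3),
                         strides = c(8, 1, 1),
                         pool_after = c(TRUE, TRUE, FALSE),
                         hidden = 100, flatten_size = NA,
                         dropout = 0.5, batch_size = 32, epochs = 100,
                         lr = 1e-3, weight_decay = 1e-4,
                         optimizer = "radam", seed = 1,
                         lr_schedule = c("cosine", "constant"),
                         profile = c("default", "paper")) {
  profile <- match.arg(profile)
  lr_schedule <- match.arg(lr_schedule)
  if (profile == "paper") { lr <- 0.5; epochs <- 500 }
  stopifnot(length(channels) == length(kernels),
            length(kernels) == length(strides),
            length(strides) == length(pool_after))
  if (n_classes < 2) stop("model_config: n_classes must be >= 2")
  if (input_length < kernels[1L])
    stop("model_config: input_length must be >= first kernel length")
  if (dropout < 0 || dropout >= 1)
    stop("model_config: dropout must lie in [0, 1)")
  cfg <- structure(list(
    input_length = as.integer(input_length), n_classes = as.integer(n_classes),
    channels = as.integer(channels), kernels = as.integer(kernels),
    strides = as.integer(strides), pool_after = as.logical(pool_after),
    hidden = as.integer(hidden), flatten_size = flatten_size,
    dropout = dropout, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
    optimizer = optimizer, seed = as.integer(seed),
    lr_schedule = lr_schedule, profile = profile),
    class = "model_config")
  tr <- trace_shapes(cfg)
  if (is.na(cfg$flatten_size) && identical(cfg$input_length, 2048L) &&
      identical(cfg$channels, c(16L, 16L, 8L)))
    cfg$flatten_size <- tr$flatten
  cfg
}

#' Trace intermediate tensor shapes of a model configuration
#'
#' @param cfg A [model_config()] (or a `qcnn_model`).
#' @return List with a per-stage `table` (data.frame of stage, length,
#'   channels) and the resulting `flatten` width.
#' @export
trace_shapes <- function(cfg) {
  if (inherits(cfg, "qcnn_model")) cfg <- cfg$cfg
  L <- cfg$input_length; C <- 1L
  rows <- data.frame(stage = "input", length = L, channels = C)
  for (i in seq_along(cfg$channels)) {
    g <- conv_geom(L, cfg$kernels[i], cfg$strides[i], "same")
    L <- g$L_out; C <- cfg$channels[i]
    rows <- rbind(rows, data.frame(stage = sprintf("conv%d", i),
                                   length = L, channels = C))
    if (cfg$pool_after[i]) {
      L <- L %/% 2L
      rows <- rbind(rows, data.frame(stage = sprintf("pool%d", i),
                                     length = L, channels = C))
    }
  }
  list(table = rows, flatten = L * C)
}

#' Build a 1DQCNN (or its linear ablation baseline)
#'
#' With `quadratic = TRUE` the first convolution uses quadratic neurons
#' initialized so that the network starts exactly linear (the (g) branch
#' is the constant 1 and the squared branch is zero); with
#' `quadratic = FALSE` every convolution is linear, giving the ablation
#' baseline that differs only in the first layer's neuron type.
#'
#' @param cfg A [model_config()].
#' @param quadratic Use a quadratic first convolution (default TRUE).
#' @return Object of class `qcnn_model`.
#' @export
build_model <- function(cfg, quadratic = TRUE) {
  stopifnot(inherits(cfg, "model_config"))
  tr <- trace_shapes(cfg)
  if (!is.na(cfg$flatten_size) && tr$flatten != cfg$flatten_size)
    stop(sprintf(
      "build_model: declared flatten size %d but traced size is %d",
      cfg$flatten_size, tr$flatten))
  set.seed(cfg$seed)
  layers <- list()
  in_ch <- 1L
  for (i in seq_along(cfg$channels)) {
    layers <- c(layers, list(
      layer_conv(in_ch, cfg$channels[i], cfg$kernels[i], cfg$strides[i],
                 quadratic = quadratic && i == 1L),
      layer_bn(cfg$channels[i]),
      layer_relu()))
    if (cfg$pool_after[i]) layers <- c(layers, list(layer_pool()))
    in_ch <- cfg$channels[i]
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(tr$flatten, cfg$hidden),
    layer_relu(),
    layer_dropout(cfg$dropout),
    layer_dense(cfg$hidden, cfg$n_classes)))
  structure(list(cfg = cfg, layers = layers, quadratic = quadratic,
                 trained = FALSE, flatten = tr$flatten),
            class = "qcnn_model")
}

#' @export
print.qcnn_model <- function(x, ...) {
  cat(sprintf("<qcnn_model> %s first layer, input %d, flatten %d, %d classes%s\n",
              if (x$quadratic) "quadratic" else "linear",
              x$cfg$input_length, x$flatten, x$cfg$n_classes,
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

# Full forward pass. X: B x input_length matrix. Returns logits and the
# per-layer caches needed for backprop (training = TRUE also returns the
# refreshed BN running statistics).
forward_model <- function(model, X, training = FALSE) {
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- vector("list", length(model$layers))
  running <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- fwd_layer(model$layers[[i]], A, training)
    A <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$running)) running[[i]] <- r$running
  }
  list(logits = A, caches = caches, running = running)
}

# Backward pass; returns one grads list per layer (empty for
# parameter-free layers).
backward_model <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  dA <- dlogits
  for (i in rev(seq_along(model$layers))) {
    r <- bwd_layer(model$layers[[i]], caches[[i]], dA)
    dA <- r$dA
    grads[[i]] <- r$grads
  }
  grads
}
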