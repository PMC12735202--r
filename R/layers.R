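# Internal neural-network primitives for the 1-D (quadratic) CNN.
#
# Activations are stored as 3-D arrays [batch B, length L, channels C].
# Convolutions are evaluated as matrix products via im2col: the receptive
# fields are gathered into a (B*L_out) x (C*k) matrix so that both the
# linear branch and the two extra branches of the quadratic neuron are
# single BLAS calls per layer.

# column-wise broadcast helpers (faster than sweep(): no aperm copies)
addcol <- function(X, v) X + rep(v, each = nrow(X))
mulcol <- function(X, v) X * rep(v, each = nrow(X))
divcol <- function(X, v) X * rep(1 / v, each = nrow(X))
subcol <- function(X, v) X - rep(v, each = nrow(X))

conv_geom <- function(L, k, s, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  if (k < 1 || s < 1) stop("conv: kernel and stride must be >= 1")
  if (padding == "same") {
    L_out <- as.integer(ceiling(L / s))
    pad_total <- max((L_out - 1L) * s + k - L, 0L)
    pad_left <- pad_total %/% 2L
    L_pad <- L + pad_total
  } else {
    if (L < k) stop("conv: signal shorter than kernel under valid padding")
    L_out <- as.integer((L - k) %/% s + 1L)
    pad_left <- 0L
    L_pad <- L
  }
  # idx[p, j]: padded position feeding output p at kernel offset j
  idx <- outer((seq_len(L_out) - 1L) * s, seq_len(k), "+")
  list(L = L, L_out = L_out, pad_left = pad_left, L_pad = L_pad,
       k = as.integer(k), s = as.integer(s), idx = idx)
}

im2col <- function(A, g) {
  d <- dim(A); B <- d[1L]; L <- d[2L]; C <- d[3L]
  iv <- as.vector(g$idx)
  M <- matrix(0, B * g$L_out, C * g$k)
  for (cc in seq_len(C)) {
    Ap <- matrix(0, B, g$L_pad)
    Ap[, g$pad_left + seq_len(L)] <- A[, , cc]
    Mc <- Ap[, iv, drop = FALSE]          # B x (L_out*k), offset-major cols
    dim(Mc) <- c(B * g$L_out, g$k)
    M[, (cc - 1L) * g$k + seq_len(g$k)] <- Mc
  }
  M
}

col2im <- function(dM, g, B, L, C) {
  dA <- array(0, c(B, L, C))
  for (cc in seq_len(C)) {
    dAp <- matrix(0, B, g$L_pad)
    block <- (cc - 1L) * g$k
    for (j in seq_len(g$k)) {
      col <- dM[, block + j]
      dim(col) <- c(B, g$L_out)
      pos <- g$idx[, j]                   # distinct positions for fixed j
      dAp[, pos] <- dAp[, pos] + col
    }
    dA[, , cc] <- dAp[, g$pad_left + seq_len(L), drop = FALSE]
  }
  dA
}

# He-style fan-in initialization for convolution / dense weights
init_weight <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# ---- layer constructors --------------------------------------------------

layer_conv <- function(in_ch, out_ch, k, s, padding = "same",
                       quadratic = FALSE) {
  fan_in <- in_ch * k
  params <- list(W = init_weight(fan_in, out_ch, fan_in),
                 b = numeric(out_ch))
  if (quadratic) {
    # quadratic neuron starts exactly linear: the (g) branch is the
    # constant 1 and the squared branch is off, so at initialization the
    # layer coincides with its linear counterpart sharing W
    params <- list(Wr = params$W, br = numeric(out_ch),
                   Wg = matrix(0, fan_in, out_ch), bg = rep(1, out_ch),
                   Wb = matrix(0, fan_in, out_ch), c0 = numeric(out_ch))
  }
  list(type = if (quadratic) "qconv" else "conv",
       in_ch = in_ch, out_ch = out_ch, k = k, s = s, padding = padding,
       params = params)
}

layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

layer_relu <- function() list(type = "relu", params = list())
layer_pool <- function() list(type = "pool", params = list())
layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       params = list(W = init_weight(d_in, d_out, d_in),
                     b = numeric(d_out)))
}

layer_dropout <- function(p) list(type = "dropout", p = p, params = list())

# ---- forward / backward --------------------------------------------------

fwd_layer <- function(layer, A, training = FALSE) {
  switch(layer$type,
    conv = {
      g <- conv_geom(dim(A)[2L], layer$k, layer$s, layer$padding)
      B <- dim(A)[1L]
      M <- im2col(A, g)
      out <- addcol(M %*% layer$params$W, layer$params$b)
      dim(out) <- c(B, g$L_out, layer$out_ch)
      list(out = out, cache = list(g = g, M = M, dimA = dim(A)))
    },
    qconv = {
      g <- conv_geom(dim(A)[2L], layer$k, layer$s, layer$padding)
      B <- dim(A)[1L]
      M <- im2col(A, g)
      p <- layer$params
      R <- addcol(M %*% p$Wr, p$br)
      G <- addcol(M %*% p$Wg, p$bg)
      Q <- addcol((M * M) %*% p$Wb, p$c0)
      out <- R * G + Q
      dim(out) <- c(B, g$L_out, layer$out_ch)
      list(out = out, cache = list(g = g, M = M, R = R, G = G, dimA = dim(A)))
    },
    bn = {
      d <- dim(A)
      X <- matrix(A, d[1L] * d[2L], d[3L])
      if (training) {
        mu <- colMeans(X)
        Xc <- subcol(X, mu)
        va <- colMeans(Xc^2)              # biased, used for normalization
        sd_ <- sqrt(va + layer$eps)
        Xh <- divcol(Xc, sd_)
        cache <- list(Xh = Xh, sd = sd_, d = d)
      } else {
        Xc <- subcol(X, layer$running_mean)
        sd_ <- sqrt(layer$running_var + layer$eps)
        Xh <- divcol(Xc, sd_)
        cache <- NULL
      }
      out <- addcol(mulcol(Xh, layer$params$gamma), layer$params$beta)
      dim(out) <- d
      res <- list(out = out, cache = cache)
      if (training) {
        n <- d[1L] * d[2L]
        unb <- if (n > 1L) va * n / (n - 1L) else va
        res$running <- list(
          mean = (1 - layer$momentum) * layer$running_mean + layer$momentum * mu,
          var = (1 - layer$momentum) * layer$running_var + layer$momentum * unb)
      }
      res
    },
    relu = {
      mask <- A > 0
      list(out = A * mask, cache = list(mask = mask))
    },
    pool = {
      d <- dim(A)
      L2 <- d[2L] %/% 2L
      a1 <- A[, seq(1L, 2L * L2, 2L), , drop = FALSE]
      a2 <- A[, seq(2L, 2L * L2, 2L), , drop = FALSE]
      mask <- a1 >= a2                    # ties take the earlier position
      list(out = pmax(a1, a2), cache = list(mask = mask, d = d, L2 = L2))
    },
    flatten = {
      d <- dim(A)
      out <- A
      dim(out) <- c(d[1L], d[2L] * d[3L])
      list(out = out, cache = list(d = d))
    },
    dense = {
      list(out = addcol(A %*% layer$params$W, layer$params$b),
           cache = list(X = A))
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- (stats::runif(length(A)) >= layer$p) / (1 - layer$p)
        dim(mask) <- dim(A)
        list(out = A * mask, cache = list(mask = mask))
      } else {
        list(out = A, cache = NULL)
      }
    },
    stop("unknown layer type: ", layer$type))
}

bwd_layer <- function(layer, cache, dOut) {
  switch(layer$type,
    conv = {
      g <- cache$g
      B <- cache$dimA[1L]
      dY <- dOut; dim(dY) <- c(B * g$L_out, layer$out_ch)
      grads <- list(W = crossprod(cache$M, dY), b = colSums(dY))
      dM <- tcrossprod(dY, layer$params$W)
      list(dA = col2im(dM, g, B, cache$dimA[2L], cache$dimA[3L]),
           grads = grads)
    },
    qconv = {
      g <- cache$g
      B <- cache$dimA[1L]
      p <- layer$params
      dY <- dOut; dim(dY) <- c(B * g$L_out, layer$out_ch)
      dR <- dY * cache$G
      dG <- dY * cache$R
      M <- cache$M
      grads <- list(Wr = crossprod(M, dR), br = colSums(dR),
                    Wg = crossprod(M, dG), bg = colSums(dG),
                    Wb = crossprod(M * M, dY), c0 = colSums(dY))
      dM <- dR %*% t(p$Wr) + dG %*% t(p$Wg) + 2 * (dY %*% t(p$Wb)) * M
      list(dA = col2im(dM, g, B, cache$dimA[2L], cache$dimA[3L]),
           grads = grads)
    },
    bn = {
      d <- cache$d
      n <- d[1L] * d[2L]
      dY <- dOut; dim(dY) <- c(n, d[3L])
      Xh <- cache$Xh
      grads <- list(gamma = colSums(dY * Xh), beta = colSums(dY))
      dXh <- mulcol(dY, layer$params$gamma)
      # dX = (dXh - mean(dXh) - Xh * mean(dXh * Xh)) / sd
      t1 <- subcol(dXh, colMeans(dXh))
      t2 <- mulcol(Xh, colMeans(dXh * Xh))
      dX <- divcol(t1 - t2, cache$sd)
      dim(dX) <- d
      list(dA = dX, grads = grads)
    },
    relu = list(dA = dOut * cache$mask, grads = list()),
    pool = {
      d <- cache$d
      L2 <- cache$L2
      dA <- array(0, d)
      dA[, seq(1L, 2L * L2, 2L), ] <- dOut * cache$mask
      dA[, seq(2L, 2L * L2, 2L), ] <- dOut * !cache$mask
      list(dA = dA, grads = list())
    },
    flatten = {
      dA <- dOut; dim(dA) <- cache$d
      list(dA = dA, grads = list())
    },
    dense = {
      list(dA = tcrossprod(dOut, layer$params$W),
           grads = list(W = crossprod(cache$X, dOut), b = colSums(dOut)))
    },
    dropout = {
      if (is.null(cache)) list(dA = dOut, grads = list())
      else list(dA = dOut * cache$mask, grads = list())
    },
    stop("unknown layer type: ", layer$type))
}

softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# mean cross-entropy over the batch plus its gradient w.r.t. the logits
softmax_xent <- function(logits, y) {
  B <- nrow(logits)
  prob <- softmax(logits)
  eps <- 1e-12
  loss <- -mean(log(prob[cbind(seq_len(B), y)] + eps))
  dlogits <- prob
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = dlogits / B, prob = prob)
}

#' Quadratic 1-D convolution
#'
#' Evaluates the quadratic-neuron convolution
#' `out = (x . w_r + b_r) * (x . w_g + b_g) + (x^2) . w_b + c`
#' over sliding windows `x` of a 1-D (possibly multi-channel) signal,
#' where `x^2` is the elementwise square of the window. With
#' `w_g = 0, b_g = 1, w_b = 0, c = 0` it reduces exactly to the ordinary
#' linear convolution `x . w_r + b_r`. No activation is applied; that is
#' the enclosing layer's job.
#'
#' @param x Numeric vector (single channel) or `L x C_in` matrix.
#' @param w_r,w_g,w_b Kernel weights: vectors of length `k` for a single
#'   input channel, or arrays of dim `(k, C_in, C_out)`.
#' @param b_r,b_g,c Bias terms, scalars or length-`C_out` vectors.
#' @param stride Convolution stride (default 1).
#' @param padding `"valid"` (no padding) or `"same"`
#'   (zero padding, output length `ceiling(L / stride)`).
#' @return `L_out x C_out` matrix of feature maps (a vector when the
#'   input was a vector and `C_out == 1`).
#' @export
#' @examples
#' # single window, k = 3: (6)(2) + 1 + 1 = 14
#' quad_conv1d(c(1, 2, 3), w_r = c(1, 1, 1), b_r = 0,
#'             w_g = c(0, 0, 0), b_g = 2, w_b = c(1, 0, 0), c = 1,
#'             padding = "valid")
quad_conv1d <- function(x, w_r, w_g, w_b, b_r = 0, b_g = 0, c = 0,
                        stride = 1, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(as.numeric(x), ncol = 1L)
  L <- nrow(x); C_in <- ncol(x)
  as_w <- function(w, name) {
    if (is.null(dim(w))) {
      if (C_in != 1L)
        stop("quad_conv1d: ", name, " must be a (k, C_in, C_out) array ",
             "for multi-channel input")
      w <- array(as.numeric(w), c(length(w), 1L, 1L))
    }
    if (length(dim(w)) != 3L || dim(w)[2L] != C_in)
      stop("quad_conv1d: ", name, " has inconsistent shape")
    w
  }
  w_r <- as_w(w_r, "w_r"); w_g <- as_w(w_g, "w_g"); w_b <- as_w(w_b, "w_b")
  if (!identical(dim(w_r), dim(w_g)) || !identical(dim(w_r), dim(w_b)))
    stop("quad_conv1d: w_r, w_g, w_b must share one shape")
  if (any(!is.finite(w_r)) || any(!is.finite(w_g)) || any(!is.finite(w_b)))
    stop("quad_conv1d: non-finite weights")
  k <- dim(w_r)[1L]; C_out <- dim(w_r)[3L]
  pack <- function(w) {                    # (k, C_in, C_out) -> (C_in*k, C_out)
    m <- matrix(0, C_in * k, C_out)
    for (cc in seq_len(C_in))
      m[(cc - 1L) * k + seq_len(k), ] <- w[, cc, ]
    m
  }
  g <- conv_geom(L, k, stride, padding)
  A <- array(0, c(1L, L, C_in)); A[1L, , ] <- x
  M <- im2col(A, g)
  expand <- function(b) if (length(b) == 1L) rep(b, C_out) else b
  R <- addcol(M %*% pack(w_r), expand(b_r))
  G <- addcol(M %*% pack(w_g), expand(b_g))
  out <- R * G + addcol((M * M) %*% pack(w_b), expand(c))
  if (vec_in && C_out == 1L) as.numeric(out) else out
}
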