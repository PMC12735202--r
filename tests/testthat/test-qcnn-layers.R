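test_that("quad_conv1d matches the triple-loop oracle on random instances", {
  set.seed(21)
  for (trial in 1:40) {
    C <- sample(1:3, 1); Co <- sample(1:3, 1)
    k <- sample(1:7, 1); L <- sample(k:50, 1)
    s <- sample(1:3, 1); pad <- sample(c("same", "valid"), 1)
    x <- matrix(rnorm(L * C), L, C)
    wr <- array(rnorm(k * C * Co), c(k, C, Co))
    wg <- array(rnorm(k * C * Co), c(k, C, Co))
    wb <- array(rnorm(k * C * Co), c(k, C, Co))
    br <- rnorm(Co); bg <- rnorm(Co); c0 <- rnorm(Co)
    expect_equal(quad_conv1d(x, wr, wg, wb, br, bg, c0, s, pad),
                 oracle_quad_conv(x, wr, wg, wb, br, bg, c0, s, pad),
                 tolerance = 1e-10)
  }
})

test_that("quad_conv1d reproduces hand-computed and degenerate cases", {
  # single valid window: (1+2+3)(0+2) + 1^2*1 + 1 = 14
  expect_equal(quad_conv1d(c(1, 2, 3), w_r = c(1, 1, 1), b_r = 0,
                           w_g = c(0, 0, 0), b_g = 2, w_b = c(1, 0, 0), c = 1,
                           padding = "valid"), 14)
  # all-zero weights with c = 5 give a constant map everywhere
  out <- quad_conv1d(rnorm(20), w_r = rep(0, 3), w_g = rep(0, 3),
                     w_b = rep(0, 3), c = 5, padding = "same")
  expect_equal(out, rep(5, 20))
  expect_error(quad_conv1d(1:5, w_r = c(1, NA), w_g = c(0, 0), w_b = c(0, 0)),
               "non-finite")
  expect_error(quad_conv1d(1:5, w_r = 1:2, w_g = 1:3, w_b = 1:2), "shape")
})

test_that("quadratic convolution reduces exactly to the linear one", {
  set.seed(5)
  for (trial in 1:10) {
    k <- sample(2:6, 1); L <- sample(k:30, 1)
    x <- rnorm(L)
    wr <- rnorm(k); br <- rnorm(1)
    quad <- quad_conv1d(x, w_r = wr, w_g = rep(0, k), w_b = rep(0, k),
                        b_r = br, b_g = 1, c = 0, padding = "valid")
    lin <- vapply(seq_len(L - k + 1), function(p)
      sum(x[p:(p + k - 1)] * wr) + br, numeric(1))
    expect_equal(quad, lin, tolerance = 1e-12)
  }
})

test_that("backpropagation matches finite differences through every layer", {
  set.seed(7)
  for (quad in c(TRUE, FALSE)) {
    model <- build_model(tiny_cfg(seed = 3), quadratic = quad)
    B <- 4
    X <- matrix(rnorm(B * 64), B, 64)
    y <- c(1L, 2L, 3L, 4L)
    fw <- forward_model(model, X, training = TRUE)
    ls <- softmax_xent(fw$logits, y)
    grads <- backward_model(model, fw$caches, ls$dlogits)
    gf <- quadspec:::flatten_grads(model, grads)
    pf <- quadspec:::flatten_params(model)
    lossfn <- function(flat) {
      m2 <- quadspec:::restore_params(model, flat)
      softmax_xent(forward_model(m2, X, training = TRUE)$logits, y)$loss
    }
    for (key in names(pf)) {
      n <- length(pf[[key]])
      for (i in sample(n, min(2L, n))) {
        eps <- 1e-5
        up <- pf; up[[key]][i] <- up[[key]][i] + eps
        dn <- pf; dn[[key]][i] <- dn[[key]][i] - eps
        num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
        ana <- gf[[key]][i]
        expect_equal(ana, num, tolerance = 1e-3,
                     label = sprintf("grad %s[%d] (quad=%s)", key, i, quad))
      }
    }
  }
})

test_that("quadratic gradients w.r.t. w_r match the linear layer's at the
          linear initialization point", {
  # at (w_g = 0, b_g = 1, w_b = 0, c = 0) the reduction holds for the
  # gradients too: dL/dWr must equal the linear layer's dL/dW
  cfg <- tiny_cfg(seed = 8)
  qm <- build_model(cfg, quadratic = TRUE)
  lm <- build_model(cfg, quadratic = FALSE)
  lm$layers[[1]]$params$W <- qm$layers[[1]]$params$Wr
  lm$layers[[1]]$params$b <- qm$layers[[1]]$params$br
  X <- matrix(rnorm(3 * 64), 3, 64)
  y <- c(1L, 2L, 4L)
  fq <- forward_model(qm, X, training = TRUE)
  fl <- forward_model(lm, X, training = TRUE)
  expect_equal(fq$logits, fl$logits, tolerance = 1e-12)
  gq <- backward_model(qm, fq$caches, softmax_xent(fq$logits, y)$dlogits)
  gl <- backward_model(lm, fl$caches, softmax_xent(fl$logits, y)$dlogits)
  expect_equal(gq[[1]]$Wr, gl[[1]]$W, tolerance = 1e-12)
  expect_equal(gq[[1]]$br, gl[[1]]$b, tolerance = 1e-12)
})
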