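# Shared fixtures and independent oracles used across the test files.

# small wavelength grid for fast spectral tests
tiny_grid <- function(n = 64) wavelength_grid(400, 1000, n)

# tiny model configuration that exercises every layer type quickly
tiny_cfg <- function(seed = 1, ...) {
  model_config(input_length = 64, kernels = c(8, 3, 3), strides = c(2, 1, 1),
               channels = c(4, 4, 3), hidden = 10, dropout = 0,
               seed = seed, ...)
}

# noise-free, well-separated 4-class set for learning sanity checks
separable_set <- function(n_per_class = 10, seed = 1, n_bands = 64) {
  cfg <- generator_config(n_per_class = n_per_class, noise_sd = 0,
                          scatter_mult_sd = 0, scatter_add_sd = 0,
                          seed = seed, grid = tiny_grid(n_bands))
  generate_dataset(cfg)
}

# naive triple-loop evaluation of the quadratic convolution, kept
# deliberately independent of the im2col implementation path
oracle_quad_conv <- function(x, wr, wg, wb, br, bg, c0, stride, padding) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  L <- nrow(x); C <- ncol(x); k <- dim(wr)[1L]; Co <- dim(wr)[3L]
  if (padding == "same") {
    Lo <- ceiling(L / stride)
    pt <- max((Lo - 1) * stride + k - L, 0)
    pl <- pt %/% 2
    xp <- rbind(matrix(0, pl, C), x, matrix(0, pt - pl, C))
  } else {
    Lo <- (L - k) %/% stride + 1
    xp <- x
  }
  out <- matrix(0, Lo, Co)
  for (p in seq_len(Lo)) {
    win <- xp[(p - 1) * stride + seq_len(k), , drop = FALSE]
    for (co in seq_len(Co)) {
      r <- sum(win * wr[, , co]) + br[co]
      g <- sum(win * wg[, , co]) + bg[co]
      out[p, co] <- r * g + sum(win^2 * wb[, , co]) + c0[co]
    }
  }
  out
}

# brute-force SPXY reference: recomputes every candidate's minimum
# distance to the selected set from scratch at each accretion step
oracle_spxy <- function(X, y, n_train) {
  X <- as.matrix(X)
  n <- nrow(X)
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(as.numeric(y), as.numeric(y), "-"))
  d <- dx / max(dx) + dy / max(dy)
  best <- -Inf; pair <- c(1L, 2L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && d[i, j] > best) { best <- d[i, j]; pair <- sort(c(i, j)) }
  }
  sel <- pair
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(i) min(d[i, sel]), numeric(1L))
    sel <- c(sel, cand[which.max(score)])
  }
  sort(sel)
}

# disc mask of radius r centred in an n x n image
disc_mask <- function(r, n = 64) {
  x <- seq_len(n) - (n + 1) / 2
  outer(x, x, function(a, b) sqrt(a^2 + b^2)) <= r
}

# canonical sphere-in-sphere phantom (fruit r = 40 mm, watercore r = 20 mm)
sphere_phantom <- function(pitch = 1) {
  make_phantom(phantom_spec(
    c(40, 40, 40), list(list(centre = c(0, 0, 0), semiaxes = c(20, 20, 20))),
    pitch = pitch))
}
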