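test_that("snv centres and scales with the n-1 convention", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, mean = 3, sd = 2)
  z <- snv(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(snv(z), z, tolerance = 1e-12)        # idempotent on normalized
  expect_equal(snv(x + 5), snv(x), tolerance = 1e-12) # offset invariance
  expect_error(snv(c(5, 5, 5)), "degenerate")
})

test_that("minmax maps onto [0,1] and is positive-affine invariant", {
  expect_equal(minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax(c(0, 1)), c(0, 1))
  x <- rnorm(30)
  expect_equal(range(minmax(x)), c(0, 1))
  expect_equal(minmax(3 * x + 2), minmax(x), tolerance = 1e-12)
  expect_error(minmax(rep(1, 4)), "degenerate")
})

test_that("msc removes affine scatter exactly", {
  # spectra constructed as a_i * ref + b_i recover ref for every row
  ref <- sin(seq(0, 3, length.out = 40)) + 2
  a <- c(0.7, 1.0, 1.3, 2.0); b <- c(-0.2, 0, 0.4, 1.0)
  X <- t(vapply(seq_along(a), function(i) a[i] * ref + b[i], ref))
  corr <- msc(X, reference = ref)
  for (i in seq_len(nrow(corr)))
    expect_equal(unname(corr[i, ]), unname(ref), tolerance = 1e-9)

  # two-spectrum closed form: both rows collapse onto the mean spectrum
  X2 <- rbind(c(1, 2, 3), c(2, 4, 6))
  corr2 <- msc(X2)
  expect_equal(unname(corr2[1, ]), c(1.5, 3, 4.5), tolerance = 1e-12)
  expect_equal(unname(corr2[2, ]), c(1.5, 3, 4.5), tolerance = 1e-12)

  # a single spectrum is its own reference and passes through unchanged
  X1 <- matrix(c(1, 3, 2, 5), 1)
  expect_equal(unname(msc(X1)[1, ]), c(1, 3, 2, 5))

  # idempotence against the stored reference
  again <- msc(corr, reference = attr(corr, "reference"))
  expect_equal(unname(again), unname(corr), tolerance = 1e-9)
  expect_error(msc(matrix(1, 3, 4)), "degenerate")
})

test_that("standardization fits columns and reuses parameters on new data", {
  X <- rbind(c(0, 10), c(2, 30))
  Z <- standardize(X)
  expect_equal(unname(Z[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(Z[, 2]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  Xr <- matrix(rnorm(200, 5, 3), 20, 10)
  fit <- standardize_fit(Xr)
  Zr <- standardize_apply(fit, Xr)
  expect_true(all(abs(colMeans(Zr)) < 1e-9))
  expect_true(all(abs(apply(Zr, 2, sd) - 1) < 1e-9))
  # applying the fitted transform to already-transformed data is the
  # same as fitting on it (parameters persisted, not re-estimated)
  held <- matrix(rnorm(50, 5, 3), 5, 10)
  expect_equal(standardize_apply(fit, held),
               sweep(sweep(held, 2, fit$center), 2, fit$scale, "/"))
  bad <- cbind(rnorm(5), rep(1, 5))
  expect_error(standardize_fit(bad), "column")
})

test_that("resample_to_length interpolates linearly and preserves endpoints", {
  expect_equal(resample_to_length(c(0, 1), 3), c(0, 0.5, 1))
  x <- rnorm(37)
  expect_identical(resample_to_length(x, 37), x)        # identity at L = P
  expect_equal(resample_to_length(rep(2, 10), 25), rep(2, 25))
  y <- resample_to_length(x, 101)
  expect_equal(y[1], x[1]); expect_equal(y[101], x[37])
  expect_error(resample_to_length(x, 1), "L must be")
})
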