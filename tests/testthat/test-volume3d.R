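test_that("phantoms voxelize to their closed-form ratio", {
  ph <- phantom_spec(c(40, 40, 40),
                     list(list(centre = c(0, 0, 0), semiaxes = c(20, 20, 20))),
                     pitch = 1)
  expect_equal(ph$true_ratio, 0.125)
  v <- make_phantom(ph)
  expect_equal(attr(v, "true_ratio"), 0.125)
  expect_equal(watercore_ratio(v), 0.125, tolerance = 0.01)

  # no watercore components
  empty <- make_phantom(phantom_spec(c(30, 25, 20), pitch = 2))
  expect_equal(attr(empty, "true_ratio"), 0)
  expect_equal(watercore_ratio(empty), 0)

  # refinement: voxel-count ratio strictly closer to truth at finer pitch
  err <- vapply(c(2, 1), function(p)
    abs(watercore_ratio(sphere_phantom(pitch = p)) - 0.125), numeric(1))
  expect_lt(err[2], err[1])

  expect_error(phantom_spec(c(10, 10, 10),
                            list(list(centre = c(8, 0, 0),
                                      semiaxes = c(5, 5, 5)))), "outside")
  expect_error(make_phantom(phantom_spec(
    c(40, 40, 40),
    list(list(centre = c(0, 0, 0), semiaxes = c(10, 10, 10)),
         list(centre = c(5, 0, 0), semiaxes = c(10, 10, 10))))), "overlap")
})

test_that("slice counts follow floor(depth / thickness)", {
  v <- sphere_phantom(pitch = 1)                  # 80 mm deep
  expect_length(slice_volume(v, 4.5)$fruit, 17)
  # 40 mm-tall volume at 4.5 mm -> floor(40 / 4.5) = 8 full slices
  ph40 <- make_phantom(phantom_spec(c(25, 25, 20), pitch = 1))
  expect_length(slice_volume(ph40, 4.5)$fruit, 8)
  expect_error(slice_volume(ph40, 30), "thinner")
})

test_that("slice -> extrude -> re-slice is idempotent", {
  v <- sphere_phantom(pitch = 1)
  st <- slice_volume(v, 4.5)
  v0 <- reconstruct(st, 0)
  st2 <- slice_volume(v0, 4.5)
  for (i in seq_along(st$fruit)) {
    expect_identical(st2$fruit[[i]], st$fruit[[i]] > 0)
    expect_identical(st2$watercore[[i]], st$watercore[[i]] > 0)
  }
})

test_that("mask interpolation fixed points, disc radii and errors", {
  m <- disc_mask(12)
  # identical endpoints: every intermediate equals the endpoint
  mids <- interpolate_masks(m, m, 3)
  expect_length(mids, 3)
  for (x in mids) expect_identical(x, m)
  expect_identical(interpolate_masks(m, m, 0), list())
  # concentric discs r = 10, 20 at t = 0.5 blend to a disc of radius 15
  mid <- interpolate_masks(disc_mask(10), disc_mask(20), 1)[[1]]
  expect_lt(abs(sqrt(sum(mid) / pi) - 15), 1)
  # nested inputs vary monotonically in t
  seq5 <- interpolate_masks(disc_mask(10), disc_mask(25), 5)
  areas <- vapply(seq5, sum, numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_error(interpolate_masks(disc_mask(5, 32), disc_mask(5, 64), 1),
               "dimension")
})

test_that("interpolation toward an empty slice closes the region", {
  m <- disc_mask(12)
  none <- matrix(FALSE, nrow(m), ncol(m))
  mids <- interpolate_masks(m, none, 5)
  areas <- vapply(mids, sum, numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_equal(areas[5], 0)          # closed before reaching the empty end
  expect_true(all(vapply(interpolate_masks(none, none, 2), function(x)
    !any(x), logical(1))))
})

test_that("reconstruction preserves containment and handles empty channels", {
  v <- make_phantom(phantom_spec(
    c(30, 30, 30), list(list(centre = c(5, 0, 4), semiaxes = c(12, 10, 11))),
    pitch = 1))
  st <- slice_volume(v, 4.5)
  for (n in c(0, 3)) {
    r <- reconstruct(st, n)
    expect_false(any(r$watercore & !r$fruit))
    expect_equal(sum(r$layer_thickness),
                 length(st$fruit) * st$thickness, tolerance = 1e-9)
  }
  # an all-empty watercore stack reconstructs to zero watercore volume
  empty <- make_phantom(phantom_spec(c(30, 30, 30), pitch = 1))
  vol <- model_volumes(reconstruct(slice_volume(empty, 4.5), 2))
  expect_equal(unname(vol["watercore"]), 0)
})

test_that("watercore_ratio handles degenerate volumes", {
  a <- array(TRUE, c(4, 4, 3))
  expect_warning(r <- watercore_ratio(volume_model(a, a, 1, 1)), "degenerate")
  expect_equal(r, 1)
  none <- array(FALSE, c(4, 4, 3))
  expect_equal(watercore_ratio(volume_model(a, none, 1, 1)), 0)
  expect_error(watercore_ratio(volume_model(none, none, 1, 1)), "empty fruit")
  expect_error(volume_model(none, a, 1, 1), "outside")
})

test_that("grade_from_ratio applies the documented boundary convention", {
  expect_identical(grade_from_ratio(c(0, 0.029, 0.03, 0.06, 0.061)),
                   c(1L, 2L, 3L, 3L, 4L))
  expect_identical(grade_from_ratio(0.0005), 1L)   # trace amounts are normal
  expect_identical(grade_from_ratio(0.045), 3L)
  expect_identical(grade_from_ratio(0.060001), 4L)
  expect_error(grade_from_ratio(-0.01), "ratio")
  expect_error(grade_from_ratio(1), "ratio")
})

test_that("mask stacks round-trip through PGM + manifest", {
  v <- make_phantom(phantom_spec(
    c(20, 20, 15), list(list(centre = c(0, 0, 0), semiaxes = c(8, 8, 7))),
    pitch = 1))
  st <- slice_volume(v, 4.5)
  dir <- file.path(tempdir(), "stack")
  write_mask_stack(st, dir)
  back <- read_mask_stack(dir)
  expect_equal(length(back$fruit), length(st$fruit))
  expect_equal(back$thickness, st$thickness)
  expect_equal(back$pixel_size, st$pixel_size)
  for (i in seq_along(st$fruit)) {
    expect_identical(back$fruit[[i]], st$fruit[[i]] > 0)
    expect_identical(back$watercore[[i]], st$watercore[[i]] > 0)
  }
  q <- quantify_stack(back, 2)
  expect_true(q$ratio > 0 && q$ratio < 1)
  expect_true(q$level %in% 1:4)
})
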