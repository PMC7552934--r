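test_that("liquid norm samples the central vitreous and averages symmetrically", {
  vol <- tiny_volume(8, 8, 16, fill = 12)
  expect_identical(compute_liquid_norm(vol), 12)
  # a volume whose top quarter (vitreous) is 10 and rest 200
  v <- array(200, c(8, 8, 16)); v[, , 1:4] <- 10
  expect_identical(compute_liquid_norm(v), 10)
  # permuting slices along the averaged axes leaves the sampled plane intact
  v2 <- v[c(2, 1, 3:8), , ]
  expect_identical(compute_liquid_norm(v2), compute_liquid_norm(v))
})

test_that("normalization maps the liquid norm to 0 and the maximum to 255", {
  # identity when the input already spans 0-255 and the norm is 0
  v <- array(c(0, 17, 128, 255), c(1, 2, 2))
  expect_identical(normalize_volume(v, 0), v)
  # the stated linear map: v >= LN -> 255 (v - LN) / (vmax - LN)
  v2 <- array(c(10, 100, 255, 255), c(1, 2, 2))
  out <- normalize_volume(v2, 50)
  expect_identical(out[1, 1, 1], 0)
  expect_equal(out[1, 2, 1], 255 * 50 / 205)
  expect_identical(out[1, 1, 2], 255)
  # range contract on random volumes
  set.seed(3)
  r <- array(sample(30:255, 60, TRUE), c(3, 4, 5))
  o <- normalize_volume(r, 30)
  expect_true(min(o) >= 0 && max(o) == 255)
  expect_error(normalize_volume(array(5, c(2, 2, 2)), 10), "degenerate")
})

test_that("median blur equals the sort-based oracle and removes salt noise", {
  set.seed(4)
  sl <- matrix(sample(0:255, 49, TRUE), 7, 7)
  expect_identical(median_filter(sl, 3), median_brute(sl, 3))
  expect_identical(median_filter(sl, 5), median_brute(sl, 5))
  # constant slice unchanged; an isolated bright voxel is removed
  expect_identical(median_filter(matrix(7, 5, 5), 3), matrix(7, 5, 5))
  salt <- matrix(0, 9, 9); salt[5, 5] <- 255
  expect_identical(median_filter(salt, 3), matrix(0, 9, 9))
  # per-slice application on volumes
  v <- array(sample(0:255, 3 * 7 * 7, TRUE) + 0, c(3, 7, 7))
  mb <- median_blur(v, 3)
  for (b in 1:3) expect_identical(mb[b, , ], median_brute(v[b, , ], 3))
})

test_that("Niblack matches the brute-force circular-window oracle bit-exactly", {
  set.seed(5)
  for (n in c(15, 31)) {
    sl <- matrix(sample(0:255, n * n, TRUE), n, n)
    for (r in c(1, 3, 20)) {
      expect_identical(niblack_binarize(sl, k = 0.2, radius = r),
                       niblack_brute(sl, r, 0.2))
    }
  }
})

test_that("Niblack degenerate and invariance properties hold", {
  # constant slice: sigma = 0, T = c, nothing strictly above -> all 0
  expect_identical(niblack_binarize(matrix(80, 12, 12), k = 0.2, radius = 3),
                   matrix(0L, 12, 12))
  # invariance under positive scaling (T scales with the data)
  set.seed(6)
  sl <- matrix(sample(0:200, 225, TRUE), 15, 15)
  expect_identical(niblack_binarize(sl, k = 0.2, radius = 4),
                   niblack_binarize(sl * 1.25, k = 0.2, radius = 4))
  # a two-valued slice: boundary pixels classified by sign of v - m - k*sigma
  two <- cbind(matrix(50, 10, 5), matrix(200, 10, 5))
  expect_identical(niblack_binarize(two, k = 0.2, radius = 8),
                   niblack_brute(two, 8, 0.2))
})

test_that("binarize_volume composes the stages deterministically", {
  ph <- default_phantom()
  b1 <- binarize_volume(ph$volume)
  b2 <- binarize_volume(ph$volume)
  expect_identical(b1$binary, b2$binary)
  expect_identical(dim(b1$binary), dim(ph$volume$intensities))
  expect_true(b1$params$liquid_norm >= 0 && b1$params$liquid_norm <= 255)
})

test_that("voxel-level lumen recovery on the default phantom reaches 90% balanced accuracy", {
  ph <- default_phantom()
  bin <- binarize_volume(ph$volume)
  roi <- roi_from_surfaces(ph$surfaces, ph$geometry)
  b <- bin$binary; m <- roi$mask; lum <- ph$lumen_mask
  sens <- sum(b == 0 & lum & m) / sum(lum & m)
  spec <- sum(b == 1 & !lum & m) / sum(!lum & m)
  expect_gte((sens + spec) / 2, 0.90)
})
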