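test_that("lateral pixel scale follows the magnification formula", {
  g <- scan_geometry(1024, 1024, 1536)
  # hand evaluation: (24.83 - 1.82) * 0.6981317 / (1024 * 1.336)
  expect_equal(lateral_pixel_scale(24.83, g), 0.01174215, tolerance = 1e-6)
  # proportionality: doubling the pixel count halves the scale exactly
  expect_identical(lateral_pixel_scale(24.83, g, d_p = 2048) * 2,
                   lateral_pixel_scale(24.83, g, d_p = 1024))
  # strictly increasing in eye length
  expect_true(lateral_pixel_scale(26, g) > lateral_pixel_scale(24, g))
  expect_error(lateral_pixel_scale(1.82, g), "must exceed")
})

test_that("axial conversion factor is the depth ratio", {
  expect_identical(axial_conversion_factor(scan_geometry(4, 4, 1536)), 1.953125)
  expect_identical(axial_conversion_factor(scan_geometry(4, 4, 1500)), 2)
  g <- scan_geometry(4, 4, 1536, depth_um = 3000)
  expect_identical(axial_conversion_factor(g) * g$depth_px, g$depth_um)
})

test_that("grid masks partition the frame and respect the ONH exclusion", {
  g <- scan_geometry(64, 128, 256)
  onh <- onh_circle(20, 100, 6)
  grid <- build_grid(c(64, 128), lateral_pixel_scales(24.83, g),
                     eye = "OD", onh = onh)
  # pairwise disjoint and consistent with the label map
  stack <- Reduce(`+`, lapply(grid$region_masks, as.numeric))
  expect_true(all(stack <= 1))
  expect_true(all((stack == 1) == (grid$label_map >= 1 & grid$label_map <= 13)))
  # every pixel counted exactly once: regions + ONH + outside
  expect_identical(sum(stack == 1) + sum(grid$onh_mask) +
                     sum(grid$label_map == 0), length(grid$label_map))
  # ONH removed from every region
  for (m in grid$region_masks) expect_false(any(m & grid$onh_mask))
  # fovea pixel is central
  fc <- round(grid$fovea_center)
  expect_identical(grid$label_map[fc[1], fc[2]], 1L)
})

test_that("mask areas match the analytic ring-sector areas within 2%", {
  p_mm <- 10 / 220   # 10 mm disc across a 220 px frame, isotropic
  grid <- build_grid(c(221, 221), p_mm, eye = "OD")
  radii_px <- grid$ring_radii_mm / p_mm
  # central disc
  expect_equal(sum(grid$region_masks$central), pi * radii_px[1]^2,
               tolerance = 0.02)
  # each annulus quadrant
  for (k in 1:3) {
    analytic <- pi * (radii_px[k + 1]^2 - radii_px[k]^2) / 4
    ring <- c("inner", "outer", "extended")[k]
    for (s in c("superior", "inferior", "temporal", "nasal"))
      expect_equal(sum(grid$region_masks[[paste(ring, s, sep = "_")]]),
                   analytic, tolerance = 0.02)
  }
})

test_that("OD and OS grids are mirror images across the vertical meridian", {
  grid_od <- build_grid(c(61, 61), 0.17, eye = "OD")
  grid_os <- build_grid(c(61, 61), 0.17, eye = "OS")
  flip <- function(m) m[, ncol(m):1]
  for (nm in etdrs_region_names())
    expect_identical(grid_od$region_masks[[nm]],
                     flip(grid_os$region_masks[[nm]]))
  # nasal sectors sit on opposite sides of the two label maps
  expect_gt(mean(col(grid_od$label_map)[grid_od$region_masks$inner_nasal]), 31)
  expect_lt(mean(col(grid_os$label_map)[grid_os$region_masks$inner_nasal]), 31)
  expect_false(grid_od$truncated)
})

test_that("grid pixel radii shrink as the eye lengthens", {
  g <- scan_geometry(64, 64, 256)
  r_px <- function(ael) 5 / lateral_pixel_scale(ael, g, 64)
  expect_true(r_px(26) < r_px(24))
})

test_that("ONH circle construction and mask follow the pixel-centre rule", {
  m <- onh_mask_from_circle(onh_circle(5, 5, 0.5), c(9, 9))
  expect_identical(which(m), which(matrix(seq_len(81), 9, 9) == 41))  # centre only
  circ <- onh_circle_from_diameter(c(1, 1), c(1, 11))
  expect_equal(circ$center_bscan, 1)
  expect_equal(circ$center_ascan, 6)
  expect_equal(circ$radius_px, 5)
})

test_that("a grid exceeding the frame warns and sets the truncation flag", {
  expect_warning(grid <- build_grid(c(32, 32), 0.2, eye = "OD"), "clipped")
  expect_true(grid$truncated)
  g2 <- build_grid(c(221, 221), 10 / 220, eye = "OD")
  expect_false(g2$truncated)
})

test_that("the grid label map exports as TIFF with JSON metadata", {
  grid <- build_grid(c(61, 61), 0.2, eye = "OD", onh = onh_circle(30, 55, 4))
  p <- tempfile(fileext = ".tif")
  write_grid_labels(grid, p)
  lab <- round(tiff::readTIFF(p) * 255)
  expect_identical(unname(lab), unname(grid$label_map + 0))
  meta <- jsonlite::read_json(sub("\\.tif$", ".json", p))
  expect_identical(meta$labels$onh, 14L)
  unlink(c(p, sub("\\.tif$", ".json", p)))
})
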