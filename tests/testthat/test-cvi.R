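test_that("the ROI volume expands surfaces into half-open depth runs", {
  g <- scan_geometry(2, 2, 10)
  s <- segmentation_surfaces(matrix(3, 2, 2), matrix(2, 2, 2), 10)
  roi <- roi_from_surfaces(s, g)
  # depths just below the RPE boundary at 3 px: voxels 4 and 5 (1-based)
  expect_identical(which(roi$mask[1, 1, ]), c(4L, 5L))
  # zero thickness -> all-false column; conservation of voxel counts
  s2 <- segmentation_surfaces(matrix(3, 2, 2), matrix(c(2, 0, 1.4, 2.6), 2, 2), 10)
  roi2 <- roi_from_surfaces(s2, g)
  expect_false(any(roi2$mask[2, 1, ]))
  expect_identical(sum(roi2$mask), as.integer(sum(floor(s2$thickness_px + 0.5))))
})

test_that("column CVI implements n_v / n_roi x 100 with NA for empty columns", {
  g <- scan_geometry(1, 3, 12)
  s <- segmentation_surfaces(matrix(1, 1, 3), matrix(c(10, 10, 0), 1, 3), 12)
  roi <- roi_from_surfaces(s, g)
  bin <- array(1L, c(1, 3, 12))
  bin[1, 1, 2:5] <- 0L           # 4 lumen voxels of 10
  bin[1, 2, ] <- 0L              # all lumen
  col <- column_cvi(bin, roi)
  expect_equal(col$cvi[1, 1], 40)
  expect_equal(col$cvi[1, 2], 100)
  expect_true(is.na(col$cvi[1, 3]))
  expect_error(column_cvi(array(1L, c(1, 3, 11)), roi), "does not match")
})

test_that("region CVI is the ROI-weighted mean of column CVIs and conserves counts", {
  ph <- default_phantom()
  bin <- binarize_volume(ph$volume)
  roi <- roi_from_surfaces(ph$surfaces, ph$geometry)
  col <- column_cvi(bin, roi)
  reg <- region_cvi(bin, roi, ph$grid)
  for (i in c(1, 5, 13)) {
    m <- ph$grid$region_masks[[reg$region[i]]]
    w <- col$n_roi[m]
    expect_equal(reg$cvi_pct[i], sum(col$cvi[m] * w, na.rm = TRUE) / sum(w))
    expect_true(reg$cvi_pct[i] >= min(col$cvi[m], na.rm = TRUE) &&
                reg$cvi_pct[i] <= max(col$cvi[m], na.rm = TRUE))
  }
  # conservation: regions + ONH + outside = all ROI voxels, exactly
  onh_nroi <- sum(col$n_roi[ph$grid$onh_mask])
  outside <- sum(col$n_roi[ph$grid$label_map == 0])
  expect_identical(sum(reg$n_roi) + onh_nroi + outside,
                   as.numeric(sum(roi$mask)))
})

test_that("masking out an ONH circle removes exactly the ROI voxels under it", {
  ph <- default_phantom()
  roi <- roi_from_surfaces(ph$surfaces, ph$geometry)
  bin <- 1L - ph$lumen_mask
  grid0 <- ph$grid   # no ONH
  onh <- onh_circle(22, 90, 7)
  grid1 <- build_grid(dim(grid0$label_map), grid0$pixel_scale_mm,
                      eye = "OD", onh = onh)
  reg0 <- region_cvi(bin, roi, grid0)
  reg1 <- region_cvi(bin, roi, grid1)
  # brute-force recount of ROI voxels under the circle and inside regions
  under <- onh_mask_from_circle(onh, dim(grid0$label_map)) &
    grid0$label_map >= 1 & grid0$label_map <= 13
  n_roi_map <- rowSums(roi$mask, dims = 2)
  expect_identical(sum(reg0$n_roi) - sum(reg1$n_roi), sum(n_roi_map[under]))
})

test_that("regional thickness converts pixel means with the axial factor", {
  g <- scan_geometry(64, 128, 1536)
  s <- segmentation_surfaces(matrix(100, 64, 128), matrix(160, 64, 128), 1536)
  grid <- build_grid(c(64, 128), lateral_pixel_scales(24.83, g), eye = "OD")
  cht <- region_thickness(s, grid, g)
  expect_equal(cht$cht_um, rep(160 * 1.953125, 13))
  expect_equal(cht$cht_um, rep(312.5, 13))
  # halving the depth sampling doubles the factor and the micrometre value
  g2 <- scan_geometry(64, 128, 768)
  s2 <- segmentation_surfaces(matrix(100, 64, 128), matrix(160, 64, 128), 768)
  expect_equal(region_thickness(s2, grid, g2)$cht_um, cht$cht_um * 2)
})

test_that("render_maps writes the four panels with whitened ONH", {
  ph <- default_phantom()
  grid <- build_grid(dim(ph$grid$label_map), ph$grid$pixel_scale_mm,
                     eye = "OD", onh = onh_circle(22, 90, 7))
  roi <- roi_from_surfaces(ph$surfaces, ph$geometry)
  res <- cvi_result(1L - ph$lumen_mask, roi, ph$surfaces, grid, ph$geometry)
  out <- tempfile()
  paths <- render_maps(res, grid, ph$surfaces, ph$geometry, out)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  overlay <- png::readPNG(paths[4])
  expect_true(all(overlay[grid$onh_mask] == 1))
  unlink(out, recursive = TRUE)
})
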