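#' Choroidal region-of-interest volume from segmentation surfaces
#'
#' Expands the per-column RPE depth and choroidal thickness into a 3D
#' boolean mask that is true between the RPE and the choroidal-scleral
#' interface. Surface values are depths in pixels from the top edge of the
#' image; fractional values are rounded half-up, and column `[b, a]` is
#' true for the `round(thickness)` voxels starting just below depth
#' `round(rpe)`. Columns with zero thickness are all false.
#'
#' @param surfaces a [segmentation_surfaces()].
#' @param geometry a [scan_geometry()]; provides the depth extent.
#' @return an object of class `roi_volume`: list with `mask` (logical
#'   `[bscan, ascan, depth]` array) and `n_roi` (en-face matrix of ROI
#'   voxel counts per column).
#' @export
roi_from_surfaces <- function(surfaces, geometry) {
  stopifnot(inherits(surfaces, "segmentation_surfaces"),
            inherits(geometry, "scan_geometry"))
  nb <- nrow(surfaces$rpe_depth_px); na <- ncol(surfaces$rpe_depth_px)
  nz <- geometry$depth_px
  top <- round_half_up(surfaces$rpe_depth_px)       # last voxel above the ROI
  thick <- round_half_up(surfaces$thickness_px)
  if (any(top + thick > nz))
    stop("rounded choroidal-scleral interface exceeds scan depth")
  z <- array(rep(seq_len(nz), each = nb * na), c(nb, na, nz))
  top3 <- array(top, c(nb, na, nz))
  thick3 <- array(thick, c(nb, na, nz))
  mask <- z > top3 & z <= top3 + thick3
  structure(list(mask = mask, n_roi = matrix(thick, nb, na)),
            class = "roi_volume")
}

#' Per-column choroidal vascularity index
#'
#' For each A-scan column, counts the lumen voxels (binary label 0) inside
#' the choroidal ROI, `n_v`, and the total ROI voxels, `n_roi`, and
#' returns `CVI_col = n_v / n_roi * 100`. Columns without ROI voxels are
#' `NA`, never 0/0.
#'
#' @param binary a [binarize_volume()] result or 0/1 array (1 = stroma).
#' @param roi a [roi_from_surfaces()] result.
#' @return list with en-face matrices `cvi` (percent, `NA` where
#'   `n_roi == 0`), `n_v` and `n_roi`.
#' @export
column_cvi <- function(binary, roi) {
  b <- if (inherits(binary, "binary_volume")) binary$binary else binary
  stopifnot(inherits(roi, "roi_volume"))
  if (!all(dim(b) == dim(roi$mask)))
    stop(sprintf("binary volume shape (%s) does not match ROI shape (%s)",
                 paste(dim(b), collapse = "x"),
                 paste(dim(roi$mask), collapse = "x")))
  n_v <- rowSums(roi$mask & b == 0L, dims = 2)
  n_roi <- rowSums(roi$mask, dims = 2)
  cvi <- ifelse(n_roi > 0, 100 * n_v / n_roi, NA_real_)
  list(cvi = cvi, n_v = n_v, n_roi = n_roi)
}

#' Regional choroidal vascularity index over the ETDRS grid
#'
#' Sums lumen and ROI voxel counts over the in-region, non-ONH columns of
#' each grid region: `CVI_reg = N_v / N_roi * 100`. Regions whose columns
#' contain no ROI voxels get `NA`.
#'
#' @param binary a [binarize_volume()] result or 0/1 array.
#' @param roi a [roi_from_surfaces()] result.
#' @param grid an [build_grid()] result with matching en-face shape.
#' @return data frame with columns `region`, `n_v`, `n_roi`, `cvi_pct`.
#' @export
region_cvi <- function(binary, roi, grid) {
  stopifnot(inherits(grid, "etdrs_grid"))
  col <- column_cvi(binary, roi)
  if (!all(dim(grid$label_map) == dim(col$n_roi)))
    stop("grid en-face shape does not match the volume")
  regions <- etdrs_region_names()
  n_v <- n_roi <- numeric(13)
  for (i in seq_along(regions)) {
    m <- grid$region_masks[[regions[i]]]
    n_v[i] <- sum(col$n_v[m])
    n_roi[i] <- sum(col$n_roi[m])
  }
  cvi <- ifelse(n_roi > 0, 100 * n_v / n_roi, NA_real_)
  if (any(n_roi == 0))
    message("regions without ROI voxels: ",
            paste(regions[n_roi == 0], collapse = ", "))
  data.frame(region = regions, n_v = n_v, n_roi = n_roi, cvi_pct = cvi,
             stringsAsFactors = FALSE)
}

#' Regional choroidal thickness over the ETDRS grid
#'
#' Mean of the per-column choroidal thickness over the in-region, non-ONH
#' columns of each region, converted from pixels to micrometres with the
#' axial conversion factor `depth_um / depth_px`.
#'
#' @param surfaces a [segmentation_surfaces()].
#' @param grid an [build_grid()] result.
#' @param geometry a [scan_geometry()].
#' @return data frame with columns `region`, `n_columns`, `cht_um` (`NA`
#'   for empty regions).
#' @export
region_thickness <- function(surfaces, grid, geometry) {
  stopifnot(inherits(surfaces, "segmentation_surfaces"),
            inherits(grid, "etdrs_grid"),
            inherits(geometry, "scan_geometry"))
  if (!all(dim(grid$label_map) == dim(surfaces$thickness_px)))
    stop("grid en-face shape does not match the surfaces")
  fac <- axial_conversion_factor(geometry)
  regions <- etdrs_region_names()
  n_col <- integer(13); cht <- numeric(13)
  for (i in seq_along(regions)) {
    m <- grid$region_masks[[regions[i]]]
    n_col[i] <- sum(m)
    cht[i] <- if (n_col[i] > 0) mean(surfaces$thickness_px[m]) * fac else NA_real_
  }
  data.frame(region = regions, n_columns = n_col, cht_um = cht,
             stringsAsFactors = FALSE)
}

#' Full CVI/ChT result for one scan
#'
#' Convenience wrapper combining the column maps with the regional tables.
#'
#' @inheritParams region_cvi
#' @param surfaces a [segmentation_surfaces()].
#' @param geometry a [scan_geometry()].
#' @return an object of class `cvi_result`: list with `column_cvi_map`,
#'   `column_n_v`, `column_n_roi` (en-face matrices) and `regions` (data
#'   frame: `region`, `cht_um`, `cvi_pct`, `n_v`, `n_roi`, `n_columns`,
#'   `truncated`).
#' @export
cvi_result <- function(binary, roi, surfaces, grid, geometry) {
  col <- column_cvi(binary, roi)
  reg_cvi <- region_cvi(binary, roi, grid)
  reg_cht <- region_thickness(surfaces, grid, geometry)
  regions <- data.frame(region = reg_cvi$region,
                        cht_um = reg_cht$cht_um,
                        cvi_pct = reg_cvi$cvi_pct,
                        n_v = reg_cvi$n_v, n_roi = reg_cvi$n_roi,
                        n_columns = reg_cht$n_columns,
                        truncated = grid$truncated,
                        stringsAsFactors = FALSE)
  structure(list(column_cvi_map = col$cvi, column_n_v = col$n_v,
                 column_n_roi = col$n_roi, regions = regions),
            class = "cvi_result")
}

#' @export
print.cvi_result <- function(x, ...) {
  cat("regional choroidal metrics:\n")
  print(x$regions, digits = 4)
  invisible(x)
}

# map a matrix to a grayscale [0,1] image, NA -> 0
.to_gray <- function(m, lo = min(m, na.rm = TRUE), hi = max(m, na.rm = TRUE)) {
  g <- (m - lo) / max(hi - lo, .Machine$double.eps)
  g[!is.finite(g)] <- 0
  pmin(pmax(g, 0), 1)
}

#' Render en-face result maps
#'
#' Writes four grayscale PNG panels: (a) the choroidal-thickness ROI map
#' in micrometres, (b) the per-column lumen voxel count, (c) the CVI map,
#' and (d) the CVI map with the ETDRS ring/diagonal overlay, with the ONH
#' exclusion rendered white.
#'
#' @param result a [cvi_result()].
#' @param grid an [build_grid()] result.
#' @param surfaces a [segmentation_surfaces()].
#' @param geometry a [scan_geometry()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the four file paths.
#' @export
render_maps <- function(result, grid, surfaces, geometry, out_dir) {
  stopifnot(inherits(result, "cvi_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fac <- axial_conversion_factor(geometry)
  panels <- list(
    cht_roi_map = .to_gray(surfaces$thickness_px * fac),
    lumen_count_map = .to_gray(result$column_n_v),
    cvi_map = .to_gray(result$column_cvi_map, 0, 100)
  )
  overlay <- panels$cvi_map
  # ring circles at the magnification-corrected pixel radii r_mm / p_mm
  sh <- dim(grid$label_map)
  dy <- (seq_len(sh[1]) - grid$fovea_center[1]) * grid$pixel_scale_mm[1]
  dx <- (seq_len(sh[2]) - grid$fovea_center[2]) * grid$pixel_scale_mm[2]
  r_mm <- sqrt(outer(dy^2, dx^2, `+`))
  px_mm <- min(grid$pixel_scale_mm)
  for (r in grid$ring_radii_mm) overlay[abs(r_mm - r) <= px_mm / 2] <- 1
  ang <- atan2(outer(dy, rep(1, sh[2])), outer(rep(1, sh[1]), dx)) * 180 / pi
  diag_px <- abs(abs(ang) %% 90 - 45) <= 60 * px_mm / pmax(r_mm, px_mm)
  overlay[diag_px & r_mm >= grid$ring_radii_mm[1] &
            r_mm < grid$ring_radii_mm[4]] <- 1
  overlay[grid$onh_mask] <- 1  # ONH whitened
  panels$cvi_map_grid <- overlay
  paths <- character(0)
  for (nm in names(panels)) {
    p <- file.path(out_dir, paste0(nm, ".png"))
    png::writePNG(panels[[nm]], p)
    paths <- c(paths, p)
  }
  paths
}
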