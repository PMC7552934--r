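is_tiff_path <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)
is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read an OCT volume scan
#'
#' Reads a multi-page TIFF (one grayscale 8-bit page per B-scan; page rows
#' are depth with the vitreous at the top, page columns are A-scans) or a
#' NIfTI-1 file (stored directly as `[bscan, ascan, depth]`), validates
#' the dimensions against the geometry, and returns a [volume_scan()].
#' Intensities are preserved bit-exactly.
#'
#' @param path input file (`.tif`/`.tiff`, `.nii`, `.nii.gz`).
#' @param geometry a [scan_geometry()] describing the expected shape.
#' @param axial_eye_length_mm,eye per-eye metadata, see [volume_scan()].
#' @param allow_rescale if `TRUE`, inputs with values outside [0, 255]
#'   are linearly rescaled to 8-bit range; otherwise they are refused.
#' @return a [volume_scan()].
#' @export
read_volume <- function(path, geometry, axial_eye_length_mm,
                        eye = c("OD", "OS"), allow_rescale = FALSE) {
  eye <- match.arg(eye)
  stopifnot(inherits(geometry, "scan_geometry"))
  want <- c(geometry$n_bscans, geometry$n_ascans, geometry$depth_px)
  if (is_tiff_path(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    found <- c(length(pages), ncol(pages[[1]]), nrow(pages[[1]]))
    if (!all(found == want))
      stop(sprintf("volume format error: expected %s (bscans x ascans x depth), found %s in %s",
                   paste(want, collapse = "x"), paste(found, collapse = "x"), path))
    vol <- array(0, want)
    for (b in seq_along(pages)) vol[b, , ] <- t(pages[[b]])
  } else if (is_nifti_path(path)) {
    vol <- as.array(RNifti::readNifti(path))
    vol <- array(as.vector(vol), dim(vol))
    if (length(dim(vol)) != 3 || !all(dim(vol) == want))
      stop(sprintf("volume format error: expected %s (bscans x ascans x depth), found %s in %s",
                   paste(want, collapse = "x"), paste(dim(vol), collapse = "x"), path))
  } else stop("unsupported volume format (expected TIFF or NIfTI): ", path)
  if (min(vol) < 0 || max(vol) > 255) {
    if (!allow_rescale)
      stop("input is not 8-bit (values outside [0, 255]); pass allow_rescale = TRUE to rescale")
    vol <- round(255 * (vol - min(vol)) / (max(vol) - min(vol)))
  }
  volume_scan(vol, geometry, axial_eye_length_mm, eye)
}

#' Write an OCT volume scan
#'
#' Inverse of [read_volume()]: multi-page 8-bit grayscale TIFF or NIfTI-1,
#' chosen by file extension. Round-trips are lossless for 8-bit volumes.
#'
#' @param volume a [volume_scan()] or 3D array with values in [0, 255].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  v <- as_intensity_array(volume)
  if (is_tiff_path(path)) {
    pages <- lapply(seq_len(dim(v)[1]), function(b) t(v[b, , ]) / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else if (is_nifti_path(path)) {
    RNifti::writeNifti(RNifti::asNifti(v, datatype = "uint8"), path)
  } else stop("unsupported volume format (expected TIFF or NIfTI): ", path)
  invisible(path)
}

# Surface TIFFs written by this package store pixel values scaled by
# 2^-16 (libtiff floats are confined to [0, 1]); external float TIFFs in
# raw pixel units are detected by their range and read as-is.
.surface_tiff_scale <- 65536

read_surface_file <- function(path) {
  if (is_tiff_path(path)) {
    m <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(m)) != 2) stop("surface TIFF must be single-channel: ", path)
    if (max(m) <= 1) m * .surface_tiff_scale else m
  } else {
    as.matrix(read.csv(path, header = FALSE))
  }
}

#' Read segmentation surfaces
#'
#' Reads the RPE depth map and the choroidal thickness map (both in
#' pixels) from CSV (headerless numeric grid, RFC 4180) or single-page
#' 32-bit float TIFF, and returns a validated [segmentation_surfaces()]
#' with the derived choroidal-scleral interface.
#'
#' @param path_rpe,path_thickness input files; both must have the same
#'   en-face shape.
#' @param depth_px optional scan depth for CSI validation.
#' @return a [segmentation_surfaces()].
#' @export
read_surfaces <- function(path_rpe, path_thickness, depth_px = NULL) {
  rpe <- unname(read_surface_file(path_rpe))
  thick <- unname(read_surface_file(path_thickness))
  if (!all(dim(rpe) == dim(thick)))
    stop(sprintf("surface shape mismatch: RPE %s vs thickness %s",
                 paste(dim(rpe), collapse = "x"), paste(dim(thick), collapse = "x")))
  segmentation_surfaces(rpe, thick, depth_px)
}

#' Write a surface map
#'
#' @param m numeric matrix (pixel units).
#' @param path output path; `.csv` (full precision) or single-page
#'   `.tif` (32-bit samples, stored scaled by 2^-16 because libtiff
#'   values live in the unit interval; [read_surfaces()] reverses the
#'   scaling, with a quantization error below 2e-5 pixel).
#' @return invisibly, `path`.
#' @export
write_surface <- function(m, path) {
  if (is_tiff_path(path)) {
    tiff::writeTIFF(m / .surface_tiff_scale, path, bits.per.sample = 32L,
                    reduce = FALSE)
  } else {
    utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write pipeline results to a directory
#'
#' Writes the regional table as `regions.csv` (one row per ETDRS region:
#' `region_id`, `region_name`, `chT_um`, `CVI_pct`, `n_v`, `N_roi`,
#' `n_columns`, `truncated_flag`; empty regions keep `N_roi = 0` and `NA`
#' values), the en-face CVI and thickness maps as 32-bit float TIFF and
#' CSV, and echoes the run configuration as `config.json`. TIFF values
#' are confined to the unit interval, so the TIFF maps store CVI as a
#' fraction (0-1) and thickness as um scaled by 2^-16 (the same
#' convention as [write_surface()]), with `NA` as NaN; the CSV maps keep
#' the display units (percent, um).
#'
#' @param result a [cvi_result()].
#' @param out_dir output directory (created if needed).
#' @param surfaces optional [segmentation_surfaces()]; enables the
#'   thickness map export.
#' @param geometry optional [scan_geometry()] for the micrometre scaling
#'   of the thickness map.
#' @param config optional list echoed as JSON provenance.
#' @return invisibly, character vector of the files written.
#' @export
write_results <- function(result, out_dir, surfaces = NULL, geometry = NULL,
                          config = NULL) {
  stopifnot(inherits(result, "cvi_result"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  reg <- result$regions
  tab <- data.frame(region_id = seq_len(nrow(reg)), region_name = reg$region,
                    chT_um = reg$cht_um, CVI_pct = reg$cvi_pct,
                    n_v = reg$n_v, N_roi = reg$n_roi,
                    n_columns = reg$n_columns,
                    truncated_flag = reg$truncated)
  files <- file.path(out_dir, "regions.csv")
  write.csv(tab, files[1], row.names = FALSE)
  write_map <- function(m, stem, tiff_scale) {
    p_tif <- file.path(out_dir, paste0(stem, ".tif"))
    p_csv <- file.path(out_dir, paste0(stem, ".csv"))
    m_t <- m / tiff_scale
    m_t[is.na(m_t)] <- NaN
    if (any(m_t < 0 | m_t > 1, na.rm = TRUE))
      warning("map values outside the TIFF unit-interval range are clamped")
    # libtiff warns on the NaN missing-value markers; values are in range
    suppressWarnings(
      tiff::writeTIFF(m_t, p_tif, bits.per.sample = 32L, reduce = FALSE))
    utils::write.table(m, p_csv, sep = ",", row.names = FALSE, col.names = FALSE)
    c(p_tif, p_csv)
  }
  files <- c(files, write_map(result$column_cvi_map, "cvi_map", 100))
  if (!is.null(surfaces)) {
    fac <- if (is.null(geometry)) 1 else axial_conversion_factor(geometry)
    files <- c(files, write_map(surfaces$thickness_px * fac, "cht_map",
                                .surface_tiff_scale))
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config %||% list(), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, cfg_path))
}
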