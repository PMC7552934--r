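#' ETDRS region names
#'
#' The 13 regions of the extended ETDRS grid in reporting order: the
#' central field, then the inner (0.5-1.5 mm), outer (1.5-3 mm) and
#' extended (3-5 mm radius) rings, each split into superior, inferior,
#' temporal and nasal sectors.
#' @export
etdrs_region_names <- function() {
  rings <- c("inner", "outer", "extended")
  sects <- c("superior", "inferior", "temporal", "nasal")
  c("central", as.vector(t(outer(rings, sects, paste, sep = "_"))))
}

#' Axial pixel-to-micrometre conversion factor
#'
#' Ratio of the true scan depth to the digital image depth. For a 3000 um
#' depth sampled on 1536 pixels the factor is 1.953125 um per pixel.
#'
#' @param geometry a [scan_geometry()].
#' @return micrometres per depth pixel.
#' @export
axial_conversion_factor <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  geometry$depth_um / geometry$depth_px
}

#' Lateral pixel scale from axial eye length
#'
#' Lateral magnification correction: the physical length of one en-face
#' pixel is
#' \deqn{p_{mm} = (l_a - \Delta_{cp})\,\theta_{air} / (d_p\, n_B)}
#' where `l_a` is the axial eye length in mm, `Delta_cp` the distance from
#' cornea to the second principal plane (1.82 mm), `theta_air` the scan
#' angle in air in radians, `d_p` the en-face extent in pixels and `n_B`
#' the bulk refractive index (1.336).
#'
#' @param axial_eye_length_mm axial eye length in mm; must exceed
#'   `cornea_to_principal_mm`.
#' @param geometry a [scan_geometry()].
#' @param d_p en-face extent in pixels; defaults to the geometry's
#'   `en_face_extent_px`.
#' @return mm per en-face pixel (strictly positive).
#' @export
lateral_pixel_scale <- function(axial_eye_length_mm, geometry,
                                d_p = geometry$en_face_extent_px) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (axial_eye_length_mm <= geometry$cornea_to_principal_mm)
    stop(sprintf("axial eye length (%.2f mm) must exceed the cornea-principal-plane distance (%.2f mm)",
                 axial_eye_length_mm, geometry$cornea_to_principal_mm))
  theta <- geometry$scan_angle_deg * pi / 180
  (axial_eye_length_mm - geometry$cornea_to_principal_mm) * theta /
    (d_p * geometry$bulk_refractive_index)
}

#' Per-axis lateral pixel scales
#'
#' The raster is isometric in scan angle, so when the B-scan and A-scan
#' counts differ the two en-face axes have different pixel pitches. Returns
#' the mm-per-pixel scale for the B-scan (slow) and A-scan (fast) axes.
#'
#' @inheritParams lateral_pixel_scale
#' @return named numeric vector `c(bscan = ..., ascan = ...)`.
#' @export
lateral_pixel_scales <- function(axial_eye_length_mm, geometry) {
  c(bscan = lateral_pixel_scale(axial_eye_length_mm, geometry, geometry$n_bscans),
    ascan = lateral_pixel_scale(axial_eye_length_mm, geometry, geometry$n_ascans))
}

#' Optic nerve head mask from a circle
#'
#' Pixel-centre test: a pixel belongs to the mask when its centre lies at
#' distance <= radius from the circle centre.
#'
#' @param circle an [onh_circle()].
#' @param shape en-face dimensions `c(n_bscans, n_ascans)`.
#' @return logical `[bscan, ascan]` matrix.
#' @export
onh_mask_from_circle <- function(circle, shape) {
  stopifnot(inherits(circle, "onh_circle"), length(shape) == 2)
  db <- (seq_len(shape[1]) - circle$center_bscan)^2
  da <- (seq_len(shape[2]) - circle$center_ascan)^2
  outer(db, da, `+`) <= circle$radius_px^2
}

#' Build the magnification-corrected extended ETDRS grid
#'
#' Assigns every en-face pixel to at most one of 13 regions by the polar
#' coordinates of its centre relative to the fovea: concentric rings with
#' half-open radius bands `[r_in, r_out)` at the given mm radii, and
#' quadrant sectors split at the 45 degree diagonals with half-open angle
#' intervals so the partition is exact. Distances are measured in mm using
#' the per-axis pixel scale, so the grid is circular on the retina even
#' when the two en-face axes have different pitches. The temporal/nasal
#' assignment mirrors between right (OD) and left (OS) eyes: for OD the
#' nasal sectors lie at increasing A-scan index.
#'
#' @param shape en-face dimensions `c(n_bscans, n_ascans)`.
#' @param pixel_scale_mm mm per pixel; a scalar, or length-2
#'   `(bscan, ascan)` vector for anisotropic grids.
#' @param fovea_center en-face `(bscan, ascan)` coordinates of the fovea;
#'   defaults to the geometric scan centre (the acquisition protocol
#'   centres the volume on the fovea).
#' @param eye `"OD"` or `"OS"`.
#' @param ring_radii_mm the four ring radii in mm, strictly increasing
#'   (default 0.5, 1.5, 3.0, 5.0: central / inner / outer / extended).
#' @param onh optional [onh_circle()]; the ONH mask is removed from every
#'   region.
#' @return an object of class `etdrs_grid` with fields `region_masks`
#'   (named list of 13 disjoint logical matrices), `onh_mask`, `label_map`
#'   (0 outside, 1-13 regions, 14 ONH), `pixel_scale_mm`, `fovea_center`,
#'   `ring_radii_mm`, `eye` and `truncated` (TRUE when the outer ring
#'   exceeds the scanned frame and regions were clipped).
#' @export
build_grid <- function(shape, pixel_scale_mm, fovea_center = NULL,
                       eye = c("OD", "OS"),
                       ring_radii_mm = c(0.5, 1.5, 3.0, 5.0),
                       onh = NULL) {
  eye <- match.arg(eye)
  stopifnot(length(shape) == 2, all(shape >= 1))
  if (length(pixel_scale_mm) == 1) pixel_scale_mm <- rep(pixel_scale_mm, 2)
  if (any(pixel_scale_mm <= 0)) stop("`pixel_scale_mm` must be > 0")
  if (length(ring_radii_mm) != 4 || any(diff(ring_radii_mm) <= 0))
    stop("`ring_radii_mm` must be four strictly increasing radii")
  if (is.null(fovea_center)) fovea_center <- (shape + 1) / 2
  if (fovea_center[1] < 1 || fovea_center[1] > shape[1] ||
      fovea_center[2] < 1 || fovea_center[2] > shape[2])
    stop("fovea centre lies outside the en-face frame")

  dy <- (seq_len(shape[1]) - fovea_center[1]) * pixel_scale_mm[1]  # + = inferior
  dx <- (seq_len(shape[2]) - fovea_center[2]) * pixel_scale_mm[2]  # + = right
  # mirroring the horizontal coordinate for left eyes makes OD and OS
  # grids exact mirror images, including the half-open sector boundaries
  if (eye == "OS") dx <- -dx
  r_mm <- sqrt(outer(dy^2, dx^2, `+`))
  ang <- atan2(outer(dy, rep(1, shape[2])), outer(rep(1, shape[1]), dx)) * 180 / pi

  # ring index: 0 central, 1 inner, 2 outer, 3 extended, NA outside disc
  ring <- matrix(NA_integer_, shape[1], shape[2])
  bounds <- c(0, ring_radii_mm)
  for (i in 1:4) ring[r_mm >= bounds[i] & r_mm < bounds[i + 1]] <- i - 1L

  # quadrants split at the diagonals, half-open to keep the partition exact
  # angles: 0 = +x (right), 90 = +y (inferior, rows grow downward)
  sect <- matrix(NA_character_, shape[1], shape[2])
  sect[ang >= -45 & ang < 45] <- "right"
  sect[ang >= 45 & ang < 135] <- "inferior"
  sect[ang >= -135 & ang < -45] <- "superior"
  sect[is.na(sect)] <- "left"
  # in the (possibly mirrored) coordinate, +x is always nasal
  sect[sect == "right"] <- "nasal"
  sect[sect == "left"] <- "temporal"

  onh_mask <- if (is.null(onh)) matrix(FALSE, shape[1], shape[2])
              else onh_mask_from_circle(onh, shape)

  names13 <- etdrs_region_names()
  region_masks <- vector("list", 13)
  names(region_masks) <- names13
  region_masks[["central"]] <- !is.na(ring) & ring == 0L & !onh_mask
  rings <- c("inner", "outer", "extended")
  for (k in 1:3) for (s in c("superior", "inferior", "temporal", "nasal")) {
    nm <- paste(rings[k], s, sep = "_")
    region_masks[[nm]] <- !is.na(ring) & ring == k & sect == s & !onh_mask
  }

  # clipped when the 2*max-radius disc does not fit inside the frame
  r_out_px <- ring_radii_mm[4] / pixel_scale_mm
  truncated <- (fovea_center[1] - r_out_px[1] < 0.5) ||
               (fovea_center[1] + r_out_px[1] > shape[1] + 0.5) ||
               (fovea_center[2] - r_out_px[2] < 0.5) ||
               (fovea_center[2] + r_out_px[2] > shape[2] + 0.5)
  if (truncated)
    warning("extended ETDRS disc exceeds the scanned frame; regions clipped")

  label_map <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(names13)) label_map[region_masks[[i]]] <- i
  label_map[onh_mask] <- 14L

  structure(list(region_masks = region_masks, onh_mask = onh_mask,
                 label_map = label_map, pixel_scale_mm = pixel_scale_mm,
                 fovea_center = fovea_center, ring_radii_mm = ring_radii_mm,
                 eye = eye, truncated = truncated),
            class = "etdrs_grid")
}

#' @export
print.etdrs_grid <- function(x, ...) {
  cat(sprintf("extended ETDRS grid: %dx%d px, pixel scale %.5f x %.5f mm, eye %s%s\n",
              nrow(x$label_map), ncol(x$label_map),
              x$pixel_scale_mm[1], x$pixel_scale_mm[2], x$eye,
              if (x$truncated) " (clipped to frame)" else ""))
  invisible(x)
}

#' Export the grid as an indexed label map
#'
#' Writes a single-page TIFF whose integer labels are 0 outside the disc,
#' 1-13 for the regions (in [etdrs_region_names()] order) and 14 for the
#' ONH exclusion, plus a JSON sidecar with the region metadata.
#'
#' @param grid an [build_grid()] result.
#' @param path output TIFF path; the JSON sidecar gets extension `.json`.
#' @return invisibly, the paths written.
#' @export
write_grid_labels <- function(grid, path) {
  stopifnot(inherits(grid, "etdrs_grid"))
  tiff::writeTIFF(grid$label_map / 255, path, bits.per.sample = 8L)
  meta <- list(labels = c(list(outside = 0L),
                          as.list(setNames(1:13, etdrs_region_names())),
                          list(onh = 14L)),
               pixel_scale_mm = grid$pixel_scale_mm,
               fovea_center = grid$fovea_center,
               ring_radii_mm = grid$ring_radii_mm,
               eye = grid$eye, truncated = grid$truncated)
  jpath <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, jpath))
}
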