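#' Scan geometry of an OCT volume
#'
#' Describes the voxel grid and the optical constants needed for
#' magnification correction. The defaults correspond to a widefield
#' swept-source protocol: a 40 degree (in air) isometric raster with a
#' 3 mm (3000 um) imaging depth.
#'
#' @param n_bscans,n_ascans,depth_px voxel counts along the slow (B-scan),
#'   fast (A-scan) and depth axes.
#' @param depth_um physical scan depth in micrometres (default 3000).
#' @param scan_angle_deg scan angle in air, degrees (default 40).
#' @param cornea_to_principal_mm distance from cornea to the eye's second
#'   principal plane in mm (default 1.82).
#' @param bulk_refractive_index bulk refractive index of the ocular humors
#'   (default 1.336).
#' @param en_face_extent_px en-face extent in pixels used for lateral
#'   scaling; defaults to `n_ascans` (the within-B-scan axis).
#' @return an object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_bscans, n_ascans, depth_px,
                          depth_um = 3000, scan_angle_deg = 40,
                          cornea_to_principal_mm = 1.82,
                          bulk_refractive_index = 1.336,
                          en_face_extent_px = n_ascans) {
  counts <- c(n_bscans = n_bscans, n_ascans = n_ascans, depth_px = depth_px,
              en_face_extent_px = en_face_extent_px)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("voxel counts must be integers >= 1")
  if (depth_um <= 0) stop("`depth_um` must be > 0")
  if (scan_angle_deg <= 0 || scan_angle_deg >= 180)
    stop("`scan_angle_deg` must be in (0, 180)")
  if (bulk_refractive_index <= 1)
    stop("`bulk_refractive_index` must be > 1")
  structure(list(
    n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
    depth_px = as.integer(depth_px), depth_um = depth_um,
    scan_angle_deg = scan_angle_deg,
    cornea_to_principal_mm = cornea_to_principal_mm,
    bulk_refractive_index = bulk_refractive_index,
    en_face_extent_px = as.integer(en_face_extent_px)
  ), class = "scan_geometry")
}

#' An OCT volume scan with metadata
#'
#' @param intensities 3D numeric array indexed `[bscan, ascan, depth]`,
#'   8-bit unsigned values (0-255); depth index 1 is the vitreous side.
#' @param geometry a [scan_geometry()].
#' @param axial_eye_length_mm axial eye length in mm. Values outside the
#'   typical 23-27 mm adult range trigger a warning, not an error.
#' @param eye laterality, `"OD"` (right) or `"OS"` (left).
#' @return an object of class `volume_scan`.
#' @export
volume_scan <- function(intensities, geometry, axial_eye_length_mm,
                        eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  stopifnot(inherits(geometry, "scan_geometry"))
  d <- dim(intensities)
  want <- c(geometry$n_bscans, geometry$n_ascans, geometry$depth_px)
  if (length(d) != 3L || !all(d == want))
    stop(sprintf("volume shape (%s) does not match geometry (%s)",
                 paste(d, collapse = "x"), paste(want, collapse = "x")))
  if (min(intensities) < 0 || max(intensities) > 255)
    stop("intensities must lie in [0, 255] (8-bit unsigned)")
  if (!is.na(axial_eye_length_mm) &&
      (axial_eye_length_mm < 23 || axial_eye_length_mm > 27))
    warning(sprintf("axial eye length %.2f mm is outside the typical 23-27 mm range",
                    axial_eye_length_mm))
  structure(list(intensities = intensities, geometry = geometry,
                 axial_eye_length_mm = axial_eye_length_mm, eye = eye),
            class = "volume_scan")
}

#' @export
print.volume_scan <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("OCT volume scan: %d B-scans x %d A-scans x %d depth px, %s, AEL %.2f mm\n",
              g$n_bscans, g$n_ascans, g$depth_px, x$eye, x$axial_eye_length_mm))
  invisible(x)
}

#' Choroidal segmentation surfaces
#'
#' Holds the RPE depth map and the choroidal thickness map, both
#' `[bscan, ascan]` matrices in pixel units measured from the top (vitreous
#' side) of the B-scan image. The choroidal-scleral interface (CSI) depth
#' is their elementwise sum and is computed here, never stored
#' independently, so `csi_depth_px - rpe_depth_px == thickness_px` holds
#' exactly.
#'
#' @param rpe_depth_px matrix of RPE (inner choroid boundary) depths, px.
#' @param thickness_px matrix of choroidal thicknesses, px; zero thickness
#'   marks columns without measurable choroid.
#' @param depth_px optional scan depth used to validate that the CSI stays
#'   inside the imaged depth range.
#' @return an object of class `segmentation_surfaces` with fields
#'   `rpe_depth_px`, `thickness_px` and the derived `csi_depth_px`.
#' @export
segmentation_surfaces <- function(rpe_depth_px, thickness_px, depth_px = NULL) {
  rpe_depth_px <- as.matrix(rpe_depth_px)
  thickness_px <- as.matrix(thickness_px)
  if (!all(dim(rpe_depth_px) == dim(thickness_px)))
    stop("RPE and thickness maps must have the same en-face shape")
  bad <- which(thickness_px < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative choroidal thickness at [bscan, ascan]: ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  if (any(rpe_depth_px < 0))
    stop("RPE depths must be >= 0")
  csi <- rpe_depth_px + thickness_px
  if (!is.null(depth_px)) {
    if (any(rpe_depth_px >= depth_px))
      stop("RPE depth at or beyond scan depth (", depth_px, " px)")
    bad <- which(csi > depth_px, arr.ind = TRUE)
    if (nrow(bad))
      stop("choroidal-scleral interface beyond scan depth at [bscan, ascan]: ",
           paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  }
  structure(list(rpe_depth_px = rpe_depth_px, thickness_px = thickness_px,
                 csi_depth_px = csi),
            class = "segmentation_surfaces")
}

#' Optic nerve head exclusion circle
#'
#' The ONH region suffers inherent segmentation errors and is excluded
#' from all regional statistics. The circle is given in en-face pixel
#' coordinates, either directly or via the two endpoints of a diameter.
#'
#' @param center_bscan,center_ascan en-face centre coordinates (pixels).
#' @param radius_px circle radius in pixels, > 0.
#' @return an object of class `onh_circle`.
#' @export
onh_circle <- function(center_bscan, center_ascan, radius_px) {
  if (radius_px <= 0) stop("`radius_px` must be > 0")
  structure(list(center_bscan = center_bscan, center_ascan = center_ascan,
                 radius_px = radius_px), class = "onh_circle")
}

#' @rdname onh_circle
#' @param p1,p2 length-2 vectors `(bscan, ascan)`: endpoints of a diameter.
#' @export
onh_circle_from_diameter <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  ctr <- (p1 + p2) / 2
  r <- sqrt(sum((p1 - p2)^2)) / 2
  onh_circle(ctr[1], ctr[2], r)
}
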