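#' Binarization parameters
#'
#' Parameters of the lumen/stroma binarization: the Niblack weight `k`
#' (default 0.2), the radius of the circular threshold window in pixels
#' (default 20), the median-blur window edge (default 3, must be odd), and
#' an optional override for the liquid norm (the vitreous baseline
#' intensity, normally estimated from the scan itself).
#'
#' @param niblack_k Niblack weight on the local standard deviation.
#' @param niblack_radius_px radius of the circular window, >= 1.
#' @param median_window odd edge length of the median-blur window.
#' @param liquid_norm optional fixed vitreous baseline in [0, 255]; `NULL`
#'   means estimate it with [compute_liquid_norm()].
#' @return an object of class `binarization_params`.
#' @export
binarization_params <- function(niblack_k = 0.2, niblack_radius_px = 20,
                                median_window = 3, liquid_norm = NULL) {
  if (niblack_radius_px < 1) stop("`niblack_radius_px` must be >= 1")
  if (median_window < 1 || median_window %% 2 == 0)
    stop("`median_window` must be an odd integer >= 1")
  if (!is.null(liquid_norm) && (liquid_norm < 0 || liquid_norm > 255))
    stop("`liquid_norm` must lie in [0, 255]")
  structure(list(niblack_k = niblack_k,
                 niblack_radius_px = as.integer(niblack_radius_px),
                 median_window = as.integer(median_window),
                 liquid_norm = liquid_norm),
            class = "binarization_params")
}

as_intensity_array <- function(volume) {
  if (inherits(volume, "volume_scan")) volume$intensities else volume
}

#' Estimate the vitreous baseline ("liquid norm")
#'
#' Samples the two central cross-sectional planes of the volume - the
#' central B-scan and the central A-scan plane - at 50% of the slice width
#' and 75% of the slice height measured from the image bottom (25% from
#' the top, i.e. the vitreous side), and averages the sampled voxels. The
#' result quantifies the grayscale value of typical fluid and anchors the
#' intensity normalization. The position cannot be verified to lie in the
#' vitreous; callers may override via
#' [binarization_params()]`$liquid_norm`.
#'
#' @param volume a [volume_scan()] or 3D `[bscan, ascan, depth]` array.
#' @return scalar intensity in [0, 255].
#' @export
compute_liquid_norm <- function(volume) {
  v <- as_intensity_array(volume)
  d <- dim(v)
  if (is.null(d) || length(d) != 3 || any(d < 1)) stop("volume must be a non-empty 3D array")
  z <- max(1L, round(0.25 * d[3]))          # 25% from the top = vitreous side
  b_mid <- floor(d[1] / 2) + 1L             # central planes
  a_mid <- floor(d[2] / 2) + 1L
  a_half <- floor(d[2] / 2) + 1L            # 50% of slice width (B-scan plane)
  b_half <- floor(d[1] / 2) + 1L            # 50% of slice width (A-scan plane)
  mean(c(v[b_mid, a_half, z], v[b_half, a_mid, z]))
}

#' Normalize a volume against the liquid norm
#'
#' The liquid norm acts as a lower threshold: voxels below it are set to
#' zero, and the remaining values are rescaled linearly so the volume
#' maximum maps to 255:
#' `v < LN -> 0`; `v >= LN -> 255 * (v - LN) / (v_max - LN)`.
#' Anchoring the rescale at the liquid norm keeps the fluid baseline at 0.
#'
#' @param volume a [volume_scan()] or 3D array with values in [0, 255].
#' @param liquid_norm the vitreous baseline, in [0, 255].
#' @return object of the same type with values in [0, 255] (possibly
#'   non-integer after rescaling).
#' @export
normalize_volume <- function(volume, liquid_norm) {
  if (liquid_norm < 0 || liquid_norm > 255)
    stop("`liquid_norm` must lie in [0, 255]")
  v <- as_intensity_array(volume)
  v_max <- max(v)
  if (v_max < liquid_norm)
    stop("degenerate volume: every voxel lies below the liquid norm")
  out <- v
  below <- v < liquid_norm
  out[below] <- 0
  if (v_max > liquid_norm) {
    out[!below] <- 255 * (v[!below] - liquid_norm) / (v_max - liquid_norm)
  } else {
    out[!below] <- 255  # all surviving voxels equal the maximum
  }
  if (inherits(volume, "volume_scan")) { volume$intensities <- out; volume }
  else out
}

#' Median blur, slice by slice
#'
#' Applies a `window x window` median filter independently to each B-scan
#' slice (the acquisition plane), with replicate padding at the image
#' edges. Used to reduce speckle before thresholding.
#'
#' @param volume a [volume_scan()] or 3D `[bscan, ascan, depth]` array.
#' @param window odd window edge length (default 3).
#' @return object of the same type, filtered.
#' @export
median_blur <- function(volume, window = 3) {
  v <- as_intensity_array(volume)
  out <- v
  for (b in seq_len(dim(v)[1]))
    out[b, , ] <- .median_filter_cpp(v[b, , ], as.integer(window))
  if (inherits(volume, "volume_scan")) { volume$intensities <- out; volume }
  else out
}

#' Median filter a single 2D slice
#'
#' @param slice numeric matrix.
#' @param window odd window edge length.
#' @return filtered matrix of the same shape.
#' @export
median_filter <- function(slice, window = 3) {
  .median_filter_cpp(as.matrix(slice), as.integer(window))
}

#' Niblack local adaptive thresholding of one slice
#'
#' For every pixel, the threshold is `T = m + k * sigma`, where `m` and
#' `sigma` are the mean and population standard deviation of the
#' intensities within a circular window of the given radius centred on the
#' pixel (clipped at the image borders, statistics over in-image pixels
#' only). Pixels with intensity strictly above `T` are labelled 1
#' (stroma); all others, including exact ties, are labelled 0 (vessel
#' lumen candidates, which are hyporeflective).
#'
#' @param slice numeric matrix (one B-scan).
#' @param params a [binarization_params()], or `NULL` to use `k` and
#'   `radius` directly.
#' @param k,radius Niblack weight and circular window radius; defaults
#'   taken from `params`.
#' @return integer 0/1 matrix of the same shape.
#' @export
niblack_binarize <- function(slice, params = binarization_params(),
                             k = params$niblack_k,
                             radius = params$niblack_radius_px) {
  .niblack_cpp(as.matrix(slice), as.integer(radius), k)
}

#' Binarize a volume into lumen and stroma
#'
#' The full binarization chain: estimate the liquid norm (unless
#' overridden), normalize the volume, median-blur each B-scan slice, then
#' apply Niblack thresholding slice by slice. Binarization runs on the
#' whole slice - masking by the choroidal ROI happens downstream - so the
#' window statistics near the choroid boundary include real neighbouring
#' tissue.
#'
#' @param volume a [volume_scan()] or 3D array.
#' @param params a [binarization_params()].
#' @return an object of class `binary_volume`: list with `binary` (integer
#'   0/1 array of the input shape; 0 = lumen candidate, 1 = stroma) and
#'   `params` (the parameters used, including the realized liquid norm,
#'   for provenance).
#' @export
binarize_volume <- function(volume, params = binarization_params()) {
  stopifnot(inherits(params, "binarization_params"))
  v <- as_intensity_array(volume)
  ln <- params$liquid_norm %||% compute_liquid_norm(v)
  norm <- normalize_volume(v, ln)
  blur <- median_blur(norm, params$median_window)
  bin <- array(0L, dim(v))
  for (b in seq_len(dim(v)[1]))
    bin[b, , ] <- .niblack_cpp(blur[b, , ], params$niblack_radius_px,
                               params$niblack_k)
  params$liquid_norm <- ln
  structure(list(binary = bin, params = params), class = "binary_volume")
}
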