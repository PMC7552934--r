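#' Parameters of the synthetic OCT phantom
#'
#' The phantom emulates the structures the pipeline relies on: a dark
#' vitreous (for the liquid-norm estimate), a retina, a bright RPE line, a
#' choroid band of hyperreflective stroma with hyporeflective vessel
#' lumina at a controlled volume fraction, and a scleral base, all under
#' multiplicative gamma speckle of unit mean. Layer boundaries follow a
#' smooth paraboloid RPE surface plus a choroidal thickness profile with
#' an optional linear nasal thinning.
#'
#' @param dims voxel counts `c(n_bscans, n_ascans, depth_px)`.
#' @param axial_eye_length_mm eye length used for grid scaling.
#' @param eye laterality.
#' @param vitreous_mean,retina_mean,rpe_mean,stroma_mean,lumen_mean,sclera_mean
#'   layer mean intensities in [0, 255].
#' @param rpe_depth_frac RPE surface depth at the scan centre, as a
#'   fraction of `depth_px`.
#' @param rpe_curvature_frac peak-to-centre bowing of the paraboloid RPE
#'   surface, as a fraction of `depth_px`.
#' @param thickness_frac choroidal thickness at the temporal edge, as a
#'   fraction of `depth_px`.
#' @param nasal_thinning fractional linear decrease of thickness toward
#'   the nasal edge (0.3 = 30% thinner nasally, the topography typical of
#'   healthy choroids; 0 = flat profile, the default, which keeps the
#'   band geometry identical across regions for recovery experiments).
#' @param retina_frac retinal thickness as a fraction of `depth_px`.
#' @param rpe_band_px thickness of the bright RPE line in pixels.
#' @param target_lumen_fraction target lumen volume fraction `f` in the
#'   choroid band, in (0, 1); vessels are added until the realized
#'   fraction is within 0.01 of `f`.
#' @param vessel_radius_range_px min/max vessel radius in pixels.
#' @param speckle_shape shape of the unit-mean multiplicative gamma
#'   speckle (smaller = noisier; 4 approximates OCT speckle after light
#'   averaging); `Inf` disables noise.
#' @param vessel_shadows if `TRUE`, darken a few random A-scan columns to
#'   mimic retinal-vessel shadowing (off by default).
#' @param seed RNG seed; the phantom is fully reproducible from it.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(dims = c(64, 128, 256),
                           axial_eye_length_mm = 24.83,
                           eye = "OD",
                           vitreous_mean = 10, retina_mean = 110,
                           rpe_mean = 220, stroma_mean = 140,
                           lumen_mean = 40, sclera_mean = 90,
                           rpe_depth_frac = 0.38, rpe_curvature_frac = 0.04,
                           thickness_frac = 0.40, nasal_thinning = 0,
                           retina_frac = 0.10, rpe_band_px = 3,
                           target_lumen_fraction = 0.70,
                           vessel_radius_range_px = c(5, 7),
                           speckle_shape = 4,
                           vessel_shadows = FALSE,
                           seed = 1) {
  means <- c(vitreous_mean, retina_mean, rpe_mean, stroma_mean, lumen_mean,
             sclera_mean)
  if (any(means < 0 | means > 255)) stop("layer means must lie in [0, 255]")
  if (target_lumen_fraction <= 0 || target_lumen_fraction >= 1)
    stop("`target_lumen_fraction` must be in (0, 1)")
  if (rpe_depth_frac + rpe_curvature_frac + thickness_frac >= 1)
    stop("layer profile does not fit within the scan depth")
  structure(list(dims = as.integer(dims),
                 axial_eye_length_mm = axial_eye_length_mm, eye = eye,
                 vitreous_mean = vitreous_mean, retina_mean = retina_mean,
                 rpe_mean = rpe_mean, stroma_mean = stroma_mean,
                 lumen_mean = lumen_mean, sclera_mean = sclera_mean,
                 rpe_depth_frac = rpe_depth_frac,
                 rpe_curvature_frac = rpe_curvature_frac,
                 thickness_frac = thickness_frac,
                 nasal_thinning = nasal_thinning,
                 retina_frac = retina_frac,
                 rpe_band_px = as.integer(rpe_band_px),
                 target_lumen_fraction = target_lumen_fraction,
                 vessel_radius_range_px = vessel_radius_range_px,
                 speckle_shape = speckle_shape,
                 vessel_shadows = vessel_shadows,
                 seed = seed),
            class = "phantom_params")
}

# voxelize one vessel tube into a sub-box. Tubes run along the B-scan
# axis over [b_lo, b_hi] and follow the curved band: the centreline sits
# at a fixed relative depth `zfrac` within the local choroid (top +
# zfrac * thickness per column), as real choroidal vessels run within
# the curved choroid rather than at constant absolute depth. Returns
# list(b, a, z index ranges, vox logical sub-array).
.vessel_voxels <- function(dims, b_lo, b_hi, a0, zfrac, r, top, thk) {
  clamp <- function(x, n) max(1L, min(n, x))
  b_rng <- b_lo:b_hi
  a_rng <- clamp(floor(a0 - r), dims[2]):clamp(ceiling(a0 + r), dims[2])
  tt <- outer(rep(0, length(b_rng)), (a_rng - a0)^2, `+`)
  z0 <- top[b_rng, a_rng, drop = FALSE] + zfrac * thk[b_rng, a_rng, drop = FALSE]
  z_rng <- clamp(floor(min(z0) - r), dims[3]):clamp(ceiling(max(z0) + r), dims[3])
  nbs <- length(b_rng); nas <- length(a_rng); nzs <- length(z_rng)
  zi <- array(rep(z_rng, each = nbs * nas), c(nbs, nas, nzs))
  q <- array(tt, c(nbs, nas, nzs)) + (zi - array(z0, c(nbs, nas, nzs)))^2
  list(b = b_rng, a = a_rng, z = z_rng, vox = q <= r^2)
}

#' Generate a synthetic OCT phantom with known lumen fraction
#'
#' Builds the layered volume described in [phantom_params()]: the RPE
#' surface is a paraboloid, the choroid band lies below the RPE line with
#' the configured thickness profile, and vessel tubes (radii uniform in
#' the configured range, running the full B-scan extent and bending with
#' the band) are added inside the band until the realized lumen volume
#' fraction lies within 0.01 of the target. Tube positions follow a
#' low-discrepancy sequence with a random phase, emulating the even
#' spacing of real vascular beds, so the realized fraction is spatially
#' homogeneous; proposals that would overshoot the target are rejected.
#' Intensities are the layer means under multiplicative unit-mean gamma
#' speckle, clipped to [0, 255] and quantized to 8 bits. Byte-identical
#' output is guaranteed for a fixed seed.
#'
#' @param params a [phantom_params()].
#' @return list with `volume` (a [volume_scan()]), `surfaces` (ground
#'   truth [segmentation_surfaces()]; the RPE depth marks the bottom of
#'   the bright RPE line, i.e. the top of the choroid band),
#'   `lumen_mask` (logical truth array, confined to the band),
#'   `realized_lumen_fraction`, `regional_lumen_fractions` (truth
#'   fractions over a default magnification-corrected grid), `grid` (that
#'   grid) and `geometry`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  d <- params$dims; nb <- d[1]; na <- d[2]; nz <- d[3]
  geometry <- scan_geometry(nb, na, nz)

  # ground-truth surfaces -------------------------------------------------
  bn <- (seq_len(nb) - (nb + 1) / 2) / (nb / 2)
  an <- (seq_len(na) - (na + 1) / 2) / (na / 2)
  r2 <- outer(bn^2, an^2, `+`) / 2                      # 0 centre, ~1 corner
  rpe_line_bottom <- params$rpe_depth_frac * nz +
    params$rpe_curvature_frac * nz * r2                 # bottom of RPE band
  # nasal thinning: nasal = increasing ascan for OD, decreasing for OS
  a_frac <- (seq_len(na) - 1) / (na - 1)
  if (params$eye == "OS") a_frac <- rev(a_frac)
  thick <- params$thickness_frac * nz *
    outer(rep(1, nb), 1 - params$nasal_thinning * a_frac)
  surfaces <- segmentation_surfaces(rpe_line_bottom, thick, nz)

  # choroid band (matches roi_from_surfaces rounding) ---------------------
  top <- round_half_up(rpe_line_bottom)
  thk <- round_half_up(thick)
  z <- array(rep(seq_len(nz), each = nb * na), c(nb, na, nz))
  top3 <- array(top, c(nb, na, nz))
  band <- z > top3 & z <= top3 + array(thk, c(nb, na, nz))
  n_band <- sum(band)

  # vessel placement ------------------------------------------------------
  # Tube positions (A-scan centre, relative depth) follow a low-discrepancy
  # Kronecker sequence with a random phase: every prefix of the sequence
  # covers the band nearly uniformly, emulating the even spacing of real
  # vascular beds and keeping the realized lumen fraction spatially
  # homogeneous, while the random phase and radii keep the phantom
  # stochastic. Proposals are thinned in proportion to the local band
  # thickness so the volume fraction stays flat across the thickness
  # profile, and additions that would overshoot the target are rejected
  # (retried at the minimum radius near the target).
  f <- params$target_lumen_fraction
  rmin <- params$vessel_radius_range_px[1]
  rmax <- params$vessel_radius_range_px[2]
  clampi <- function(x, n) min(n, max(1L, round(x)))
  thk_max <- max(thk)
  thk_mean <- mean(thk)
  alpha <- c(0.7548776662466927, 0.5698402909980532)  # plastic-number pair
  phase <- runif(2)
  s_grid <- max(3, floor(2 * rmin))  # every column is crossed on each pass
  n_slots <- ceiling((na + 2 * rmax) / s_grid) + 1
  lumen <- array(FALSE, d)
  n_lumen <- 0
  done <- FALSE
  for (pass in seq_len(100)) {
    # one pass = a regular A-scan grid of tubes at a common stratum depth;
    # the per-pass offset and depth follow a low-discrepancy sequence with
    # random phase, so coverage accumulates evenly across columns and
    # depths (emulating the even spacing of real vascular beds) while the
    # phantom stays stochastic through the phase, radii and jitter
    off <- ((pass * alpha[1] + phase[1]) %% 1) * s_grid - rmax
    zf0 <- (pass * alpha[2] + phase[2]) %% 1
    slot_order <- order((seq_len(n_slots) * alpha[1] + phase[2]) %% 1)
    for (k in slot_order) {
      frac <- n_lumen / n_band
      if (frac >= f - 0.002) { done <- TRUE; break }
      # cap the radius by the volume still needed so the closing passes
      # complete a uniform layer of proportionally smaller vessels rather
      # than leaving a one-slab deficit at the slots not yet visited
      r_cap <- sqrt((f - frac) * s_grid * thk_mean /
                      (pi * max(0.05, 1 - frac)))
      r <- min(runif(1, rmin, rmax), max(1.3, r_cap))
      a0 <- off + (k - 1) * s_grid
      if (a0 < 1 - r || a0 > na + r) next
      if (runif(1) > thk[1, clampi(a0, na)] / thk_max) next
      eps <- r / thk_mean
      zf <- (min(max(zf0 + runif(1, -0.05, 0.05), 0), 1)) * (1 + 2 * eps) - eps
      # tubes span half the B-scan extent, alternating halves between
      # passes, so regional averages pool two independent tube sets
      half <- (pass + k) %% 2
      b_lo <- 1L + half * (nb %/% 2)
      b_hi <- if (half == 0) nb %/% 2 else nb
      v <- .vessel_voxels(d, b_lo, b_hi, a0, zf, r, top, thk)
      sub <- lumen[v$b, v$a, v$z, drop = FALSE]
      add <- v$vox & band[v$b, v$a, v$z, drop = FALSE] & !sub
      n_new <- sum(add)
      if (n_new > 0 && (n_lumen + n_new) / n_band <= f + 0.01) {
        lumen[v$b, v$a, v$z] <- sub | add
        n_lumen <- n_lumen + n_new
      }
    }
    if (done) break
  }
  realized <- sum(lumen) / n_band
  if (abs(realized - f) > 0.01)
    stop(sprintf("infeasible lumen fraction: realized %.3f vs target %.3f",
                 realized, f))

  # layer means -----------------------------------------------------------
  mean_vol <- array(params$vitreous_mean, d)
  retina_top3 <- array(top - params$rpe_band_px -
                         round(params$retina_frac * nz), c(nb, na, nz))
  rpe_top3 <- array(top - params$rpe_band_px, c(nb, na, nz))
  csi3 <- top3 + array(thk, c(nb, na, nz))
  mean_vol[z > retina_top3] <- params$retina_mean
  mean_vol[z > rpe_top3] <- params$rpe_mean
  mean_vol[z > top3] <- params$stroma_mean
  mean_vol[lumen] <- params$lumen_mean
  mean_vol[z > csi3] <- params$sclera_mean

  if (params$vessel_shadows) {
    n_sh <- max(1, round(na / 25))
    cols <- sample(na, n_sh)
    mean_vol[, cols, ] <- mean_vol[, cols, ] * 0.6
  }

  # speckle, clip, quantize -----------------------------------------------
  if (is.finite(params$speckle_shape)) {
    sp <- rgamma(length(mean_vol), shape = params$speckle_shape,
                 rate = params$speckle_shape)
    vol <- mean_vol * array(sp, d)
  } else vol <- mean_vol
  vol <- round(pmin(pmax(vol, 0), 255))

  volume <- volume_scan(vol, geometry, params$axial_eye_length_mm, params$eye)
  grid <- build_grid(c(nb, na),
                     lateral_pixel_scales(params$axial_eye_length_mm, geometry),
                     eye = params$eye)
  regional <- true_regional_cvi(lumen, surfaces, grid, geometry)

  list(volume = volume, surfaces = surfaces, lumen_mask = lumen,
       realized_lumen_fraction = realized,
       regional_lumen_fractions = regional, grid = grid, geometry = geometry,
       params = params)
}

#' True regional lumen fraction from the phantom ground truth
#'
#' Applies the regional CVI definition to the truth lumen mask instead of
#' a binarized volume, giving the recovery target for pipeline
#' validation: identical to [region_cvi()] with the binarizer replaced by
#' the truth.
#'
#' @param lumen_mask logical truth array (TRUE = lumen).
#' @param surfaces the phantom's [segmentation_surfaces()].
#' @param grid an [build_grid()] result.
#' @param geometry a [scan_geometry()].
#' @return data frame as from [region_cvi()].
#' @export
true_regional_cvi <- function(lumen_mask, surfaces, grid, geometry) {
  roi <- roi_from_surfaces(surfaces, geometry)
  region_cvi(1L - lumen_mask, roi, grid)   # stroma = 1, lumen = 0
}

#' Simulate an intersession repeatability study
#'
#' Hierarchical normal model for regional measurements:
#' `value[s, d, r, region] = baseline[region] + subject[s, region] +
#' day[s, d, region] + noise`, with independent normal effects of the
#' given standard deviations. This emulates the three-day, three-replicate
#' protocol for exercising the repeatability statistics; with
#' `within_day_sd = 0` the daily medians are i.i.d. normal with sd
#' `between_day_sd`, so the coefficient of repeatability converges to
#' `1.96 * sqrt(2/3) * (3/2) * between_day_sd` for many subjects.
#'
#' @param n_subjects number of subjects.
#' @param n_days,n_replicates design dimensions (default 3 x 3).
#' @param baseline per-region mean; scalar or one value per region.
#' @param between_subject_sd,between_day_sd,within_day_sd effect standard
#'   deviations (all `>= 0`).
#' @param regions region names (default the 13 ETDRS regions).
#' @param seed RNG seed.
#' @return a [measurement_set()].
#' @export
generate_repeatability_sessions <- function(n_subjects, n_days = 3,
                                            n_replicates = 3,
                                            baseline = 300,
                                            between_subject_sd = 30,
                                            between_day_sd = 6,
                                            within_day_sd = 4,
                                            regions = etdrs_region_names(),
                                            seed = 1) {
  if (any(c(between_subject_sd, between_day_sd, within_day_sd) < 0))
    stop("standard deviations must be >= 0")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  nr <- length(regions)
  baseline <- rep_len(baseline, nr)
  vals <- array(0, c(n_subjects, n_days, n_replicates, nr))
  subj <- matrix(rnorm(n_subjects * nr, 0, between_subject_sd), n_subjects, nr)
  day <- array(rnorm(n_subjects * n_days * nr, 0, between_day_sd),
               c(n_subjects, n_days, nr))
  for (k in seq_len(nr))
    vals[, , , k] <- baseline[k] + subj[, k] +
      array(day[, , k], c(n_subjects, n_days, n_replicates)) +
      rnorm(n_subjects * n_days * n_replicates, 0, within_day_sd)
  measurement_set(vals, regions)
}
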