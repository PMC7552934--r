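#' Run configuration for the end-to-end pipeline
#'
#' Collects the paths and parameters of one analysis run. Accepts either
#' explicit arguments or a JSON file with the same field names.
#'
#' @param volume path to the volume scan (TIFF or NIfTI).
#' @param rpe,thickness paths to the RPE depth and choroidal thickness
#'   maps (CSV or TIFF).
#' @param out output directory.
#' @param geometry a [scan_geometry()] or a list of its arguments.
#' @param axial_eye_length_mm,eye per-eye metadata.
#' @param onh ONH circle: an [onh_circle()], a list
#'   `(center_bscan, center_ascan, radius_px)`, or a list
#'   `(p1, p2)` of diameter endpoints; `NULL` for no exclusion.
#' @param binarization a [binarization_params()] or list of its
#'   arguments.
#' @param ring_radii_mm ETDRS ring radii (mm).
#' @param fovea_center optional en-face fovea coordinates.
#' @param render_maps,export_binary output flags.
#' @return an object of class `run_config`.
#' @export
run_config <- function(volume, rpe, thickness, out,
                       geometry, axial_eye_length_mm, eye = "OD",
                       onh = NULL, binarization = list(),
                       ring_radii_mm = c(0.5, 1.5, 3.0, 5.0),
                       fovea_center = NULL,
                       render_maps = FALSE, export_binary = FALSE) {
  if (!inherits(geometry, "scan_geometry"))
    geometry <- do.call(scan_geometry, as.list(geometry))
  if (!inherits(binarization, "binarization_params"))
    binarization <- do.call(binarization_params, as.list(binarization))
  if (!is.null(onh) && !inherits(onh, "onh_circle")) {
    onh <- if (!is.null(onh$p1)) onh_circle_from_diameter(unlist(onh$p1),
                                                          unlist(onh$p2))
           else do.call(onh_circle, onh[c("center_bscan", "center_ascan",
                                          "radius_px")])
  }
  structure(list(volume = volume, rpe = rpe, thickness = thickness,
                 out = out, geometry = geometry,
                 axial_eye_length_mm = axial_eye_length_mm, eye = eye,
                 onh = onh, binarization = binarization,
                 ring_radii_mm = ring_radii_mm, fovea_center = fovea_center,
                 render_maps = render_maps, export_binary = export_binary),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON config file.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$geometry <- as.list(cfg$geometry)
  do.call(run_config, cfg)
}

config_provenance <- function(config) {
  cfg <- unclass(config)
  cfg$geometry <- unclass(cfg$geometry)
  cfg$binarization <- unclass(cfg$binarization)
  if (!is.null(cfg$onh)) cfg$onh <- unclass(cfg$onh)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(fileext = ".json"); on.exit(unlink(tmp))
  writeLines(json, tmp)
  cfg$config_hash <- unname(tools::md5sum(tmp))
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(structure(class = c("pipeline_error", "error", "condition"),
                   list(message = sprintf("[stage %s] %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name))))
}

#' Run the full choroidal analysis pipeline
#'
#' Executes read -> magnification-corrected grid -> liquid-norm /
#' median-blur / Niblack binarization -> choroidal ROI -> regional
#' CVI and ChT -> write. The liquid norm, lateral pixel scale and
#' truncation flag are logged to stderr; all results, the en-face maps
#' and a JSON provenance record (with a config hash) are written to the
#' output directory. The pipeline is fully deterministic: identical
#' inputs and config give identical outputs.
#'
#' @param config a [run_config()] or path to a JSON config file.
#' @return invisibly, a list with the [cvi_result()], the grid, the
#'   binarization provenance and the written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  g <- config$geometry

  vol <- stage("volume", read_volume(config$volume, g,
                                     config$axial_eye_length_mm, config$eye))
  surf <- stage("surfaces", read_surfaces(config$rpe, config$thickness,
                                          g$depth_px))
  if (!all(dim(surf$rpe_depth_px) == c(g$n_bscans, g$n_ascans)))
    stage("surfaces", stop("surface shape does not match the volume geometry"))

  scales <- lateral_pixel_scales(config$axial_eye_length_mm, g)
  message(sprintf("lateral pixel scale: %.6f (bscan) x %.6f (ascan) mm/px",
                  scales[1], scales[2]))
  grid <- stage("grid", build_grid(c(g$n_bscans, g$n_ascans), scales,
                                   fovea_center = config$fovea_center,
                                   eye = config$eye,
                                   ring_radii_mm = config$ring_radii_mm,
                                   onh = config$onh))
  if (grid$truncated) message("extended grid clipped to the scanned frame")

  bin <- stage("binarize", binarize_volume(vol, config$binarization))
  message(sprintf("liquid norm: %.3f", bin$params$liquid_norm))

  roi <- stage("roi", roi_from_surfaces(surf, g))
  res <- stage("metrics", cvi_result(bin, roi, surf, grid, g))

  prov <- config_provenance(config)
  prov$liquid_norm <- bin$params$liquid_norm
  prov$pixel_scale_mm <- as.list(scales)
  prov$truncated <- grid$truncated
  files <- stage("write", write_results(res, config$out, surf, g, prov))
  if (isTRUE(config$export_binary)) {
    p <- file.path(config$out, "binary_volume.tif")
    write_volume(bin$binary * 255L, p)
    files <- c(files, p)
  }
  if (isTRUE(config$render_maps))
    files <- c(files, render_maps(res, grid, surf, g, config$out))
  invisible(list(result = res, grid = grid, binarization = bin$params,
                 files = files))
}

#' Summary-statistics tables from a long-format measurement file
#'
#' The statistics companion to [run_pipeline()]: given per-scan regional
#' values in long format (`subject, day, replicate, region, value`),
#' produces the topography summary (median, IQR per region), the
#' intersession repeatability table (CR and CR/median per region), or the
#' per-region Spearman correlation with a per-subject covariate.
#'
#' @param measurements a [measurement_set()] or path to a long-format CSV.
#' @param mode `"topography"`, `"repeatability"` or `"correlation"`.
#' @param covariate per-subject covariate values (or a CSV path with
#'   columns `subject`, `value`), required for `mode = "correlation"`.
#' @return the corresponding data frame; topography and repeatability
#'   tables carry the across-region quartile CV as attribute
#'   `"quartile_cv"`.
#' @export
stats_tables <- function(measurements,
                         mode = c("topography", "repeatability",
                                  "correlation"),
                         covariate = NULL) {
  mode <- match.arg(mode)
  ms <- if (is.character(measurements)) read_measurements(measurements)
        else measurements
  switch(mode,
    topography = summarize_topography(ms),
    repeatability = repeatability_table(ms),
    correlation = {
      if (is.null(covariate)) stop("correlation mode needs a covariate")
      if (is.character(covariate)) {
        cv <- read.csv(covariate)
        covariate <- cv$value[order(cv$subject)]
      }
      correlate_with_covariate(ms, covariate)
    })
}

#' Command-line entry point
#'
#' Thin dispatcher used by the installed `choroquant` Rscript
#' (`system.file("cli", "choroquant.R", package = "choroquant")`).
#' Subcommands: `run --config cfg.json`; `stats --mode <m> --in file.csv
#' [--covariate file.csv] --out file.csv`; `phantom generate
#' [--config cfg.json] --out dir`; `grid-preview --config cfg.json --out
#' labels.tif`. Logs to stderr, writes results to files only.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  status <- tryCatch({
    cmd <- if (length(args)) args[1] else "help"
    switch(cmd,
      run = {
        run_pipeline(opt("--config", stop("run needs --config")))
        0L
      },
      stats = {
        out <- opt("--out", stop("stats needs --out"))
        tab <- stats_tables(opt("--in", stop("stats needs --in")),
                            mode = opt("--mode", "topography"),
                            covariate = opt("--covariate"))
        write.csv(tab, out, row.names = FALSE)
        cv <- attr(tab, "quartile_cv")
        if (!is.null(cv)) message(sprintf("across-region quartile CV: %.2f", cv))
        0L
      },
      phantom = {
        out <- opt("--out", stop("phantom needs --out"))
        cfgp <- opt("--config")
        prm <- if (is.null(cfgp)) phantom_params()
               else do.call(phantom_params,
                            jsonlite::read_json(cfgp, simplifyVector = TRUE))
        ph <- generate_phantom(prm)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_volume(ph$volume, file.path(out, "volume.tif"))
        write_surface(ph$surfaces$rpe_depth_px, file.path(out, "rpe.csv"))
        write_surface(ph$surfaces$thickness_px, file.path(out, "thickness.csv"))
        write_volume(ph$lumen_mask * 255L, file.path(out, "lumen_truth.tif"))
        jsonlite::write_json(
          list(realized_lumen_fraction = ph$realized_lumen_fraction,
               regional_lumen_fractions = ph$regional_lumen_fractions,
               seed = prm$seed),
          file.path(out, "truth.json"),
          auto_unbox = TRUE, digits = NA, dataframe = "rows")
        0L
      },
      `grid-preview` = {
        cfg <- read_run_config(opt("--config", stop("grid-preview needs --config")))
        g <- cfg$geometry
        grid <- build_grid(c(g$n_bscans, g$n_ascans),
                           lateral_pixel_scales(cfg$axial_eye_length_mm, g),
                           fovea_center = cfg$fovea_center, eye = cfg$eye,
                           ring_radii_mm = cfg$ring_radii_mm, onh = cfg$onh)
        write_grid_labels(grid, opt("--out", stop("grid-preview needs --out")))
        0L
      },
      {
        message("usage: choroquant <run|stats|phantom|grid-preview> [options]")
        if (cmd == "help") 0L else 2L
      })
  }, error = function(e) {
    err <- list(error = conditionMessage(e),
                stage = if (inherits(e, "pipeline_error")) e$stage else "cli")
    message(jsonlite::toJSON(err, auto_unbox = TRUE))
    1L
  })
  invisible(status)
}
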