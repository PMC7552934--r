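#' Bundled reference values for healthy adult eyes
#'
#' Regional reference values for the 13 extended-ETDRS regions, from a
#' published healthy-eye cohort (14 young adults, 12 x 12 mm swept-source
#' OCT volumes, three scans per day on three days): the across-subject
#' median and IQR of choroidal thickness (um) and CVI (percent), and the
#' intersession coefficient of repeatability of each metric. These are
#' the conventional desk-scale inputs for the summary statistics - e.g.
#' `quartile_cv(choroid_reference()$cht_median_um)` gives the
#' across-region dispersion of thickness - and serve as realistic
#' baselines for simulation.
#'
#' @return data frame with one row per region: `region`, `cht_median_um`,
#'   `cht_iqr_um`, `cvi_median_pct`, `cvi_iqr_pct`, `cht_cr_um`,
#'   `cvi_cr_pct`.
#' @export
choroid_reference <- function() {
  data.frame(
    region = etdrs_region_names(),
    cht_median_um = c(323.24, 333.98, 299.80, 315.43, 298.82,
                      329.10, 303.71, 297.85, 246.09,
                      344.72, 285.15, 287.11, 200.19),
    cht_iqr_um = c(29.30, 54.69, 64.45, 48.83, 54.69,
                   64.45, 111.33, 50.78, 78.12,
                   70.31, 64.45, 46.87, 60.55),
    cvi_median_pct = c(72.89, 74.20, 74.12, 75.11, 73.78,
                       73.80, 74.15, 76.05, 76.08,
                       73.35, 73.49, 75.34, 74.72),
    cvi_iqr_pct = c(4.51, 4.12, 4.58, 3.75, 4.61,
                    4.49, 4.14, 5.65, 5.35,
                    3.72, 3.95, 6.01, 5.44),
    cht_cr_um = c(11.96, 16.35, 13.95, 10.37, 10.76,
                  13.95, 12.76, 11.36, 11.56,
                  11.16, 10.37, 11.16, 20.33),
    cvi_cr_pct = c(4.00, 4.20, 4.21, 4.54, 4.15,
                   3.93, 3.90, 5.41, 4.88,
                   5.00, 4.39, 5.51, 4.02),
    stringsAsFactors = FALSE
  )
}
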