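#' Quartile-based coefficient of variation
#'
#' `CV = (Q75 - Q25) / (Q75 + Q25) * 100`, a nonparametric dispersion
#' measure suited to non-normal regional summaries. Quartiles are computed
#' by linear interpolation of the order statistics at positions
#' `(n - 1) * q` (the convention of [stats::quantile()] type 7).
#'
#' @param values numeric vector, `n >= 2`.
#' @return the CV as a percentage of the quartile midpoint (scale-free:
#'   `CV(c * x) = CV(x)` for `c > 0`).
#' @export
quartile_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  if (anyNA(values)) stop("missing values not allowed")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] + q[2] == 0) stop("quartile midpoint is zero; CV undefined")
  (q[2] - q[1]) / (q[2] + q[1]) * 100
}

#' Interquartile range with the package's quartile convention
#' @param values numeric vector.
#' @return `Q75 - Q25`.
#' @export
iqr_q7 <- function(values) {
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' A repeated-measures set of regional values
#'
#' Container for an intersession design: `values[subject, day, replicate,
#' region]`. The reference protocol is 3 consecutive scans per day on 3
#' separate days.
#'
#' @param values 4D numeric array; the 4th dimension may carry region
#'   names as dimnames.
#' @param regions optional region names (defaults to existing dimnames or
#'   [etdrs_region_names()] when there are 13 regions).
#' @return an object of class `measurement_set`.
#' @export
measurement_set <- function(values, regions = NULL) {
  stopifnot(length(dim(values)) == 4)
  if (is.null(regions)) {
    regions <- dimnames(values)[[4]]
    if (is.null(regions))
      regions <- if (dim(values)[4] == 13) etdrs_region_names()
                 else paste0("region_", seq_len(dim(values)[4]))
  }
  dimnames(values) <- list(NULL, NULL, NULL, regions)
  structure(list(values = values,
                 n_subjects = dim(values)[1], n_days = dim(values)[2],
                 n_replicates = dim(values)[3], regions = regions),
            class = "measurement_set")
}

#' Nonparametric coefficient of repeatability for an intersession design
#'
#' Within each subject, the three replicates of a day are collapsed to
#' the daily median; each daily median's difference to that subject's
#' mean across the days is a delta. All deltas are pooled across subjects
#' into one empirical distribution, its 2.5th and 97.5th percentiles
#' (same linear-interpolation convention) are multiplied by 3/2 - the
#' correction factor for data centred on the per-subject mean of three
#' days - and the CR is half the length of the resulting interval. Only
#' intersession variability enters: replicates within a day are never
#' compared directly.
#'
#' @param values numeric array `[subject, day, replicate]` for one region
#'   and metric; no missing cells allowed.
#' @return the CR, in the units of the metric; `>= 0`,
#'   translation-invariant, and linear in the data scale.
#' @export
coefficient_of_repeatability <- function(values) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3)
    stop("`values` must be a [subject, day, replicate] array")
  if (d[1] < 2) stop("need at least 2 subjects")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    colnames(bad) <- c("subject", "day", "replicate")
    stop("missing cells at (subject, day, replicate): ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  }
  if (d[2] != 3 || d[3] != 3)
    warning(sprintf("design is %d days x %d replicates; the reference protocol is 3 x 3",
                    d[2], d[3]))
  daily_median <- apply(values, c(1, 2), median)       # [subject, day]
  deltas <- daily_median - rowMeans(daily_median)      # centred per subject
  lims <- quantile(as.vector(deltas), c(0.025, 0.975), type = 7,
                   names = FALSE) * 3 / 2
  (lims[2] - lims[1]) / 2
}

#' Repeatability coefficient relative to the regional median
#'
#' @param cr a coefficient of repeatability.
#' @param median_value the regional median on the same scale; must be > 0.
#' @return `100 * cr / median_value` (percent).
#' @export
cr_over_median <- function(cr, median_value) {
  if (any(median_value <= 0)) stop("`median_value` must be > 0")
  100 * cr / median_value
}

#' Spearman rank correlation with t-approximation p value
#'
#' rho is the Pearson correlation of the mid-ranks (average ranks for
#' ties); the two-sided p value uses the t approximation with `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return list with `rho`, `p` and `n`; `rho` is `NA` (with a warning)
#'   when either input is constant.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (var(rx) == 0 || var(ry) == 0) {
    warning("constant input: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Topographical summary across subjects
#'
#' Averages all scans (every day and replicate) within each subject, then
#' summarizes each region across subjects as median and interquartile
#' range, with the quartile-based CV of the regional medians as the
#' across-region dispersion.
#'
#' @param ms a [measurement_set()].
#' @return data frame with columns `region`, `median`, `iqr`; the
#'   across-region quartile CV of the medians is attached as attribute
#'   `"quartile_cv"`.
#' @export
summarize_topography <- function(ms) {
  stopifnot(inherits(ms, "measurement_set"))
  if (ms$n_subjects < 2) stop("need at least 2 subjects")
  per_subject <- apply(ms$values, c(1, 4), mean)   # [subject, region]
  med <- apply(per_subject, 2, median)
  iqr <- apply(per_subject, 2, iqr_q7)
  out <- data.frame(region = ms$regions, median = med, iqr = iqr,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "quartile_cv") <- quartile_cv(med)
  out
}

#' Per-region repeatability table
#'
#' Computes the coefficient of repeatability for every region of a
#' measurement set and, when the topographical medians are supplied (or
#' computable), the CR as a percentage of the regional median.
#'
#' @param ms a [measurement_set()].
#' @param medians optional named vector of regional medians; defaults to
#'   the medians from [summarize_topography()].
#' @return data frame with columns `region`, `cr`, `median`,
#'   `cr_over_median_pct`; the across-region quartile CV of the CRs is
#'   attached as attribute `"quartile_cv"`.
#' @export
repeatability_table <- function(ms, medians = NULL) {
  stopifnot(inherits(ms, "measurement_set"))
  if (is.null(medians)) {
    topo <- summarize_topography(ms)
    medians <- setNames(topo$median, topo$region)
  }
  cr <- vapply(seq_along(ms$regions), function(i)
    coefficient_of_repeatability(ms$values[, , , i, drop = TRUE]), numeric(1))
  med <- as.numeric(medians[ms$regions])
  out <- data.frame(region = ms$regions, cr = cr, median = med,
                    cr_over_median_pct = ifelse(med > 0, 100 * cr / med, NA_real_),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "quartile_cv") <- quartile_cv(cr)
  out
}

#' Per-region Spearman correlation with a subject covariate
#'
#' Correlates the per-subject mean regional values with a per-subject
#' covariate (typically axial eye length).
#'
#' @param ms a [measurement_set()].
#' @param covariate numeric vector, one value per subject.
#' @return data frame with columns `region`, `rho`, `p`.
#' @export
correlate_with_covariate <- function(ms, covariate) {
  stopifnot(inherits(ms, "measurement_set"))
  if (length(covariate) != ms$n_subjects)
    stop("`covariate` must have one value per subject")
  per_subject <- apply(ms$values, c(1, 4), mean)
  res <- lapply(seq_along(ms$regions), function(i)
    spearman_rho(per_subject[, i], covariate))
  data.frame(region = ms$regions,
             rho = vapply(res, `[[`, numeric(1), "rho"),
             p = vapply(res, `[[`, numeric(1), "p"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write long-format measurement CSVs
#'
#' Long format: columns `subject`, `day`, `replicate`, `region`, `value`
#' (one metric per file). [read_measurements()] validates completeness
#' and returns a [measurement_set()].
#'
#' @param path CSV file path.
#' @return a [measurement_set()].
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "day", "replicate", "region", "value")
  if (!all(need %in% names(df)))
    stop("long-format CSV must have columns: ", paste(need, collapse = ", "))
  subjects <- sort(unique(df$subject)); days <- sort(unique(df$day))
  reps <- sort(unique(df$replicate)); regions <- unique(df$region)
  arr <- array(NA_real_, c(length(subjects), length(days), length(reps),
                           length(regions)),
               dimnames = list(NULL, NULL, NULL, regions))
  idx <- cbind(match(df$subject, subjects), match(df$day, days),
               match(df$replicate, reps), match(df$region, regions))
  arr[idx] <- df$value
  if (anyNA(arr)) {
    bad <- which(is.na(arr), arr.ind = TRUE)
    stop("incomplete measurement grid; first missing cell: subject ",
         subjects[bad[1, 1]], ", day ", days[bad[1, 2]], ", replicate ",
         reps[bad[1, 3]], ", region ", regions[bad[1, 4]])
  }
  measurement_set(arr, regions)
}

#' @rdname read_measurements
#' @param ms a [measurement_set()].
#' @export
write_measurements <- function(ms, path) {
  stopifnot(inherits(ms, "measurement_set"))
  g <- expand.grid(subject = seq_len(ms$n_subjects), day = seq_len(ms$n_days),
                   replicate = seq_len(ms$n_replicates),
                   region = ms$regions, stringsAsFactors = FALSE)
  g$value <- as.vector(ms$values)
  write.csv(g, path, row.names = FALSE)
  invisible(path)
}
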