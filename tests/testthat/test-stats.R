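test_that("quartile CV reproduces the published regional summaries", {
  ref <- choroid_reference()
  expect_equal(round(quartile_cv(ref$cht_median_um), 2), 5.92)
  expect_equal(round(quartile_cv(ref$cvi_median_pct), 2), 0.89)
  expect_equal(round(quartile_cv(ref$cht_cr_um), 2), 11.11)
  expect_equal(round(quartile_cv(ref$cvi_cr_pct), 2), 9.66)
})

test_that("quartile CV is scale-free and zero for constant data", {
  expect_equal(quartile_cv(rep(7, 5)), 0)
  set.seed(7)
  x <- rlnorm(40, 3, 0.4)
  expect_equal(quartile_cv(3.7 * x), quartile_cv(x))
  expect_error(quartile_cv(c(-1, 1)), "midpoint is zero")
  expect_error(quartile_cv(3), "at least 2")
})

test_that("CR is zero for constant data and invariant under translation/scale", {
  vals <- array(5, c(4, 3, 3))
  expect_equal(coefficient_of_repeatability(vals), 0)
  set.seed(8)
  v <- array(rnorm(14 * 9, 300, 20), c(14, 3, 3))
  cr <- coefficient_of_repeatability(v)
  expect_equal(coefficient_of_repeatability(v + 100), cr)
  expect_equal(coefficient_of_repeatability(v * 2.5), cr * 2.5)
  expect_true(cr >= 0)
})

test_that("CR matches the closed form 1.96 sqrt(2/3) (3/2) sigma on simulated medians", {
  # with no within-day noise the daily medians are i.i.d. normal(sd sigma)
  sigma <- 4
  ms <- generate_repeatability_sessions(10000, between_subject_sd = 0,
                                        between_day_sd = sigma,
                                        within_day_sd = 0,
                                        regions = "r1", seed = 9)
  cr <- coefficient_of_repeatability(ms$values[, , , 1])
  expect_equal(cr, 1.96 * sqrt(2 / 3) * 1.5 * sigma, tolerance = 0.02)
})

test_that("CR at the study's size (14 subjects) lands near the closed form", {
  # stochastic check: at n = 14 the estimate stays within +-35% of the
  # asymptotic value in nearly all seeds
  sigma <- 6; target <- 1.96 * sqrt(2 / 3) * 1.5 * sigma
  hits <- vapply(1:40, function(s) {
    ms <- generate_repeatability_sessions(14, between_subject_sd = 25,
                                          between_day_sd = sigma,
                                          within_day_sd = 0,
                                          regions = "r1", seed = 1000 + s)
    abs(coefficient_of_repeatability(ms$values[, , , 1]) / target - 1) <= 0.35
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("CR validates the measurement grid and names missing cells", {
  v <- array(1, c(3, 3, 3)); v[2, 1, 3] <- NA
  expect_error(coefficient_of_repeatability(v), "2,1,3")
  expect_error(coefficient_of_repeatability(array(1, c(1, 3, 3))), "2 subjects")
  expect_warning(coefficient_of_repeatability(array(rnorm(16), c(4, 2, 2))),
                 "3 x 3")
})

test_that("CR over median reproduces the published central-field ratios", {
  expect_equal(round(cr_over_median(11.96, 323.24), 2), 3.70)
  expect_equal(round(cr_over_median(4.00, 72.89), 2), 5.49)
  expect_equal(round(cr_over_median(20.33, 200.19), 2), 10.16)
  expect_equal(cr_over_median(0, 10), 0)
  expect_error(cr_over_median(1, 0), "must be > 0")
})

test_that("Spearman rho matches a brute-force rank-then-Pearson oracle", {
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    if (i > 3) { x[1:3] <- x[4]; y[5:6] <- y[7] }  # ties
    r <- spearman_rho(x, y)
    oracle <- cor(rank(x), rank(y))
    expect_equal(r$rho, oracle, tolerance = 1e-12)
    tstat <- oracle * sqrt(8 / (1 - oracle^2))
    expect_equal(r$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  }
  expect_equal(spearman_rho(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_rho(1:8, rev(1:8))$rho, -1)
  expect_warning(r0 <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r0$rho))
})

test_that("topography summary averages scans per subject then summarizes", {
  set.seed(11)
  ms <- generate_repeatability_sessions(6, baseline = c(300, 250),
                                        between_subject_sd = 30,
                                        between_day_sd = 5, within_day_sd = 3,
                                        regions = c("a", "b"), seed = 12)
  topo <- summarize_topography(ms)
  expect_equal(nrow(topo), 2)
  per_subj <- apply(ms$values, c(1, 4), mean)
  expect_equal(topo$median, unname(apply(per_subj, 2, median)))
  q <- apply(per_subj, 2, quantile, c(0.25, 0.75), type = 7)
  expect_equal(topo$iqr, unname(q[2, ] - q[1, ]))
  # identical subjects -> IQR 0
  ms0 <- measurement_set(array(5, c(3, 3, 3, 2)), c("a", "b"))
  expect_equal(summarize_topography(ms0)$iqr, c(0, 0))
})

test_that("the repeatability table carries CR, CR/median and the across-region CV", {
  ms <- generate_repeatability_sessions(8, seed = 13)
  tab <- repeatability_table(ms)
  expect_equal(nrow(tab), 13)
  expect_true(all(tab$cr >= 0))
  expect_equal(tab$cr_over_median_pct, 100 * tab$cr / tab$median)
  expect_equal(attr(tab, "quartile_cv"), quartile_cv(tab$cr))
})

test_that("long-format CSV round-trips and incomplete grids are rejected", {
  ms <- generate_repeatability_sessions(3, regions = c("x", "y"), seed = 14)
  p <- tempfile(fileext = ".csv")
  write_measurements(ms, p)
  back <- read_measurements(p)
  expect_equal(back$values, ms$values)
  df <- read.csv(p)[-5, ]
  p2 <- tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE)
  expect_error(read_measurements(p2), "missing cell")
  unlink(c(p, p2))
})
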