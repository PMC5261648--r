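test_that("analysis window keeps day 98 and drops earlier scans with a reason", {
  scans <- data.frame(subject_id = c("a", "b", "c"),
                      ga_days = c(90, 98, 286),
                      bpd_mm = 30, hc_mm = 110, ac_mm = 90, fl_mm = 15,
                      hl_mm = 15)
  fl <- filter_analysis_set(scans, screen_outliers = FALSE)
  expect_identical(fl$kept$subject_id, c("b", "c"))
  expect_identical(fl$dropped$reason, "ga-window")
  expect_identical(fl$dropped$subject_id, "a")
  # day 287 is outside [14w+0d, 40w+6d]
  fl2 <- filter_analysis_set(transform(scans, ga_days = c(287, 200, 150)),
                             screen_outliers = FALSE)
  expect_identical(fl2$dropped$reason, "ga-window")
  empty <- filter_analysis_set(scans[0, ])
  expect_identical(nrow(empty$dropped), 0L)
})

test_that("the MAD screen flags exactly a grossly aberrant measurement", {
  co <- small_cohort(seed = 31, n_per_country = 15)
  scans <- filter_analysis_set(co$scans, screen_outliers = FALSE)$kept
  scans$ac_mm[57] <- scans$ac_mm[57] * 10
  fl <- filter_analysis_set(scans, screen_outliers = TRUE)
  expect_identical(nrow(fl$dropped), 1L)
  expect_identical(fl$dropped$reason, "outlier-ac")
  expect_identical(fl$dropped$subject_id, scans$subject_id[57])
})

test_that("design dimensions follow the model specification", {
  co <- small_cohort(seed = 32)
  scans <- filter_analysis_set(co$scans, screen_outliers = FALSE)$kept
  d0 <- build_design(scans, co$subjects, chart_spec("efw", ga_degree = 3))
  expect_identical(ncol(d0$x), 4L)        # intercept + cubic GA
  ds <- build_design(scans, co$subjects,
                     chart_spec("efw", covariates = "sex"))
  expect_identical(ncol(ds$x), 5L)
  dc <- build_design(scans, co$subjects,
                     chart_spec("efw", covariates = "country",
                                ga_by_country = TRUE))
  expect_identical(ncol(dc$x), 4L + 9L + 27L)   # ten countries
  expect_identical(length(d0$y), nrow(scans))
  expect_equal(d0$y, log(efw_hadlock3(scans$hc_mm, scans$ac_mm, scans$fl_mm)))
})

test_that("missing covariates name the subject and field", {
  co <- small_cohort(seed = 33)
  co$subjects$maternal_age_y[2] <- NA
  scans <- filter_analysis_set(co$scans, screen_outliers = FALSE)$kept
  err <- tryCatch(build_design(scans, co$subjects,
                               chart_spec("efw", covariates = "age")),
                  error = identity)
  expect_s3_class(err, "fg_missing_covariate")
  expect_match(conditionMessage(err), "age")
  expect_match(conditionMessage(err), co$subjects$subject_id[2])
})

test_that("non-crossing enforcement sorts within weeks, idempotently", {
  m <- rbind(c(10, 9, 11), c(1, 2, 3))
  s <- enforce_noncrossing(m)
  expect_identical(s[1, ], c(9, 10, 11))
  expect_identical(s[2, ], c(1, 2, 3))
  expect_identical(enforce_noncrossing(s), s)
  set.seed(61)
  r <- matrix(rnorm(27 * 9), 27)
  s2 <- enforce_noncrossing(r)
  expect_true(all(apply(s2, 1, function(v) !is.unsorted(v))))
  expect_identical(enforce_noncrossing(s2), s2)
})

test_that("Bowley coefficient matches the printed chart quartiles", {
  expect_equal(round(bowley_coefficient(106, 114, 124), 3), 0.111)
  expect_equal(round(bowley_coefficient(3333, 3617, 3892), 3), -0.016)
  expect_identical(bowley_coefficient(1, 2, 3), 0)
  expect_error(bowley_coefficient(2, 2, 2), class = "fg_degenerate_spread")
  expect_error(bowley_coefficient(3, 2, 1), class = "fg_invalid_parameter")
  # affine invariance with positive scale
  set.seed(62)
  q <- sort(rnorm(3))
  expect_equal(bowley_coefficient(q[1], q[2], q[3]),
               bowley_coefficient(10 + 2 * q[1], 10 + 2 * q[2], 10 + 2 * q[3]))
})

test_that("identical fetuses with zero noise give equal percentile rows", {
  cfg <- sim_config(seed = 34, n_per_country = 5, spread_scale = 0,
                    measurement_cv = 0,
                    countries = zero_country_effects(),
                    covariate_effects = zero_covariate_effects(),
                    missed_visit_rate = 0, withdrawal_rate = 0, loss_rate = 0)
  co <- simulate_cohort(cfg)
  g <- construct_chart(co$scans, co$subjects,
                       chart_spec("efw", taus = c(0.1, 0.5, 0.9)))
  expect_equal(g$values_raw[, 1], g$values_raw[, 2], tolerance = 1e-8)
  expect_equal(g$values_raw[, 2], g$values_raw[, 3], tolerance = 1e-8)
  expect_true(all(g$values_raw > 0))
  # and the single-quantile chart tracks the (monotone) base curve
  g1 <- construct_chart(co$scans, co$subjects, chart_spec("efw", taus = 0.5))
  expect_true(all(diff(g1$values_raw[, 1]) > 0))
  expect_equal(g1$values_raw[, 1],
               true_quantile(cfg, g1$weeks * 7, 0.5), tolerance = 5e-3,
               ignore_attr = TRUE)
})

test_that("fitted charts retransform positive, monotone and rounded by convention", {
  co <- small_cohort(seed = 35, n_per_country = 20)
  g <- construct_chart(co$scans, co$subjects,
                       chart_spec("efw", taus = c(0.05, 0.5, 0.95)))
  expect_true(all(g$values > 0))
  expect_true(all(apply(g$values, 1, function(v) !is.unsorted(v))))
  expect_identical(g$values, round(g$values))          # grams are integers
  gr <- construct_chart(co$scans, co$subjects,
                        chart_spec("fl_hc", taus = c(0.1, 0.9)))
  expect_identical(gr$values, round(gr$values, 2))     # ratios two decimals
  expect_s3_class(g, "growth_chart")
  df <- as.data.frame(g)
  expect_identical(names(df), c("week", "p5", "p50", "p95"))
  rep <- chart_fit_report(g)
  expect_identical(rep$n_coef, 4L)
  expect_true(all(rep$converged))
})

test_that("covariate percent effects are invariant to the GA centring constant", {
  co <- small_cohort(seed = 36, n_per_country = 15)
  scans <- filter_analysis_set(co$scans, screen_outliers = FALSE)$kept
  spec <- chart_spec("efw", covariates = "sex", taus = 0.5)
  d1 <- build_design(scans, co$subjects, spec, ga_center = 27)
  d2 <- build_design(scans, co$subjects, spec, ga_center = 20)
  f1 <- qreg_fit(d1$x, d1$y, 0.5)
  f2 <- qreg_fit(d2$x, d2$y, 0.5)
  expect_equal(coef(f1)[["sex_male"]], coef(f2)[["sex_male"]],
               tolerance = 1e-6)
})
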