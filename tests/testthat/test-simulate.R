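test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- sim_config(seed = 81, n_per_country = 10)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$scans, b$scans)
  c2 <- simulate_cohort(sim_config(seed = 82, n_per_country = 10))
  expect_false(identical(a$scans, c2$scans))
  # the caller's RNG stream is untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(simulate_cohort(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero spread, effects and noise put every scan on the base curve", {
  cfg <- sim_config(seed = 83, n_per_country = 3, spread_scale = 0,
                    measurement_cv = 0,
                    countries = zero_country_effects(),
                    covariate_effects = zero_covariate_effects(),
                    missed_visit_rate = 0, withdrawal_rate = 0, loss_rate = 0)
  co <- simulate_cohort(cfg)
  keep <- co$scans$ga_days >= 98 & co$scans$ga_days <= 286
  s <- co$scans[keep, ]
  efw <- efw_hadlock3(s$hc_mm, s$ac_mm, s$fl_mm)
  expect_equal(efw, true_quantile(cfg, s$ga_days, 0.5), tolerance = 1e-8)
  expect_equal(efw, true_quantile(cfg, s$ga_days, 0.9), tolerance = 1e-8)
})

test_that("true quantiles are strictly increasing in tau everywhere", {
  cfg <- sim_config(seed = 84)
  taus <- c(0.001, 0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99, 0.999)
  for (ga in c(98, 140, 189, 238, 286)) {
    q <- true_quantile(cfg, ga, taus)
    expect_true(all(diff(q) > 0), info = paste("ga", ga))
    qm <- true_quantile(cfg, ga, taus,
                        covariates = list(sex = "male", age = 35, height = 175,
                                          weight = 75, parity = 2),
                        country = "Norway")
    expect_true(all(diff(qm) > 0), info = paste("ga", ga, "covariates"))
    expect_true(all(qm > q))   # every configured effect is positive here
  }
  expect_error(true_quantile(cfg, 90, 0.5), class = "fg_ga_range")
  expect_error(true_quantile(cfg, 290, 0.5), class = "fg_ga_range")
})

test_that("empirical quantiles of simulated draws match the closed form", {
  cfg <- sim_config(seed = 85)
  set.seed(850)
  n <- 1e6
  ranks <- runif(n)
  draws <- true_quantile(cfg, 238, ranks)   # 34 wk, reference covariates
  for (tau in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    emp <- quantile(draws, tau, names = FALSE)
    expect_equal(emp, true_quantile(cfg, 238, tau), tolerance = 5e-3)
  }
})

test_that("the Bowley asymmetry of the true quartiles follows the configured drift", {
  cfg <- sim_config(seed = 86)
  for (wk in c(15, 20, 27, 34, 40)) {
    q <- true_quantile(cfg, wk * 7, c(0.25, 0.5, 0.75))
    target <- cfg$bowley_anchor[["at15"]] +
      (cfg$bowley_anchor[["at40"]] - cfg$bowley_anchor[["at15"]]) * (wk - 15) / 25
    expect_equal(bowley_coefficient(q[1], q[2], q[3]), unname(target),
                 tolerance = 1e-9)
  }
  # symmetric configuration: zero Bowley at every GA
  cfg0 <- sim_config(seed = 86, bowley_anchor = c(at15 = 0, at40 = 0))
  for (wk in c(15, 27, 40)) {
    q <- true_quantile(cfg0, wk * 7, c(0.25, 0.5, 0.75))
    expect_equal(bowley_coefficient(q[1], q[2], q[3]), 0, tolerance = 1e-12)
  }
})

test_that("the median truth is calibrated to the published EFW medians", {
  cfg <- sim_config(seed = 87)
  b <- who_chart_bundle()
  med <- true_quantile(cfg, (14:40) * 7, 0.5)
  expect_equal(med, unname(b$efw$values[, match(50, b$efw$percentiles)]),
               tolerance = 6e-3)
})

test_that("missingness processes thin the cohort as configured", {
  cfg <- sim_config(seed = 88, n_per_country = 100)
  co <- simulate_cohort(cfg)
  expect_setequal(unique(co$subjects$status),
                  c("completed", "withdrawn", "lost"))
  expect_equal(mean(co$subjects$status == "withdrawn"), 0.036,
               tolerance = 0.5)
  expect_false(any(co$scans$subject_id %in%
                     co$subjects$subject_id[co$subjects$status == "withdrawn"]))
  # scans per completed subject: 7 scheduled visits minus ~10% missed
  done <- co$subjects$subject_id[co$subjects$status == "completed"]
  per <- table(factor(co$scans$subject_id, levels = done))
  expect_equal(mean(per), 7 * (1 - cfg$missed_visit_rate), tolerance = 0.05)
  expect_false(any(duplicated(co$scans[c("subject_id", "ga_days")])))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(missed_visit_rate = 1.2), class = "fg_config")
  expect_error(sim_config(n_per_country = 0), class = "fg_config")
  expect_error(sim_config(visit_weeks = c(10, 20)), class = "fg_config")
  expect_error(true_quantile(sim_config(), 200, 0.5, country = "Atlantis"),
               class = "fg_unknown_stratum")
})
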