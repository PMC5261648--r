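test_that("the bundle loads, verifies its manifest and matches printed cells", {
  b <- who_chart_bundle()
  expect_s3_class(b, "chart_bundle")
  expect_length(b, 12L)
  expect_identical(chart_value("efw", 40, 50), 3617)
  expect_identical(chart_value("hc", 20, 2.5), 157)
  expect_identical(chart_value("fl", 30, 50), 56)
  expect_identical(chart_value("efw", 14, 50), 90)
  expect_identical(chart_value("efw", 15, 25), 106)
  expect_identical(chart_value("efw", 15, 75), 124)
  expect_identical(chart_value("efw", 40, 2.5), 2775)
  expect_identical(chart_value("efw", 40, 25), 3333)
  expect_identical(chart_value("efw", 37, 50, stratum = "male"), 3001)
  expect_identical(chart_value("efw", 37, 50, stratum = "female"), 2917)
  expect_identical(chart_value("efw", 40, 50, stratum = "male"), 3639)
  expect_identical(chart_value("birthweight", 40, 50, stratum = "female"), 3336)
  expect_identical(chart_value("fl_bpd", 20, 50), 0.90)
})

test_that("off-grid lookups direct the caller to interpolation", {
  expect_error(chart_value("efw", 13, 50), class = "fg_off_grid")
  expect_error(chart_value("efw", 20, 33), class = "fg_off_grid")
  expect_error(chart_value("nope", 20, 50), class = "fg_unknown_parameter")
  expect_error(who_chart("efw", "other"), class = "fg_unknown_parameter")
})

test_that("every bundled chart is monotone within weeks", {
  b <- who_chart_bundle()
  for (k in names(b))
    expect_true(all(apply(b[[k]]$values, 1, function(v) !is.unsorted(v))),
                info = k)
  # across-week monotonicity deliberately NOT asserted: the printed HL 2.5th
  # percentile decreases from week 39 to 40
  expect_lt(chart_value("hl", 40, 2.5), chart_value("hl", 39, 2.5))
})

test_that("percentile placement inverts the printed grid", {
  p <- percentile_of("efw", 3617, 280)
  expect_equal(p$percentile, 50)
  expect_equal(p$z_equivalent, 0)
  expect_identical(p$flag, "in_range")
  p2 <- percentile_of("efw", 2000, 280)
  expect_identical(p2$flag, "below_min")
  expect_equal(p2$percentile, 2.5)
  p3 <- percentile_of("efw", 3475, 280)        # midway between p25 and p50
  expect_equal(p3$percentile, 37.5)
  p4 <- percentile_of("efw", 6000, 280)
  expect_identical(p4$flag, "above_max")
  expect_equal(p4$percentile, 97.5)
  expect_error(percentile_of("efw", 500, 97), class = "fg_ga_range")
  expect_error(percentile_of("efw", 500, 287), class = "fg_ga_range")
})

test_that("round trip value -> percentile recovers the grid where it is invertible", {
  b <- who_chart_bundle()
  for (k in c("efw", "hc", "ac", "efw_male", "birthweight_female")) {
    ch <- b[[k]]
    for (i in seq_along(ch$weeks)) {
      row <- ch$values[i, ]
      for (j in seq_along(ch$percentiles)) {
        pl <- percentile_of(ch$parameter, row[j], ch$weeks[i] * 7,
                            stratum = ch$stratum)
        tied <- which(row == row[j])
        if (length(tied) == 1L) {
          expect_equal(pl$percentile, ch$percentiles[j], tolerance = 1e-9)
        } else {
          # ties from integer printing: the midpoint of the tied range
          expect_equal(pl$percentile, mean(ch$percentiles[tied]),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("placement is non-decreasing in the measured value", {
  vals <- seq(2500, 4600, by = 100)
  ps <- vapply(vals, function(v) percentile_of("efw", v, 280)$percentile,
               numeric(1))
  expect_true(all(diff(ps) >= 0))
  # GA interpolation between week rows stays between the row placements
  mid <- percentile_of("efw", 3000, 270)$percentile
  lo <- percentile_of("efw", 3000, 266)$percentile
  hi <- percentile_of("efw", 3000, 273)$percentile
  expect_true(mid <= max(lo, hi) && mid >= min(lo, hi))
  # snapping to completed weeks reproduces the exact-row inversion
  snap <- percentile_of("efw", 3617, 283, snap_weeks = TRUE)
  expect_equal(snap$percentile, 50)
})

test_that("a corrupted bundle file fails the checksum", {
  src <- system.file("extdata", "who", package = "fetalgrowth")
  tmp <- file.path(tempdir(), "who_bad")
  dir.create(tmp, showWarnings = FALSE)
  file.copy(list.files(src, full.names = TRUE), tmp, overwrite = TRUE)
  man <- file.path(tmp, "MANIFEST.md5")
  lines <- readLines(man)
  lines[1] <- sub("^.", ifelse(substr(lines[1], 1, 1) == "0", "1", "0"),
                  lines[1])
  writeLines(lines, man)
  got <- tools::md5sum(file.path(tmp, "who_fgc_ac.csv"))
  expect_false(grepl(got, lines[1], fixed = TRUE))
})

test_that("aggregate study rates reproduce the printed totals", {
  r <- study_rates()
  expect_identical(r$recruited, 1439L)
  expect_identical(sum(r$enrolment$consent_withdrawal), 52L)
  expect_identical(sum(r$preterm$preterm), 99L)
  expect_identical(sum(r$preterm$births), 1312L)
  expect_identical(r$withdrawal_pct, 3.6)
  expect_identical(r$preterm_pct, 7.5)
  expect_identical(r$lost_pct, 3.2)
  expect_identical(r$miscarriage_pct, 2.4)
})
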