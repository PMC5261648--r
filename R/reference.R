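# Bundled WHO fetal growth charts (ultrasound biometry, EFW overall and by
# fetal sex, head ratios, and birthweight by neonatal sex) with integrity
# checking and clinical percentile lookup.

fg_cache <- new.env(parent = emptyenv())

bundle_keys <- function() {
  c("bpd", "hc", "ac", "fl", "hl", "efw", "fl_hc", "fl_bpd",
    "efw_female", "efw_male", "birthweight_female", "birthweight_male")
}

key_parts <- function(key) {
  if (grepl("_(female|male)$", key)) {
    list(parameter = sub("_(female|male)$", "", key),
         stratum = sub("^.*_(female|male)$", "\\1", key))
  } else list(parameter = key, stratum = NULL)
}

#' Load the bundled WHO growth-chart tables
#'
#' Reads the packaged CSV copies of the published weekly percentile tables
#' (BPD, HC, AC, FL, HL, EFW overall and by fetal sex, FL/HC, FL/BPD on
#' weeks 14-40; birthweight by neonatal sex on weeks 37-42) and returns them
#' as \code{"growth_chart"} objects keyed by parameter and stratum.  File
#' integrity is verified against an MD5 manifest.
#'
#' @param verify check the MD5 manifest (default TRUE).
#' @return Object of class \code{"chart_bundle"}: a named list of charts
#'   plus a \code{version} attribute.
#' @export
who_chart_bundle <- function(verify = TRUE) {
  cache_key <- paste0("bundle_", verify)
  if (!is.null(fg_cache[[cache_key]])) return(fg_cache[[cache_key]])
  dir <- system.file("extdata", "who", package = "fetalgrowth")
  if (verify) {
    man <- read.table(file.path(dir, "MANIFEST.md5"), col.names = c("md5", "file"),
                      stringsAsFactors = FALSE)
    got <- tools::md5sum(file.path(dir, man$file))
    bad <- man$file[is.na(got) | got != man$md5]
    if (length(bad))
      fg_stop("fg_integrity", "bundled chart checksum mismatch: %s",
              paste(bad, collapse = ", "))
  }
  charts <- list()
  for (key in bundle_keys()) {
    f <- file.path(dir, sprintf("who_fgc_%s.csv", key))
    d <- utils::read.csv(f, check.names = FALSE)
    pcts <- as.numeric(sub("^p", "", names(d)[-1]))
    vals <- as.matrix(d[-1])
    storage.mode(vals) <- "double"
    kp <- key_parts(key)
    charts[[key]] <- new_growth_chart(kp$parameter, d$week, pcts, vals,
                                      provenance = "bundled-WHO",
                                      stratum = kp$stratum)
  }
  out <- structure(charts, version = "WHO fetal growth charts (2017 tables)",
                   class = "chart_bundle")
  fg_cache[[cache_key]] <- out
  out
}

#' @export
print.chart_bundle <- function(x, ...) {
  cat(attr(x, "version"), "\n")
  for (k in names(x))
    cat(sprintf("  %-18s weeks %d-%d, percentiles %s\n", k, min(x[[k]]$weeks),
                max(x[[k]]$weeks), paste(x[[k]]$percentiles, collapse = "/")))
  invisible(x)
}

#' Retrieve one bundled chart
#'
#' @param parameter chart parameter (bpd, hc, ac, fl, hl, efw, fl_hc,
#'   fl_bpd, birthweight).
#' @param stratum optional stratum ("female"/"male" for the sex-specific EFW
#'   and birthweight charts).
#' @param bundle a [who_chart_bundle()].
#' @return The \code{"growth_chart"}.
#' @export
who_chart <- function(parameter, stratum = NULL, bundle = who_chart_bundle()) {
  key <- if (is.null(stratum)) parameter else paste(parameter, stratum, sep = "_")
  if (!key %in% names(bundle))
    fg_stop("fg_unknown_parameter", "no bundled chart '%s'", key)
  bundle[[key]]
}

#' Exact table-cell lookup
#'
#' Returns the printed cell of a bundled chart at an on-grid week and
#' percentile; no interpolation is performed (use [percentile_of()] for
#' continuous placement).
#'
#' @inheritParams who_chart
#' @param week completed gestational week on the chart grid.
#' @param percentile percentile on the chart grid.
#' @return The table value (mm, g, or unit-free ratio).
#' @examples
#' chart_value("efw", 40, 50)        # 3617 g
#' chart_value("hc", 20, 2.5)        # 157 mm
#' @export
chart_value <- function(parameter, week, percentile, stratum = NULL,
                        bundle = who_chart_bundle()) {
  ch <- who_chart(parameter, stratum, bundle)
  i <- match(week, ch$weeks)
  j <- match(percentile, ch$percentiles)
  if (is.na(i) || is.na(j))
    fg_stop("fg_off_grid",
            "week %s / percentile %s is off the chart grid (weeks %d-%d, percentiles %s); use percentile_of() for interpolation",
            week, percentile, min(ch$weeks), max(ch$weeks),
            paste(ch$percentiles, collapse = "/"))
  unname(ch$values[i, j])
}

#' Percentile placement of a measurement against a chart
#'
#' Places an observed value on a reference chart at its gestational age:
#' linear interpolation in GA between adjacent week rows, then monotone
#' piecewise-linear inversion of value against percentile.  Values below the
#' lowest or above the highest printed curve are clamped to the boundary
#' percentile and flagged rather than extrapolated.  Where adjacent printed
#' percentile columns are tied (integer rounding of the published tables),
#' the midpoint of the tied percentile range is returned.  The normal
#' z-equivalent \eqn{\Phi^{-1}(p/100)} is attached purely as a reporting
#' convenience; the charts themselves are distribution-free.
#'
#' @inheritParams who_chart
#' @param value observed measurement (same unit as the chart).
#' @param ga_days gestational age in days.
#' @param snap_weeks if TRUE, snap to the completed-week row instead of
#'   interpolating in GA.
#' @return Object of class \code{"percentile_placement"}: percentile,
#'   z_equivalent, flag ("in_range", "below_min", "above_max"), and context.
#' @examples
#' percentile_of("efw", 3617, 280)   # 50th percentile at exactly week 40
#' @export
percentile_of <- function(parameter, value, ga_days, stratum = NULL,
                          bundle = who_chart_bundle(), snap_weeks = FALSE) {
  ch <- who_chart(parameter, stratum, bundle)
  lo <- min(ch$weeks) * 7
  hi <- max(ch$weeks) * 7 + 6
  if (!is.finite(ga_days) || ga_days < lo || ga_days > hi)
    fg_stop("fg_ga_range", "ga_days = %s outside the chart range [%d, %d]",
            ga_days, lo, hi)
  gw <- ga_days / 7
  if (snap_weeks) gw <- floor(gw)
  gw <- min(gw, max(ch$weeks))   # days within the last completed week
  i0 <- max(which(ch$weeks <= gw))
  if (i0 == length(ch$weeks)) {
    row <- ch$values[i0, ]
  } else {
    f <- (gw - ch$weeks[i0]) / (ch$weeks[i0 + 1] - ch$weeks[i0])
    row <- (1 - f) * ch$values[i0, ] + f * ch$values[i0 + 1, ]
  }
  pcts <- ch$percentiles
  if (value <= row[1]) {
    p <- pcts[1]
    flag <- if (value < row[1]) "below_min" else "in_range"
  } else if (value >= row[length(row)]) {
    p <- pcts[length(pcts)]
    flag <- if (value > row[length(row)]) "above_max" else "in_range"
  } else {
    p <- stats::approx(row, pcts, xout = value, ties = mean)$y
    flag <- "in_range"
  }
  structure(list(percentile = unname(p),
                 z_equivalent = stats::qnorm(p / 100),
                 flag = flag, parameter = parameter, stratum = stratum,
                 ga_days = ga_days, value = value),
            class = "percentile_placement")
}

#' @export
print.percentile_placement <- function(x, ...) {
  cat(sprintf("%s%s = %s at %d d (%.1f wk): percentile %.1f (z = %.2f)%s\n",
              x$parameter,
              if (!is.null(x$stratum)) paste0("[", x$stratum, "]") else "",
              format(x$value), as.integer(x$ga_days), x$ga_days / 7,
              x$percentile, x$z_equivalent,
              if (x$flag != "in_range") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Overall study rates from the bundled enrolment and outcome counts
#'
#' Aggregates the bundled per-country recruitment table (enrolment,
#' consent withdrawal, loss to follow-up, miscarriage/intrauterine death)
#' and preterm-birth counts into overall percentages, rounded to one
#' decimal as printed.
#'
#' @return List with the per-country tables and the overall
#'   \code{withdrawal_pct}, \code{lost_pct}, \code{miscarriage_pct} and
#'   \code{preterm_pct}.
#' @export
study_rates <- function() {
  dir <- system.file("extdata", "study", package = "fetalgrowth")
  enr <- utils::read.csv(file.path(dir, "enrolment.csv"))
  pre <- utils::read.csv(file.path(dir, "preterm.csv"))
  list(enrolment = enr, preterm = pre,
       recruited = sum(enr$recruited),
       withdrawal_pct = round(100 * sum(enr$consent_withdrawal) /
                                sum(enr$recruited), 1),
       lost_pct = round(100 * sum(enr$lost_follow_up) / sum(enr$recruited), 1),
       miscarriage_pct = round(100 * sum(enr$miscarriage_iud) /
                                 sum(enr$recruited), 1),
       preterm_pct = round(100 * sum(pre$preterm) / sum(pre$births), 1))
}
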