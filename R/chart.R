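# Chart construction: analysis-set filtering, log-scale polynomial quantile
# regression (optionally with covariates and GA-by-country interactions),
# weekly-grid evaluation, retransformation, non-crossing, rounding.

FG_PARAMETERS <- c("bpd", "hc", "ac", "fl", "hl", "efw", "fl_hc", "fl_bpd",
                   "birthweight")
FG_DEFAULT_TAUS <- c(0.01, 0.025, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95,
                     0.975, 0.99)
FG_COVARIATES <- c("sex", "age", "height", "weight", "parity", "country", "bmi")
FG_GA_WINDOW <- c(98L, 286L)   # [14w+0d, 40w+6d]
FG_GA_CENTER <- 27             # weeks; centring before polynomial expansion

parameter_unit <- function(parameter) {
  switch(parameter,
         bpd = , hc = , ac = , fl = , hl = "mm",
         efw = , birthweight = "g",
         fl_hc = , fl_bpd = "",
         fg_stop("fg_unknown_parameter", "unknown parameter '%s'", parameter))
}

round_chart_values <- function(values, parameter) {
  switch(parameter_unit(parameter),
         mm = round(values),
         g = round(values),
         round(values, 2L))
}

#' Specification of a quantile-regression growth-chart model
#'
#' @param response parameter to model: one of bpd, hc, ac, fl, hl, efw,
#'   fl_hc, fl_bpd, birthweight.  Ultrasound parameters and EFW are modelled
#'   on the log scale and retransformed.
#' @param ga_degree degree of the gestational-age polynomial (default 3:
#'   linear, quadratic and cubic terms).
#' @param covariates character subset of sex, age, height, weight, parity,
#'   country, bmi, entered additively.
#' @param ga_by_country logical; include interaction terms between the GA
#'   polynomial and the country indicators (requires "country" among the
#'   covariates).
#' @param taus strictly increasing quantile levels; the default grid spans
#'   the published percentile columns and figure percentiles.
#' @return List of class \code{"chart_spec"}.
#' @export
chart_spec <- function(response = "efw", ga_degree = 3L,
                       covariates = character(), ga_by_country = FALSE,
                       taus = FG_DEFAULT_TAUS) {
  response <- match.arg(response, FG_PARAMETERS)
  if (!is.numeric(ga_degree) || ga_degree < 1L)
    fg_stop("fg_invalid_parameter", "`ga_degree` must be at least 1")
  bad <- setdiff(covariates, FG_COVARIATES)
  if (length(bad))
    fg_stop("fg_invalid_parameter", "unknown covariate(s): %s",
            paste(bad, collapse = ", "))
  if (ga_by_country && !"country" %in% covariates)
    fg_stop("fg_invalid_parameter",
            "`ga_by_country` requires 'country' among the covariates")
  check_tau(taus, several = TRUE)
  if (anyDuplicated(taus) || is.unsorted(taus))
    fg_stop("fg_invalid_parameter", "`taus` must be strictly increasing")
  structure(list(response = response, ga_degree = as.integer(ga_degree),
                 covariates = covariates, ga_by_country = ga_by_country,
                 taus = taus),
            class = "chart_spec")
}

#' Select the analysis set of scans
#'
#' Keeps scans inside the gestational-age analysis window (days 98 to 286,
#' i.e. 14w+0d to 40w+6d, so the scheduled week-40 visit is retained) and
#' optionally screens outliers per biometric parameter: within 2-week GA
#' bins a scan is flagged when its log measurement deviates from the bin
#' median by more than \code{k} times the bin MAD.
#'
#' @param scans scans data frame (must carry \code{ga_days}).
#' @param ga_window integer GA window in days, inclusive.
#' @param screen_outliers logical; apply the MAD rule.
#' @param k MAD multiplier (default 5).
#' @param parameters measurement columns screened (without the \code{_mm}
#'   suffix handled automatically).
#' @return List with \code{kept} (scans data frame) and \code{dropped}
#'   (data frame of subject_id, ga_days and a machine-readable reason).
#' @export
filter_analysis_set <- function(scans, ga_window = FG_GA_WINDOW,
                                screen_outliers = TRUE, k = 5,
                                parameters = c("bpd", "hc", "ac", "fl", "hl")) {
  empty_drop <- data.frame(subject_id = character(), ga_days = integer(),
                           reason = character(), stringsAsFactors = FALSE)
  if (is.null(scans) || nrow(scans) == 0L)
    return(list(kept = scans, dropped = empty_drop))
  drop_reason <- rep(NA_character_, nrow(scans))
  in_window <- scans$ga_days >= ga_window[1] & scans$ga_days <= ga_window[2]
  drop_reason[!in_window] <- "ga-window"
  if (screen_outliers) {
    bin <- floor((scans$ga_days / 7 - 14) / 2)
    for (par in parameters) {
      col <- paste0(par, "_mm")
      if (!col %in% names(scans)) next
      lv <- log(scans[[col]])
      for (b in unique(bin[in_window])) {
        sel <- which(bin == b & in_window & is.na(drop_reason))
        if (length(sel) < 10L) next   # a MAD from fewer scans is too noisy
        med <- stats::median(lv[sel])
        s <- stats::mad(lv[sel])
        if (!is.finite(s) || s <= 0) next
        out <- sel[abs(lv[sel] - med) > k * s]
        drop_reason[out] <- paste0("outlier-", par)
      }
    }
  }
  keep <- is.na(drop_reason)
  dropped <- data.frame(subject_id = scans$subject_id[!keep],
                        ga_days = scans$ga_days[!keep],
                        reason = drop_reason[!keep],
                        stringsAsFactors = FALSE)
  list(kept = scans[keep, , drop = FALSE], dropped = dropped)
}

response_values <- function(scans, response) {
  col <- switch(response,
                bpd = "bpd_mm", hc = "hc_mm", ac = "ac_mm", fl = "fl_mm",
                hl = "hl_mm", efw = "efw_g", fl_hc = "fl_hc",
                fl_bpd = "fl_bpd", birthweight = "birthweight_g")
  if (!col %in% names(scans)) scans <- add_derived_biometry(scans)
  if (!col %in% names(scans))
    fg_stop("fg_missing_measurement", "no column '%s' for response '%s'",
            col, response)
  scans[[col]]
}

# Polynomial GA block at centred week values t; named columns ga1..gaD.
ga_poly <- function(t, degree) {
  m <- outer(t, seq_len(degree), `^`)
  colnames(m) <- paste0("ga", seq_len(degree))
  m
}

#' Build the quantile-regression design matrix for a chart model
#'
#' The response is the natural log of the parameter; gestational age is
#' expressed in weeks (\code{ga_days/7}), centred at 27 weeks before
#' polynomial expansion; country enters as indicators against the first
#' level; GA-by-country interactions multiply each GA polynomial term with
#' each non-reference country indicator.
#'
#' @param scans scans data frame.
#' @param subjects subjects data frame (required when the spec uses maternal
#'   covariates, fetal sex or country).
#' @param spec a [chart_spec()].
#' @param ga_center centring constant in weeks.
#' @return List with the design matrix \code{x}, log-scale response \code{y},
#'   and metadata (\code{ga_center}, \code{country_levels}, \code{spec}).
#' @export
build_design <- function(scans, subjects = NULL, spec = chart_spec(),
                         ga_center = FG_GA_CENTER) {
  stopifnot(inherits(spec, "chart_spec"))
  val <- response_values(scans, spec$response)
  if (any(!is.finite(val) | val <= 0))
    fg_stop("fg_invalid_measurement",
            "non-positive response values cannot be log-transformed")
  y <- log(val)
  t <- scans$ga_days / 7 - ga_center
  x <- cbind(`(Intercept)` = 1, ga_poly(t, spec$ga_degree))

  country_levels <- NULL
  if (length(spec$covariates)) {
    if (is.null(subjects))
      fg_stop("fg_missing_covariate",
              "covariates requested but no subjects table given")
    idx <- match(scans$subject_id, subjects$subject_id)
    if (anyNA(idx))
      fg_stop("fg_integrity", "scans reference unknown subjects: %s",
              paste(unique(scans$subject_id[is.na(idx)]), collapse = ", "))
    sub <- subjects[idx, , drop = FALSE]
    need_col <- function(col, covariate) {
      v <- sub[[col]]
      if (is.null(v) || anyNA(v)) {
        bad <- if (is.null(v)) scans$subject_id else scans$subject_id[is.na(v)]
        fg_stop("fg_missing_covariate",
                "covariate '%s' (column %s) missing for subject(s): %s",
                covariate, col, paste(unique(bad)[1:min(5, length(unique(bad)))],
                                      collapse = ", "))
      }
      v
    }
    for (cv in spec$covariates) {
      x <- switch(cv,
        sex = cbind(x, sex_male =
                      as.numeric(need_col("fetal_sex", "sex") == "male")),
        age = cbind(x, age = need_col("maternal_age_y", "age")),
        height = cbind(x, height = need_col("height_cm", "height")),
        weight = cbind(x, weight = need_col("weight_kg", "weight")),
        bmi = cbind(x, bmi = need_col("weight_kg", "bmi") /
                      (need_col("height_cm", "bmi") / 100)^2),
        parity = cbind(x, parous =
                         as.numeric(need_col("parity", "parity") >= 1)),
        country = {
          co <- factor(need_col("country", "country"))
          country_levels <- levels(co)
          ind <- stats::model.matrix(~ co)[, -1, drop = FALSE]
          colnames(ind) <- paste0("country:", country_levels[-1])
          cbind(x, ind)
        })
    }
    if (spec$ga_by_country) {
      co <- factor(sub$country, levels = country_levels)
      ind <- stats::model.matrix(~ co)[, -1, drop = FALSE]
      gp <- ga_poly(t, spec$ga_degree)
      for (j in seq_len(ncol(ind))) {
        inter <- gp * ind[, j]
        colnames(inter) <- paste0("ga", seq_len(spec$ga_degree), ":country:",
                                  country_levels[-1][j])
        x <- cbind(x, inter)
      }
    }
  }
  list(x = x, y = y, ga_center = ga_center, country_levels = country_levels,
       spec = spec)
}

new_growth_chart <- function(parameter, weeks, percentiles, values,
                             provenance, stratum = NULL, values_raw = NULL,
                             fits = NULL, design_info = NULL, dropped = NULL) {
  dimnames(values) <- list(week = weeks, percentile = percentiles)
  structure(
    list(parameter = parameter, unit = parameter_unit(parameter),
         weeks = as.integer(weeks), percentiles = as.numeric(percentiles),
         values = values, values_raw = values_raw, provenance = provenance,
         stratum = stratum, fits = fits, design_info = design_info,
         dropped = dropped),
    class = "growth_chart")
}

row_sort <- function(m) {
  if (ncol(m) <= 1L) return(m)   # a single percentile is trivially monotone
  t(apply(m, 1L, sort))
}

#' Enforce within-week percentile monotonicity
#'
#' Rearranges (sorts) the values across percentiles within each week.
#' Idempotent, and bit-identical on charts that are already monotone; this
#' is the standard rearrangement remedy for quantile crossing, applied after
#' retransformation.
#'
#' @param chart a \code{"growth_chart"} (or a plain week-by-percentile
#'   matrix).
#' @return Object of the same type with non-decreasing rows.
#' @export
enforce_noncrossing <- function(chart) {
  if (is.matrix(chart)) return(row_sort(chart))
  stopifnot(inherits(chart, "growth_chart"))
  chart$values <- row_sort(chart$values)
  dimnames(chart$values) <- list(week = chart$weeks,
                                 percentile = chart$percentiles)
  if (!is.null(chart$values_raw))
    chart$values_raw <- row_sort(chart$values_raw)
  chart
}

#' Bowley quartile coefficient of asymmetry
#'
#' \eqn{((Q_3 - Q_2) - (Q_2 - Q_1)) / (Q_3 - Q_1)}: the difference of the
#' semi-quartile ranges relative to the quartile range.  Zero for symmetric
#' quartiles, positive for right skew, and invariant to positive affine
#' transformation of the quartiles.
#'
#' @param q25,q50,q75 the three quartiles (vectorised).
#' @return Coefficient(s) in \eqn{[-1, 1]}.
#' @examples
#' bowley_coefficient(106, 114, 124)      # +0.111..., right skew
#' bowley_coefficient(3333, 3617, 3892)   # -0.016..., slight left skew
#' @export
bowley_coefficient <- function(q25, q50, q75) {
  if (any(q25 > q50) || any(q50 > q75))
    fg_stop("fg_invalid_parameter", "quartiles must satisfy q25 <= q50 <= q75")
  if (any(q25 == q75))
    fg_stop("fg_degenerate_spread", "zero quartile range: q25 equals q75")
  ((q75 - q50) - (q50 - q25)) / (q75 - q25)
}

#' Construct a growth chart by quantile regression
#'
#' The full chart pipeline: restrict to the analysis window (optionally
#' screening outliers), fit polynomial quantile regressions to the log
#' parameter at every requested level, evaluate the fitted curves at exact
#' completed-week boundaries, retransform by exponentiation, enforce
#' within-week non-crossing, and round to the publication convention
#' (integer mm, integer grams, two decimals for ratios).
#'
#' @param scans scans data frame.
#' @param subjects subjects data frame (needed when covariates are used).
#' @param spec a [chart_spec()].
#' @param weeks integer week grid for evaluation.
#' @param at named list of covariate values at which curves are evaluated
#'   when the model has covariates: any of \code{sex} ("female"/"male"),
#'   \code{age}, \code{height}, \code{weight}, \code{bmi}, \code{parity},
#'   \code{country} (a level name, or "global" for the equal-weight average
#'   over countries, the default).  Unspecified covariates sit at the
#'   reference (female, nulliparous, study median maternal size).
#' @param filter logical; apply [filter_analysis_set()] first.
#' @param screen_outliers passed to the filter (off by default here so that
#'   chart construction on clean simulated cohorts is exactly reproducible;
#'   enable for raw field data).
#' @param ... passed to [qreg_fit()].
#' @return A \code{"growth_chart"} with the rounded \code{values}, the
#'   unrounded \code{values_raw}, the underlying \code{"qreg_set"} in
#'   \code{$fits}, the design metadata in \code{$design_info} and the
#'   dropped-scan log in \code{$dropped}.
#' @export
construct_chart <- function(scans, subjects = NULL, spec = chart_spec(),
                            weeks = 14:40, at = list(), filter = TRUE,
                            screen_outliers = FALSE, ...) {
  dropped <- NULL
  if (filter) {
    fl <- filter_analysis_set(scans, screen_outliers = screen_outliers)
    scans <- fl$kept
    dropped <- fl$dropped
  }
  if (is.null(scans) || nrow(scans) == 0L)
    fg_stop("fg_invalid_parameter", "analysis set is empty")
  d <- build_design(scans, subjects, spec)
  if (nrow(d$x) < 50 * ncol(d$x))
    warning(sprintf("only %d scans for %d design columns (< 50 per column)",
                    nrow(d$x), ncol(d$x)), call. = FALSE)
  fits <- qreg_fit_set(d$x, d$y, spec$taus, ...)
  xg <- evaluation_rows(weeks, d, at)
  pred <- sapply(fits, function(f) drop(xg %*% f$coefficients))
  raw <- row_sort(exp(matrix(pred, nrow = length(weeks))))
  values <- round_chart_values(raw, spec$response)
  stratum <- if (length(at)) paste(names(at), unlist(at), sep = "=",
                                   collapse = ",") else NULL
  new_growth_chart(spec$response, weeks, spec$taus * 100, values,
                   provenance = "fitted", stratum = stratum,
                   values_raw = raw, fits = fits, design_info = d,
                   dropped = dropped)
}

# Design rows for evaluating a fitted chart model on a week grid, holding
# covariates at reference (or user-supplied) values.  `country = "global"`
# averages the country indicator block with equal weights.
evaluation_rows <- function(weeks, design, at = list()) {
  spec <- design$spec
  t <- weeks - design$ga_center
  x <- cbind(`(Intercept)` = 1, ga_poly(t, spec$ga_degree))
  ref <- list(sex = "female", age = 28, height = 163, weight = 61,
              bmi = 23.1, parity = 0, country = "global")
  at <- utils::modifyList(ref, at)
  nlev <- length(design$country_levels)
  country_w <- NULL
  if ("country" %in% spec$covariates) {
    if (identical(at$country, "global")) {
      country_w <- rep(1 / nlev, nlev - 1L)
    } else {
      j <- match(at$country, design$country_levels)
      if (is.na(j))
        fg_stop("fg_unknown_stratum", "country '%s' is not in the model",
                at$country)
      country_w <- as.numeric(seq_len(nlev - 1L) == (j - 1L))
    }
  }
  for (cv in spec$covariates) {
    x <- switch(cv,
      sex = cbind(x, sex_male = as.numeric(at$sex == "male")),
      age = cbind(x, age = at$age),
      height = cbind(x, height = at$height),
      weight = cbind(x, weight = at$weight),
      bmi = cbind(x, bmi = at$bmi),
      parity = cbind(x, parous = as.numeric(at$parity >= 1)),
      country = {
        ind <- matrix(country_w, nrow = length(weeks), ncol = nlev - 1L,
                      byrow = TRUE)
        colnames(ind) <- paste0("country:", design$country_levels[-1])
        cbind(x, ind)
      })
  }
  if (spec$ga_by_country) {
    gp <- ga_poly(t, spec$ga_degree)
    for (j in seq_len(nlev - 1L)) {
      inter <- gp * country_w[j]
      colnames(inter) <- paste0("ga", seq_len(spec$ga_degree), ":country:",
                                design$country_levels[-1][j])
      x <- cbind(x, inter)
    }
  }
  x
}

#' @export
print.growth_chart <- function(x, ...) {
  cat(sprintf("Growth chart: %s%s [%s], weeks %d-%d, %s\n",
              x$parameter,
              if (!is.null(x$stratum)) paste0(" (", x$stratum, ")") else "",
              if (nzchar(x$unit)) x$unit else "ratio",
              min(x$weeks), max(x$weeks), x$provenance))
  print(utils::head(x$values, 6L), ...)
  if (length(x$weeks) > 6L) cat("...", length(x$weeks) - 6L, "more weeks\n")
  invisible(x)
}

#' @export
as.data.frame.growth_chart <- function(x, ...) {
  d <- data.frame(week = x$weeks, x$values, check.names = FALSE)
  names(d) <- c("week", paste0("p", x$percentiles))
  rownames(d) <- NULL
  d
}

#' @export
plot.growth_chart <- function(x, ...) {
  graphics::matplot(x$weeks, x$values, type = "l", lty = 1,
                    xlab = "Gestational age (completed weeks)",
                    ylab = paste0(x$parameter,
                                  if (nzchar(x$unit)) paste0(" (", x$unit, ")")),
                    main = sprintf("%s percentiles (%s)", x$parameter,
                                   x$provenance), ...)
  graphics::text(max(x$weeks), x$values[nrow(x$values), ],
                 labels = x$percentiles, pos = 4, cex = 0.7, xpd = NA)
  invisible(x)
}

#' Export a growth chart as CSV
#'
#' One row per week, one column per percentile (ascending), with a header
#' comment naming parameter, unit, stratum and provenance.
#'
#' @param chart a \code{"growth_chart"}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_chart_csv <- function(chart, path) {
  stopifnot(inherits(chart, "growth_chart"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# parameter: %s; unit: %s; stratum: %s; provenance: %s",
                     chart$parameter,
                     if (nzchar(chart$unit)) chart$unit else "ratio",
                     chart$stratum %||% "none", chart$provenance), con)
  utils::write.csv(as.data.frame(chart), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit report for a constructed chart
#'
#' Machine-readable log of the fit: quantile levels, coefficient counts,
#' objective values, convergence and dropped-scan reasons.
#'
#' @param chart a fitted \code{"growth_chart"}.
#' @param path optional path; when given the report is written as JSON.
#' @return The report list, invisibly when written.
#' @export
chart_fit_report <- function(chart, path = NULL) {
  stopifnot(inherits(chart, "growth_chart"))
  if (is.null(chart$fits))
    fg_stop("fg_invalid_parameter", "chart carries no fits (bundled chart?)")
  rep <- list(
    parameter = chart$parameter,
    taus = attr(chart$fits, "taus"),
    n_obs = chart$fits[[1]]$n_obs,
    n_coef = length(chart$fits[[1]]$coefficients),
    objectives = vapply(chart$fits, `[[`, numeric(1), "objective"),
    iterations = vapply(chart$fits, `[[`, integer(1), "iterations"),
    converged = vapply(chart$fits, `[[`, logical(1), "converged"),
    dropped = if (!is.null(chart$dropped) && nrow(chart$dropped))
      as.list(table(chart$dropped$reason)) else NULL)
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"), path)
    return(invisible(rep))
  }
  rep
}
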