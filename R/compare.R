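# Country-versus-global and covariate-effect analyses on fitted charts.

#' Quantile-quantile comparison of two growth charts
#'
#' For each common percentile level, pairs the two charts' values across the
#' shared week grid — the data behind a QQ plot.  Identical charts give
#' pairs on the diagonal; a chart scaled by a constant factor gives pairs on
#' a line through the origin with that slope.
#'
#' @param chart_a,chart_b \code{"growth_chart"} objects sharing parameter
#'   and week grid.
#' @param taus optional quantile levels (in (0,1)) to restrict to; default
#'   all common percentile levels.
#' @return Data frame with columns tau, week, value_a, value_b.
#' @export
qq_compare <- function(chart_a, chart_b, taus = NULL) {
  stopifnot(inherits(chart_a, "growth_chart"), inherits(chart_b, "growth_chart"))
  if (!identical(chart_a$parameter, chart_b$parameter))
    fg_stop("fg_incompatible_charts", "charts measure different parameters (%s vs %s)",
            chart_a$parameter, chart_b$parameter)
  if (!identical(chart_a$weeks, chart_b$weeks))
    fg_stop("fg_incompatible_charts", "charts have different week grids")
  pcts <- intersect(chart_a$percentiles, chart_b$percentiles)
  if (!is.null(taus)) {
    check_tau(taus, several = TRUE)
    want <- taus * 100
    if (!all(want %in% pcts))
      fg_stop("fg_incompatible_charts",
              "percentile(s) %s not present in both charts",
              paste(setdiff(want, pcts), collapse = ", "))
    pcts <- want
  }
  if (!length(pcts))
    fg_stop("fg_incompatible_charts", "charts share no percentile levels")
  va <- chart_a$values_raw %||% chart_a$values
  vb <- chart_b$values_raw %||% chart_b$values
  out <- do.call(rbind, lapply(pcts, function(p) {
    ia <- match(p, chart_a$percentiles); ib <- match(p, chart_b$percentiles)
    data.frame(tau = p / 100, week = chart_a$weeks,
               value_a = unname(va[, ia]), value_b = unname(vb[, ib]))
  }))
  rownames(out) <- NULL
  out
}

# A single fitted-country design row and the equal-weight global row for a
# chart fitted with country indicators (and optionally GA interactions).
country_rows <- function(chart, country, week) {
  d <- chart$design_info
  if (is.null(d) || is.null(d$country_levels))
    fg_stop("fg_unknown_stratum",
            "chart was not fitted with country in the model")
  if (!country %in% d$country_levels)
    fg_stop("fg_unknown_stratum", "country '%s' is not in the model", country)
  list(xc = evaluation_rows(week, d, at = list(country = country)),
       xg = evaluation_rows(week, d, at = list(country = "global")))
}

#' Confidence interval for a country-minus-global percentile difference
#'
#' From a chart fitted jointly with country indicators and GA-by-country
#' interaction terms, estimates the difference between the retransformed
#' fitted percentile for one country and the all-countries (equal-weight
#' average) fitted percentile at given weeks, with a delta-method standard
#' error on the linear contrast of log-scale coefficients and normal 95%
#' bounds.  The estimates rest on the asymptotic normality of the
#' quantile-regression coefficients.
#'
#' Note: with ten countries and several weeks and levels, the multiplicity
#' of inferences implies that the simultaneous confidence is much lower than
#' the nominal 95%; no multiple-testing adjustment is applied.
#'
#' @param chart a \code{"growth_chart"} from [construct_chart()] whose spec
#'   included country (and usually \code{ga_by_country}).
#' @param country country level to contrast against the global curve.
#' @param week integer week(s) at which to evaluate.
#' @param tau quantile level; must be one of the fitted levels.
#' @param conf confidence level (default 0.95).
#' @return Data frame with columns tau, week, country, estimate, se,
#'   ci_low, ci_high (response units, e.g. grams for EFW).
#' @export
percentile_difference_ci <- function(chart, country, week, tau, conf = 0.95) {
  stopifnot(inherits(chart, "growth_chart"))
  check_tau(tau)
  taus <- attr(chart$fits, "taus")
  k <- match(tau, taus)
  if (is.na(k))
    fg_stop("fg_invalid_parameter", "tau = %g was not fitted (levels: %s)",
            tau, paste(taus, collapse = ", "))
  fit <- chart$fits[[k]]
  rows <- country_rows(chart, country, week)
  v <- qreg_vcov(fit)
  b <- fit$coefficients
  qc <- exp(drop(rows$xc %*% b))
  qg <- exp(drop(rows$xg %*% b))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(tau = tau, week = week, country = country,
                    estimate = qc - qg, se = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_)
  for (i in seq_along(week)) {
    grad <- qc[i] * rows$xc[i, ] - qg[i] * rows$xg[i, ]
    out$se[i] <- sqrt(drop(grad %*% v %*% grad))
  }
  out$ci_low <- out$estimate - z * out$se
  out$ci_high <- out$estimate + z * out$se
  out
}

# covariate -> (design column, reporting unit, unit label)
covariate_units <- function() {
  data.frame(
    covariate = c("sex", "age", "height", "weight", "parity", "bmi"),
    column = c("sex_male", "age", "height", "weight", "parous", "bmi"),
    unit = c(1, 10, 10, 10, 1, 5),
    unit_label = c("male vs female", "per 10 y", "per 10 cm", "per 10 kg",
                   "parous vs nulliparous", "per 5 kg/m2"),
    stringsAsFactors = FALSE)
}

#' Covariate effects on the fitted quantiles, as percent change
#'
#' For every fitted quantile level, reports each covariate's log-scale
#' coefficient as the percent change in the response per conventional unit
#' (10 y of maternal age, 10 cm of height, 10 kg of weight, 5 kg/m2 of BMI,
#' parous vs nulliparous, male vs female): \eqn{100(\exp(u\beta) - 1)} for
#' unit \eqn{u}, with a delta-free exact interval from the coefficient CI,
#' and the single-coefficient Wald chi-square and p-value.
#'
#' @param chart a \code{"growth_chart"} fitted with covariates.
#' @param conf confidence level.
#' @return Data frame with columns tau, covariate, unit, estimate_pct,
#'   ci_low_pct, ci_high_pct, chi_square, df, p.  Percent effects are
#'   invariant to the GA centring constant.
#' @export
covariate_effect_table <- function(chart, conf = 0.95) {
  stopifnot(inherits(chart, "growth_chart"))
  if (is.null(chart$fits))
    fg_stop("fg_invalid_parameter", "chart carries no fits")
  cu <- covariate_units()
  cu <- cu[cu$column %in% names(chart$fits[[1]]$coefficients), , drop = FALSE]
  if (!nrow(cu))
    fg_stop("fg_invalid_parameter", "model contains no reportable covariates")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  taus <- attr(chart$fits, "taus")
  out <- list()
  for (k in seq_along(taus)) {
    fit <- chart$fits[[k]]
    v <- qreg_vcov(fit)
    for (i in seq_len(nrow(cu))) {
      j <- match(cu$column[i], names(fit$coefficients))
      beta <- fit$coefficients[j]
      se <- sqrt(v[j, j])
      wt <- wald_test(fit, j, vcov. = v)
      out[[length(out) + 1L]] <- data.frame(
        tau = taus[k], covariate = cu$covariate[i], unit = cu$unit_label[i],
        estimate_pct = 100 * (exp(cu$unit[i] * beta) - 1),
        ci_low_pct = 100 * (exp(cu$unit[i] * (beta - z * se)) - 1),
        ci_high_pct = 100 * (exp(cu$unit[i] * (beta + z * se)) - 1),
        chi_square = unname(wt$statistic), df = unname(wt$parameter),
        p = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "note") <-
    "No multiple-testing adjustment: simultaneous confidence is lower than nominal."
  out
}

#' Sex difference in chart values
#'
#' Difference (male minus female) between two sex-specific charts at one
#' week and quantile level, e.g. the median EFW gap.
#'
#' @param chart_male,chart_female sex-specific \code{"growth_chart"}s with
#'   identical grids and parameter.
#' @param week integer week.
#' @param tau quantile level (default 0.5, the median).
#' @return Difference in the charts' unit (grams for EFW).
#' @examples
#' b <- who_chart_bundle()
#' sex_median_difference(b$efw_male, b$efw_female, 37)  # 84 g
#' @export
sex_median_difference <- function(chart_male, chart_female, week, tau = 0.5) {
  stopifnot(inherits(chart_male, "growth_chart"),
            inherits(chart_female, "growth_chart"))
  if (!identical(chart_male$parameter, chart_female$parameter) ||
      !identical(chart_male$weeks, chart_female$weeks))
    fg_stop("fg_incompatible_charts", "charts do not share parameter and week grid")
  p <- tau * 100
  i <- match(week, chart_male$weeks)
  jm <- match(p, chart_male$percentiles)
  jf <- match(p, chart_female$percentiles)
  if (is.na(i) || is.na(jm) || is.na(jf))
    fg_stop("fg_incompatible_charts",
            "week %s / percentile %s not on both chart grids", week, p)
  unname(chart_male$values[i, jm] - chart_female$values[i, jf])
}
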