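# Longitudinal multi-country cohort simulator.
#
# Generative model (log scale, GA centred at 27 wk, t = weeks - 27):
#   log EFW(tau, t) = m(t) + sigma(t) z(tau) + gamma(t) z(tau)^2
#                     + covariate effects + country effect,
# with z = qnorm(tau).  m (cubic) and sigma (quadratic) are calibrated once
# to the bundled overall EFW chart's median and quartile columns; gamma is
# solved per GA from a linear Bowley-asymmetry target (slightly left-skewed
# early, clearly right-skewed at term) via the closed form
#   gamma = -log(cosh a - b sinh a) / z75^2,  a = sigma z75,
# so the Bowley coefficient of the true quartiles equals the target exactly.
# Each subject carries a latent uniform rank (centile tracking) unless
# rank_tracking = FALSE, in which case visits draw independent ranks.

Z75 <- stats::qnorm(0.75)

#' Configuration of the synthetic longitudinal cohort
#'
#' Defaults emulate the multi-country study design: ten countries of 140
#' women each, scans scheduled at 14/18/24/28/32/36/40 wk with uniform
#' +/-1 wk jitter, triplicate measurements reduced to their median with 2%
#' multiplicative noise, ~10% missed visits, 3.6% consent withdrawal and
#' 3.2% loss to follow-up, fetal-sex and maternal covariate effects of the
#' reported magnitudes (sex 3.5% at low quantiles to 4.5% at high, age
#' 2-3%/10 y strongest at low quantiles, height 1-2%/10 cm, weight
#' 1-1.5%/10 kg strongest at high quantiles, parity 1-1.5% diminishing with
#' quantile), and illustrative country effects spanning about +/-5%.
#'
#' @param n_per_country subjects per country (default 140).
#' @param countries named numeric vector of multiplicative log-scale country
#'   effects on EFW.
#' @param visit_weeks scheduled visit weeks.
#' @param jitter_weeks half-width of the uniform visit jitter (weeks).
#' @param covariate_effects list of two-point percent-effect profiles
#'   \code{c(lo, hi)}: the percent effect per conventional unit at tau = 0
#'   and tau = 1, interpolated linearly in tau.
#' @param bowley_anchor Bowley asymmetry targets at 15 and 40 weeks,
#'   interpolated linearly in GA.
#' @param spread_scale multiplier on the quantile spread (0 gives identical
#'   fetuses on the median curve).
#' @param measurement_cv coefficient of variation of a single biometric
#'   measurement (each stored value is the median of three).
#' @param missed_visit_rate,withdrawal_rate,loss_rate independent event
#'   rates: a missed visit drops one scan; withdrawal drops the subject
#'   entirely; loss to follow-up censors all visits after a random one.
#' @param rank_tracking if TRUE (default) a subject keeps one latent centile
#'   across visits; if FALSE every visit draws a fresh rank (useful for
#'   calibration studies needing independent observations).
#' @param seed integer RNG seed recorded in the config.
#' @return List of class \code{"sim_config"} including the calibrated
#'   base/spread coefficients.
#' @export
sim_config <- function(n_per_country = 140,
                       countries = c("Argentina" = -0.01, "Brazil" = 0.00,
                                     "D. R. Congo" = -0.03, "Denmark" = 0.03,
                                     "Egypt" = -0.02, "France" = 0.01,
                                     "Germany" = 0.04, "India" = -0.05,
                                     "Norway" = 0.05, "Thailand" = -0.04),
                       visit_weeks = c(14, 18, 24, 28, 32, 36, 40),
                       jitter_weeks = 1,
                       covariate_effects = list(sex = c(3.5, 4.5),
                                                age = c(2.5, 0.5),
                                                height = c(2, 1),
                                                weight = c(0.5, 1.25),
                                                parity = c(1.25, 0.25)),
                       bowley_anchor = c(at15 = -0.02, at40 = 0.11),
                       spread_scale = 1,
                       measurement_cv = 0.02,
                       missed_visit_rate = 0.10,
                       withdrawal_rate = 0.036,
                       loss_rate = 0.032,
                       rank_tracking = TRUE,
                       seed = 1L) {
  rates <- c(missed_visit_rate, withdrawal_rate, loss_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    fg_stop("fg_config", "rates must lie in [0, 1]")
  if (n_per_country < 1)
    fg_stop("fg_config", "n_per_country must be at least 1")
  if (any(visit_weeks < 14 | visit_weeks >= 41))
    fg_stop("fg_config", "visit_weeks must lie within [14, 41)")
  if (is.null(names(countries)) || anyDuplicated(names(countries)))
    fg_stop("fg_config", "countries must be uniquely named")

  bundle <- who_chart_bundle()
  cal <- list(efw = calibrate_curves(bundle$efw))
  for (par in c("hc", "fl", "bpd", "hl"))
    cal[[par]] <- stats::coef(stats::lm(
      log(v) ~ t + I(t^2) + I(t^3),
      data.frame(t = bundle[[par]]$weeks - FG_GA_CENTER,
                 v = bundle[[par]]$values[, match(50, bundle[[par]]$percentiles)])))

  structure(list(n_per_country = n_per_country, countries = countries,
                 visit_weeks = visit_weeks, jitter_weeks = jitter_weeks,
                 covariate_effects = covariate_effects,
                 bowley_anchor = bowley_anchor, spread_scale = spread_scale,
                 measurement_cv = measurement_cv,
                 missed_visit_rate = missed_visit_rate,
                 withdrawal_rate = withdrawal_rate, loss_rate = loss_rate,
                 rank_tracking = rank_tracking, seed = as.integer(seed),
                 calibration = cal,
                 reference = list(sex = "female", age = 28, height = 163,
                                  weight = 61, parity = 0),
                 # allometric exponents: log deviation of each biometric from
                 # its median curve per unit log-EFW deviation
                 allometry = c(hc = 0.25, fl = 0.30, bpd = 0.25, hl = 0.30)),
            class = "sim_config")
}

calibrate_curves <- function(chart) {
  t <- chart$weeks - FG_GA_CENTER
  p <- chart$percentiles
  l50 <- log(chart$values[, match(50, p)])
  l25 <- log(chart$values[, match(25, p)])
  l75 <- log(chart$values[, match(75, p)])
  sig <- (l75 - l25) / (2 * Z75)
  list(base = stats::coef(stats::lm(l50 ~ t + I(t^2) + I(t^3))),
       sigma = stats::coef(stats::lm(sig ~ t + I(t^2))))
}

poly_eval <- function(coefs, t) {
  coefs <- unname(coefs)
  out <- rep(coefs[1], length(t))
  for (k in seq_len(length(coefs) - 1L)) out <- out + coefs[k + 1L] * t^k
  out
}

sim_sigma <- function(config, t)
  config$spread_scale * poly_eval(config$calibration$efw$sigma, t)

sim_gamma <- function(config, t) {
  b <- config$bowley_anchor[["at15"]] +
    (config$bowley_anchor[["at40"]] - config$bowley_anchor[["at15"]]) *
      ((t + FG_GA_CENTER) - 15) / 25
  a <- sim_sigma(config, t) * Z75
  g <- ifelse(a > 0, -log(cosh(a) - b * sinh(a)) / Z75^2, 0)
  g
}

# percent-effect profile, linear in tau between the lo and hi anchors,
# returned as a log-scale effect per conventional unit
effect_log <- function(profile, tau) {
  pct <- profile[1] + (profile[2] - profile[1]) * tau
  log1p(pct / 100)
}

covariate_log_effect <- function(config, tau, covariates, country = NULL) {
  ref <- config$reference
  ce <- config$covariate_effects
  eff <- 0
  if (!is.null(covariates$sex))
    eff <- eff + effect_log(ce$sex, tau) * (covariates$sex == "male")
  if (!is.null(covariates$age))
    eff <- eff + effect_log(ce$age, tau) * (covariates$age - ref$age) / 10
  if (!is.null(covariates$height))
    eff <- eff + effect_log(ce$height, tau) * (covariates$height - ref$height) / 10
  if (!is.null(covariates$weight))
    eff <- eff + effect_log(ce$weight, tau) * (covariates$weight - ref$weight) / 10
  if (!is.null(covariates$parity))
    eff <- eff + effect_log(ce$parity, tau) * (covariates$parity >= 1)
  if (!is.null(country)) {
    j <- match(country, names(config$countries))
    if (anyNA(j))
      fg_stop("fg_unknown_stratum", "country not in the configuration: %s",
              paste(unique(country[is.na(j)]), collapse = ", "))
    eff <- eff + config$countries[j]
  }
  eff
}

sim_log_quantile <- function(config, ga_wk, tau, covariates = list(),
                             country = NULL) {
  t <- ga_wk - FG_GA_CENTER
  z <- stats::qnorm(tau)
  poly_eval(config$calibration$efw$base, t) +
    sim_sigma(config, t) * z +
    sim_gamma(config, t) * z^2 +
    covariate_log_effect(config, tau, covariates, country)
}

#' Closed-form true EFW quantile of the generative model
#'
#' The exact conditional quantile implied by the simulator's generative
#' model — the ground truth against which fitted charts are checked.
#' Strictly increasing in \code{tau} for every gestational age and
#' covariate vector over the supported range.
#'
#' @param config a [sim_config()].
#' @param ga_days gestational age in days, within the analysis window
#'   (days 98-286).
#' @param tau quantile level(s) in (0, 1).
#' @param covariates named list (sex, age, height, weight, parity); omitted
#'   entries sit at the reference (female, 28 y, 163 cm, 61 kg,
#'   nulliparous).
#' @param country optional country name from the configuration.
#' @return EFW in grams.
#' @export
true_quantile <- function(config, ga_days, tau, covariates = list(),
                          country = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_tau(tau, several = TRUE)
  if (any(ga_days < FG_GA_WINDOW[1] | ga_days > FG_GA_WINDOW[2]))
    fg_stop("fg_ga_range", "ga_days outside the analysis window [%d, %d]",
            FG_GA_WINDOW[1], FG_GA_WINDOW[2])
  exp(sim_log_quantile(config, ga_days / 7, tau, covariates, country))
}

#' Simulate a longitudinal multi-country cohort
#'
#' Draws per-subject covariates calibrated to the study's summary
#' statistics (median age 28 y IQR 25-31, height 163 cm IQR 157-168, weight
#' 61 kg IQR 55-68, 42% parous, 53.2% male fetuses), assigns each subject a
#' latent uniform centile rank, generates true EFW per visit from the
#' tau-structured model, decomposes EFW into consistent biometry (HC, FL,
#' BPD, HL follow fixed allometric profiles around their median curves; AC
#' is solved exactly through the Hadlock formula so that the biometry
#' reproduces the target EFW), adds triplicate measurement noise storing the
#' median, and applies missed visits, withdrawal and loss to follow-up as
#' independent events.  Fully reproducible given \code{config$seed}; the
#' caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return List of class \code{"sim_cohort"} with \code{subjects} (subject
#'   id, country, maternal covariates, fetal sex, and a \code{status}
#'   column: completed / withdrawn / lost) and \code{scans} (subject id,
#'   ga_days, five biometric medians in mm); the config is attached as an
#'   attribute.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  countries <- names(config$countries)
  n <- config$n_per_country * length(countries)
  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    country = rep(countries, each = config$n_per_country),
    maternal_age_y = round(pmin(pmax(stats::rnorm(n, 28, 4.45), 16), 48), 1),
    height_cm = round(pmin(pmax(stats::rnorm(n, 163, 8.2), 140), 195), 1),
    weight_kg = round(pmin(pmax(exp(stats::rnorm(n, log(61), 0.157)), 38), 120), 1),
    parity = ifelse(stats::runif(n) < 0.42, 1L + stats::rpois(n, 0.5), 0L),
    fetal_sex = ifelse(stats::runif(n) < 0.532, "male", "female"),
    stringsAsFactors = FALSE)
  rank <- stats::runif(n)
  status <- rep("completed", n)
  status[stats::runif(n) < config$withdrawal_rate] <- "withdrawn"
  lost <- status == "completed" & stats::runif(n) < config$loss_rate
  status[lost] <- "lost"
  nv <- length(config$visit_weeks)
  lost_after <- ifelse(lost, sample.int(nv, n, replace = TRUE), nv)
  subjects$status <- status

  scans <- vector("list", n)
  for (i in seq_len(n)) {
    if (status[i] == "withdrawn") next
    vis <- seq_len(if (status[i] == "lost") lost_after[i] else nv)
    vis <- vis[stats::runif(length(vis)) >= config$missed_visit_rate]
    if (!length(vis)) next
    ga_wk <- config$visit_weeks[vis] +
      stats::runif(length(vis), -config$jitter_weeks, config$jitter_weeks)
    ga_days <- round(ga_wk * 7)
    ga_days[duplicated(ga_days)] <- ga_days[duplicated(ga_days)] + 1L
    rnk <- if (config$rank_tracking) rep(rank[i], length(vis))
           else stats::runif(length(vis))
    covs <- list(sex = subjects$fetal_sex[i], age = subjects$maternal_age_y[i],
                 height = subjects$height_cm[i], weight = subjects$weight_kg[i],
                 parity = subjects$parity[i])
    log_efw <- sim_log_quantile(config, ga_days / 7, rnk, covs,
                                subjects$country[i])
    bio <- decompose_biometry(config, ga_days / 7, log_efw)
    bio <- measure_triplicate(bio, config$measurement_cv)
    scans[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                             ga_days = as.integer(ga_days),
                             bpd_mm = bio$bpd, hc_mm = bio$hc, ac_mm = bio$ac,
                             fl_mm = bio$fl, hl_mm = bio$hl,
                             stringsAsFactors = FALSE)
  }
  scans <- do.call(rbind, scans[!vapply(scans, is.null, logical(1))])
  rownames(scans) <- NULL
  structure(list(subjects = subjects, scans = scans),
            config = config, class = "sim_cohort")
}

# Biometry consistent with a target log EFW: head and limb measurements
# follow their median GA profiles scaled allometrically by the subject's
# log-EFW deviation; AC is then solved exactly through the Hadlock formula.
decompose_biometry <- function(config, ga_wk, log_efw) {
  t <- ga_wk - FG_GA_CENTER
  dev <- log_efw - poly_eval(config$calibration$efw$base, t)
  al <- config$allometry
  hc <- exp(poly_eval(config$calibration$hc, t) + al[["hc"]] * dev)
  fl <- exp(poly_eval(config$calibration$fl, t) + al[["fl"]] * dev)
  bpd <- exp(poly_eval(config$calibration$bpd, t) + al[["bpd"]] * dev)
  hl <- exp(poly_eval(config$calibration$hl, t) + al[["hl"]] * dev)
  hc_cm <- hc / 10; fl_cm <- fl / 10
  denom <- 0.0438 - 0.00326 * fl_cm
  if (any(denom <= 0.005))
    fg_stop("fg_config", "femur length outside the Hadlock-invertible range")
  ac_cm <- (log_efw / log(10) - 1.326 - 0.0107 * hc_cm - 0.158 * fl_cm) / denom
  list(hc = hc, fl = fl, bpd = bpd, hl = hl, ac = 10 * ac_cm)
}

measure_triplicate <- function(bio, cv) {
  if (cv <= 0) return(bio)
  lapply(bio, function(v) {
    m <- matrix(rep(v, each = 3L) * exp(stats::rnorm(3L * length(v), 0, cv)),
                nrow = 3L)
    apply(m, 2L, stats::median)
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects (%d with scans), %d scans, seed %d\n",
              nrow(x$subjects), length(unique(x$scans$subject_id)),
              nrow(x$scans), attr(x, "config")$seed))
  invisible(x)
}
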