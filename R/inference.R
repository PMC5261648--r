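#' Hall-Sheather bandwidth for sparsity estimation
#'
#' Bandwidth for the difference-quotient estimate of the sparsity function
#' (reciprocal error density at the quantile), tuned for Wald-type inference
#' at level \code{alpha}.
#'
#' @param tau quantile level.
#' @param n number of observations.
#' @param alpha nominal test level (default 0.05).
#' @return Positive bandwidth on the probability scale.
#' @export
hall_sheather_bandwidth <- function(tau, n, alpha = 0.05) {
  check_tau(tau)
  za <- stats::qnorm(1 - alpha / 2)
  zt <- stats::qnorm(tau)
  n^(-1 / 3) * za^(2 / 3) *
    ((1.5 * stats::dnorm(zt)^2) / (2 * zt^2 + 1))^(1 / 3)
}

#' Asymptotic covariance of quantile-regression coefficients
#'
#' Under independent, identically distributed errors the estimator is
#' asymptotically normal with covariance
#' \eqn{\tau(1-\tau)\, s(\tau)^2 (X'X)^{-1}}, where the sparsity
#' \eqn{s(\tau) = 1/f(F^{-1}(\tau))} is estimated by a difference quotient of
#' the empirical residual quantile function,
#' \eqn{\hat s = [\hat Q_r(\tau+h) - \hat Q_r(\tau-h)]/(2h)}, at the
#' Hall-Sheather bandwidth \code{h}.
#'
#' @param object a \code{"qreg"} fit (which carries its design and response).
#' @param bandwidth probability-scale bandwidth; default Hall-Sheather at
#'   \code{alpha}.
#' @param alpha level used by the default bandwidth rule.
#' @return Symmetric positive semidefinite covariance matrix, with the
#'   sparsity estimate attached as attribute \code{"sparsity"}.
#' @export
qreg_vcov <- function(object, bandwidth = NULL, alpha = 0.05) {
  stopifnot(inherits(object, "qreg"))
  tau <- object$tau
  n <- object$n_obs
  h <- bandwidth %||% hall_sheather_bandwidth(tau, n, alpha)
  if (!is.finite(h) || h <= 0)
    fg_stop("fg_invalid_parameter", "bandwidth must be positive")
  # keep tau +/- h inside (0, 1); shrink near the tails
  h <- min(h, tau / 2, (1 - tau) / 2)
  qs <- stats::quantile(object$residuals, c(tau - h, tau + h),
                        names = FALSE, type = 7)
  s <- (qs[2] - qs[1]) / (2 * h)
  if (!is.finite(s) || s <= 0)
    fg_stop("fg_degenerate_sparsity",
            "degenerate sparsity estimate: residual quantile spacing is non-positive at bandwidth %.4g", h)
  xtx <- crossprod(object$x)
  ch <- tryCatch(chol(xtx), error = function(e)
    fg_stop("fg_singular_design", "X'X is not positive definite"))
  v <- tau * (1 - tau) * s^2 * chol2inv(ch)
  v <- (v + t(v)) / 2
  dimnames(v) <- list(names(object$coefficients), names(object$coefficients))
  attr(v, "sparsity") <- s
  v
}

#' Wald chi-square test on quantile-regression coefficients
#'
#' Tests the linear hypothesis \eqn{C\beta = 0} with the chi-square statistic
#' \eqn{(C\beta)'(C V C')^{-1}(C\beta)} on \code{nrow(C)} degrees of freedom,
#' where \eqn{V} is the asymptotic covariance from [qreg_vcov()].
#'
#' @param fit a \code{"qreg"} object.
#' @param contrast a contrast matrix with one row per restriction (or a
#'   single numeric vector, or the names/indices of coefficients to test
#'   jointly against zero).
#' @param vcov. optional covariance matrix; default [qreg_vcov()] of the fit.
#' @return An object of class \code{"htest"} with the chi-square statistic,
#'   degrees of freedom and p-value.
#' @export
wald_test <- function(fit, contrast, vcov. = NULL) {
  stopifnot(inherits(fit, "qreg"))
  b <- fit$coefficients
  p <- length(b)
  if (is.character(contrast) || (is.numeric(contrast) && !is.matrix(contrast) &&
                                 length(contrast) < p && all(contrast == round(contrast)) &&
                                 all(contrast >= 1))) {
    idx <- if (is.character(contrast)) match(contrast, names(b)) else as.integer(contrast)
    if (anyNA(idx) || any(idx > p))
      fg_stop("fg_invalid_parameter", "unknown coefficients in `contrast`")
    cmat <- diag(p)[idx, , drop = FALSE]
  } else {
    cmat <- if (is.matrix(contrast)) contrast else matrix(contrast, nrow = 1L)
  }
  if (ncol(cmat) != p)
    fg_stop("fg_invalid_parameter",
            "contrast has %d columns but the model has %d coefficients",
            ncol(cmat), p)
  if (qr(cmat)$rank < nrow(cmat))
    fg_stop("fg_singular_contrast", "contrast matrix is not of full row rank")
  v <- vcov. %||% qreg_vcov(fit)
  cv <- cmat %*% v %*% t(cmat)
  ch <- tryCatch(chol(cv), error = function(e)
    fg_stop("fg_singular_contrast", "C V C' is singular"))
  cb <- drop(cmat %*% b)
  stat <- sum(backsolve(ch, cb, transpose = TRUE)^2)
  df <- nrow(cmat)
  structure(
    list(statistic = c(`X-squared` = stat), parameter = c(df = df),
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         method = "Wald chi-square test on quantile-regression coefficients",
         data.name = sprintf("tau = %g fit, n = %d", fit$tau, fit$n_obs)),
    class = "htest")
}
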