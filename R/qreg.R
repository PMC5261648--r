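#' Pinball (check) loss
#'
#' The asymmetric absolute loss whose minimiser over a constant is the
#' \code{tau}-quantile of the data: \eqn{\rho_\tau(r) = r(\tau - 1\{r < 0\})}.
#' Quantile regression estimates conditional quantiles by minimising the sum
#' of this loss over the residuals.
#'
#' @param residuals numeric vector of residuals.
#' @param tau quantile level, strictly inside (0, 1).
#' @return Non-negative scalar, the total pinball loss. Zero if and only if
#'   all residuals are zero.
#' @examples
#' pinball_loss(c(1, -1), 0.5)   # 1
#' pinball_loss(c(2, -3), 0.25)  # 0.25*2 + 0.75*3 = 2.75
#' @export
pinball_loss <- function(residuals, tau) {
  check_tau(tau)
  r <- as.numeric(residuals)
  if (anyNA(r)) fg_stop("fg_invalid_parameter", "residuals contain missing values")
  sum(r * (tau - (r < 0)))
}

check_tau <- function(tau, several = FALSE) {
  if (!is.numeric(tau) || (!several && length(tau) != 1L) ||
      anyNA(tau) || any(tau <= 0) || any(tau >= 1))
    fg_stop("fg_invalid_parameter",
            "`tau` must be %s strictly inside (0, 1)",
            if (several) "quantile levels" else "a single quantile level")
  invisible(tau)
}

#' Quantile regression by interior-point minimisation of the pinball loss
#'
#' Fits the linear conditional quantile model \eqn{Q_y(\tau | x) = x'\beta}
#' by solving the equivalent linear program (split the residual into
#' non-negative parts \eqn{u, v} with \eqn{y - X\beta = u - v} and minimise
#' \eqn{\tau \sum u + (1-\tau) \sum v}) with a primal-dual interior-point
#' method of the Frisch-Newton family, using Mehrotra's predictor-corrector
#' steps.  Columns are rescaled internally for conditioning; coefficients are
#' reported on the original scale.  After convergence a vertex-polishing step
#' replaces the interior iterate by an exact basic solution when that does
#' not worsen the objective, so degenerate problems (where \eqn{\tau n} is an
#' integer and the optimum is a face, not a point) may return any optimal
#' vertex; the contract is the objective value.
#'
#' @param x design matrix (observations in rows, named regressors in
#'   columns); must have full column rank and no missing cells.
#' @param y numeric response vector.
#' @param tau quantile level in (0, 1).
#' @param tol relative duality-gap tolerance on the standardised problem;
#'   the default bounds the objective optimality gap by about 1e-8.
#' @param max_iter maximum interior-point iterations.
#' @param polish if TRUE (default), attempt to move the converged interior
#'   solution to an exact vertex of the optimal face.
#' @return An object of class \code{"qreg"}: a list with components
#'   \code{coefficients}, \code{tau}, \code{residuals}, \code{fitted.values},
#'   \code{objective} (total pinball loss at the solution), \code{n_obs},
#'   \code{converged}, \code{iterations}, and the model data \code{x},
#'   \code{y}.
#' @seealso [qreg()] for the formula interface, [qreg_fit_set()] for several
#'   quantile levels on one design, [qreg_vcov()] and [wald_test()] for
#'   inference.
#' @export
qreg_fit <- function(x, y, tau, tol = 1e-10, max_iter = 200, polish = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  check_tau(tau)
  if (p < 1L) fg_stop("fg_invalid_parameter", "design matrix has no columns")
  if (length(y) != n)
    fg_stop("fg_invalid_parameter", "length(y) [%d] != nrow(x) [%d]", length(y), n)
  if (anyNA(x) || anyNA(y))
    fg_stop("fg_invalid_parameter", "missing values in design or response")
  if (n < p)
    fg_stop("fg_singular_design", "fewer observations (%d) than columns (%d)", n, p)
  if (qr(x)$rank < p)
    fg_stop("fg_singular_design", "singular design: columns are linearly dependent")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  # internal standardisation: per-column max-abs scaling, response scaling
  sc <- pmax(apply(abs(x), 2L, max), .Machine$double.eps)
  ysc <- stats::sd(y)
  if (!is.finite(ysc) || ysc < .Machine$double.eps) ysc <- max(abs(y), 1)
  xs <- sweep(x, 2L, sc, "/")
  ys <- y / ysc

  beta <- qr.coef(qr(xs), ys)              # least-squares start
  r <- ys - drop(xs %*% beta)
  d0 <- mean(abs(r))
  if (d0 < 1e-8) d0 <- 1
  u <- pmax(r, 0) + d0
  v <- u - r                               # u - v == r exactly
  z <- rep.int(tau, n)
  w <- rep.int(1 - tau, n)

  step_len <- function(a, da, b, db) {
    neg <- da < 0
    s1 <- if (any(neg)) min(-a[neg] / da[neg]) else Inf
    neg <- db < 0
    s2 <- if (any(neg)) min(-b[neg] / db[neg]) else Inf
    min(1, 0.9995 * min(s1, s2))
  }

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    gap <- sum(u * z) + sum(v * w)
    obj_s <- tau * sum(u) + (1 - tau) * sum(v)
    if (gap < tol * (1 + obj_s) * n^0.5 || gap < 1e-14 * n) {
      converged <- TRUE
      break
    }
    iq <- 1 / (u / z + v / w)
    r_uv <- u - v                          # equals ys - xs %*% beta
    a_mat <- crossprod(xs * sqrt(iq))
    ch <- tryCatch(chol(a_mat), error = function(e) NULL)
    if (is.null(ch))
      ch <- chol(a_mat + diag(1e-10 * max(diag(a_mat)), p))
    solve_a <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))

    # predictor (affine) direction
    dbeta_a <- solve_a(crossprod(xs, iq * r_uv))
    dz_a <- iq * (drop(xs %*% dbeta_a) - r_uv)
    du_a <- -u - (u / z) * dz_a
    dv_a <- -v + (v / w) * dz_a
    ap_a <- step_len(u, du_a, v, dv_a)
    ad_a <- step_len(z, dz_a, w, -dz_a)
    gap_a <- sum((u + ap_a * du_a) * (z + ad_a * dz_a)) +
             sum((v + ap_a * dv_a) * (w - ad_a * dz_a))
    sigma <- min(0.999, max(0, gap_a / gap)^3)
    mu <- sigma * gap / (2 * n)

    # corrector
    gu <- (mu - du_a * dz_a) / z
    gv <- (mu + dv_a * dz_a) / w
    dbeta <- solve_a(crossprod(xs, iq * (r_uv - (gu - gv))))
    dz <- iq * (drop(xs %*% dbeta) - r_uv + (gu - gv))
    du <- gu - u - (u / z) * dz
    dv <- gv - v + (v / w) * dz
    ap <- step_len(u, du, v, dv)
    ad <- step_len(z, dz, w, -dz)

    beta <- beta + ap * dbeta
    u <- u + ap * du
    v <- v + ap * dv
    z <- z + ad * dz
    w <- w - ad * dz
  }
  if (!converged)
    fg_stop("fg_convergence",
            "interior-point solver did not converge in %d iterations (duality gap %.3e, tau = %g, n = %d, p = %d)",
            max_iter, sum(u * z) + sum(v * w), tau, n, p)

  coef <- beta * ysc / sc
  obj <- pinball_loss(y - drop(x %*% coef), tau)

  if (polish) {
    # move to a basic (vertex) solution: interpolate the p observations
    # closest to the fitted hyperplane, keep if not worse
    idx <- order(u + v)[seq_len(p)]
    xb <- x[idx, , drop = FALSE]
    qb <- qr(xb)
    if (qb$rank == p) {
      cand <- qr.coef(qb, y[idx])
      obj_c <- pinball_loss(y - drop(x %*% cand), tau)
      if (is.finite(obj_c) && obj_c <= obj + 1e-12 * (1 + obj)) {
        coef <- cand
        obj <- obj_c
      }
    }
  }

  fitted <- drop(x %*% coef)
  names(coef) <- colnames(x)
  structure(
    list(coefficients = coef, tau = tau,
         residuals = y - fitted, fitted.values = fitted,
         objective = obj, n_obs = n, converged = converged,
         iterations = it, x = x, y = y),
    class = "qreg")
}

#' Fit one design at several quantile levels
#'
#' @param x,y design matrix and response, as in [qreg_fit()].
#' @param taus strictly increasing quantile levels in (0, 1).
#' @param ... passed to [qreg_fit()].
#' @return Object of class \code{"qreg_set"}: a list of \code{"qreg"} fits in
#'   the order of \code{taus}.
#' @export
qreg_fit_set <- function(x, y, taus, ...) {
  check_tau(taus, several = TRUE)
  if (anyDuplicated(taus))
    fg_stop("fg_invalid_parameter", "duplicate quantile levels in `taus`")
  if (is.unsorted(taus))
    fg_stop("fg_invalid_parameter", "`taus` must be strictly increasing")
  fits <- lapply(taus, function(tt) qreg_fit(x, y, tt, ...))
  structure(fits, taus = taus, class = "qreg_set")
}

#' Quantile regression with a formula interface
#'
#' Formula front end to the pinball-loss interior-point estimator
#' ([qreg_fit()]).  With a single \code{tau} returns a \code{"qreg"} fit;
#' with several, a \code{"qreg_set"}.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param tau quantile level(s) in (0, 1); several levels must be strictly
#'   increasing.
#' @param ... passed to [qreg_fit()].
#' @return \code{"qreg"} or \code{"qreg_set"} object.
#' @examples
#' d <- data.frame(x = 1:20, y = log(1:20) + rnorm(20, sd = 0.1))
#' f <- qreg(y ~ x, d, tau = 0.5)
#' coef(f)
#' @export
qreg <- function(formula, data, tau = 0.5, ...) {
  mf <- stats::model.frame(formula, data)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf, "numeric")
  x <- stats::model.matrix(mt, mf)
  decorate <- function(fit) {
    fit$terms <- mt
    fit$xlevels <- stats::.getXlevels(mt, mf)
    fit$call <- match.call()
    fit
  }
  if (length(tau) == 1L) {
    decorate(qreg_fit(x, y, tau, ...))
  } else {
    fits <- qreg_fit_set(x, y, tau, ...)
    fits[] <- lapply(fits, decorate)
    fits
  }
}

#' @export
print.qreg <- function(x, ...) {
  cat(sprintf("Quantile regression fit, tau = %g\n", x$tau))
  cat(sprintf("n = %d, pinball objective = %.6g, %d interior-point iterations\n",
              x$n_obs, x$objective, x$iterations))
  cat("Coefficients:\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' @export
coef.qreg <- function(object, ...) object$coefficients

#' @export
residuals.qreg <- function(object, ...) object$residuals

#' @export
fitted.qreg <- function(object, ...) object$fitted.values

#' @export
vcov.qreg <- function(object, ...) qreg_vcov(object, ...)

#' @export
predict.qreg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.matrix(newdata)) return(drop(newdata %*% object$coefficients))
  if (is.null(object$terms))
    fg_stop("fg_invalid_parameter",
            "fit has no formula terms; supply `newdata` as a design matrix")
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  x <- stats::model.matrix(tt, mf)
  drop(x %*% object$coefficients)
}

#' @export
summary.qreg <- function(object, ...) {
  v <- qreg_vcov(object, ...)
  se <- sqrt(diag(v))
  zval <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  structure(list(tau = object$tau, n_obs = object$n_obs,
                 objective = object$objective, coefficients = tab),
            class = "summary.qreg")
}

#' @export
print.summary.qreg <- function(x, ...) {
  cat(sprintf("Quantile regression, tau = %g (n = %d)\n", x$tau, x$n_obs))
  stats::printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' @export
print.qreg_set <- function(x, ...) {
  cat(sprintf("Quantile regression fits at %d levels: %s\n",
              length(x), paste(attr(x, "taus"), collapse = ", ")))
  print(coef(x), ...)
  invisible(x)
}

#' @export
coef.qreg_set <- function(object, ...) {
  m <- sapply(object, coef)
  if (!is.matrix(m))
    m <- matrix(m, nrow = 1L,
                dimnames = list(names(object[[1L]]$coefficients), NULL))
  colnames(m) <- paste0("tau=", attr(object, "taus"))
  m
}
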