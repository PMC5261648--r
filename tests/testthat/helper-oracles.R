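# Brute-force quantile-regression oracle: the optimum of the pinball-loss
# LP is attained at a vertex, i.e. a coefficient vector interpolating p
# observations; enumerate all full-rank subsets and take the best.  Only
# feasible for small n and p, which is exactly its job.
oracle_qreg_objective <- function(x, y, tau) {
  n <- nrow(x)
  p <- ncol(x)
  best <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    xb <- x[idx, , drop = FALSE]
    if (abs(det(xb)) < 1e-10) next
    b <- solve(xb, y[idx])
    obj <- pinball_loss(y - drop(x %*% b), tau)
    if (obj < best) best <- obj
  }
  best
}

# config helpers: effects switched off (for quantile-structure recovery and
# null-calibration studies)
zero_country_effects <- function()
  stats::setNames(rep(0, 10), names(eval(formals(sim_config)$countries)))

zero_covariate_effects <- function()
  list(sex = c(0, 0), age = c(0, 0), height = c(0, 0), weight = c(0, 0),
       parity = c(0, 0))

null_sim_config <- function(seed, n_per_country = 25, ...) {
  sim_config(seed = seed, n_per_country = n_per_country,
             countries = zero_country_effects(),
             covariate_effects = zero_covariate_effects(), ...)
}

# a small clean cohort for fast end-to-end tests
small_cohort <- function(seed = 11, n_per_country = 12, ...) {
  simulate_cohort(sim_config(seed = seed, n_per_country = n_per_country, ...))
}
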