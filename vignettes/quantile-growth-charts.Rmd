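---
title: "Constructing fetal growth charts by quantile regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing fetal growth charts by quantile regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalgrowth)
```

## The problem

A fetal growth chart gives, for each gestational age (GA), the percentiles
of a biometric measurement — biparietal diameter (BPD), head circumference
(HC), abdominal circumference (AC), femur and humerus length (FL, HL) — or
of the estimated fetal weight (EFW) derived from them.  Clinically, a chart
answers "where does this fetus sit relative to its peers at this GA?", and
it is built from longitudinal ultrasound measurements of a low-risk
multi-country cohort.

This package provides three connected things:

1. a **quantile-regression engine** (`qreg()`, `qreg_fit()`) that fits
   conditional quantiles directly, without distributional assumptions;
2. a **chart-construction pipeline** (`construct_chart()`) from raw scan
   tables to publishable weekly percentile grids, plus comparison tooling
   (`percentile_difference_ci()`, `covariate_effect_table()`,
   `qq_compare()`);
3. the **published WHO fetal growth tables** bundled for clinical lookup
   (`who_chart_bundle()`, `chart_value()`, `percentile_of()`), together
   with a **cohort simulator** (`simulate_cohort()`) whose closed-form true
   quantiles (`true_quantile()`) make end-to-end recovery testable.

## The estimator

For quantile level $\tau \in (0,1)$ the linear conditional quantile model
$Q_y(\tau \mid x) = x'\beta(\tau)$ is estimated by minimising the pinball
loss $\sum_i \rho_\tau(y_i - x_i'\beta)$ with
$\rho_\tau(r) = r(\tau - 1\{r<0\})$.  This is a linear program: writing the
residual as $u - v$ with $u, v \ge 0$, minimise
$\tau \mathbf{1}'u + (1-\tau)\mathbf{1}'v$ subject to $X\beta + u - v = y$.
`qreg_fit()` solves it with a primal–dual interior-point method of the
Frisch–Newton family (Mehrotra predictor–corrector steps, a feasible start
from the least-squares fit, and the dual box $z + w = \mathbf{1}$,
$X'z = \tau X'\mathbf{1}$ maintained exactly).  Columns are rescaled to
unit maximum absolute value and the response standardised internally, so
the relative duality-gap tolerance (`tol = 1e-10`) bounds the objective
optimality gap by about $10^{-8}$ on the standardised problem; coefficients
are reported on the original scale.

Two numerical points deserve mention.

* **Degenerate optima.** When $\tau n$ is an integer the optimum can be a
  face of the polytope rather than a vertex (the textbook example: the
  0.25 quantile of four points is any value between the first and second
  order statistic).  The interior path converges to the analytic centre of
  the optimal face; a final polishing step replaces it by an exact basic
  (vertex) solution when that does not worsen the objective.  The
  engine's contract is therefore the *objective value*; coefficients at
  degenerate quantiles may legitimately differ between solvers.  The test
  suite checks the objective against a brute-force oracle that enumerates
  every full-rank $p$-subset of observations.
* **Crossing.** Separate fits at different $\tau$ are not constrained to be
  ordered.  The engine does not reorder anything silently; ordering is
  enforced downstream, once, on the retransformed weekly grid (below).

### Standard errors and tests

Under i.i.d. errors the estimator is asymptotically normal with covariance
$\tau(1-\tau)\,s(\tau)^2 (X'X)^{-1}$, where the sparsity
$s(\tau) = 1/f(F^{-1}(\tau))$ is the reciprocal error density at the
quantile.  `qreg_vcov()` estimates $s$ by the difference quotient of the
empirical residual quantile function at the Hall–Sheather bandwidth
($\alpha = 0.05$); near the tails the bandwidth is shrunk so that
$\tau \pm h$ stays inside $(0,1)$.  The i.i.d. sparsity estimate is a
documented assumption — the published analysis states only that the
coefficient estimates are asymptotically normal, not which variance
estimator stood behind its intervals, and the Hall–Sheather i.i.d. rule is
the default of the software family used for such analyses.  In our own
null calibrations (300 replicates, ~1,400 observations, 30 parameters) the
resulting 95% intervals cover at about 92–93%: mildly anticonservative, a
known finite-sample property of this estimator, and inside the tolerance
we test against.  `wald_test()` provides the chi-square test
$(C\beta)'(C V C')^{-1}(C\beta)$ for joint hypotheses; the likelihood-ratio
variant is deliberately not implemented since every reported use is a Wald
statistic.

## From scans to charts

`construct_chart()` performs, in order:

1. **Analysis window.** Scans outside days 98–286 (14w+0d to 40w+6d) are
   dropped with a machine-readable reason.  The upper edge keeps the
   scheduled week-40 visit: "14 to 40 weeks" is read as completed week 40,
   i.e. through 40w+6d.  An optional outlier screen flags scans whose log
   measurement deviates from its 2-week GA-bin median by more than
   $k \times$ MAD ($k = 5$; bins with fewer than 10 scans are not
   screened).  The screen is off by default — the rule is a configurable
   convention, and chart construction on clean simulated data should be
   exactly reproducible.
2. **Design.** The response is the *natural log* of the parameter (the log
   base cannot affect the retransformed chart); EFW is computed per scan by
   Hadlock's third formula from HC, AC and FL
   ($\log_{10} W = 1.326 - 0.00326\,AC\!\cdot\!FL + 0.0107\,HC + 0.0438\,AC
   + 0.158\,FL$, lengths in cm).  GA enters in weeks, centred at 27 weeks
   before polynomial expansion (degree 3 by default) — a pure conditioning
   choice with no effect on fitted values, which the tests verify.
   Maternal covariates enter additively; country enters as indicators
   against a reference level, optionally with GA-polynomial-by-country
   interaction terms (the "full model": 4 + 9 + 27 = 40 columns for ten
   countries at degree 3).
3. **Fit and evaluate.** One quantile regression per level of the grid
   (default $\{0.01, 0.025, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95,
   0.975, 0.99\}$, the union of the published figure percentiles and table
   columns), evaluated at exact completed-week boundaries $w \cdot 7$ days
   for $w = 14, \dots, 40$ — matching the printed tables' week rows; the
   tables' own evaluation grid is not stated, so this is a documented
   choice.  Covariate-adjusted charts are evaluated at reference covariate
   values (female, nulliparous, the study's median maternal age 28 y,
   height 163 cm, weight 61 kg), or at any values via `at =`; for country
   models the default "global" curve is the equal-weight average of the
   country design rows.
4. **Retransform, order, round.** Fitted log-quantiles are exponentiated
   (hence every chart value is positive), made non-crossing within each
   week by rearrangement — sorting is idempotent, leaves already-monotone
   rows bit-identical, and requires no refitting — and rounded to the
   publication convention: integer mm, integer grams, two decimals for the
   FL/HC and FL/BPD ratios.  The unrounded values are kept alongside.

The quartile asymmetry of a chart is summarised by the Bowley coefficient
$((Q_3-Q_2)-(Q_2-Q_1))/(Q_3-Q_1)$ (`bowley_coefficient()`).  On the
bundled EFW chart's printed quartiles it is $+0.111$ at 15 weeks and
$-0.016$ at 40 weeks.  The published text attaches these two values to the
opposite weeks; recomputation from the printed quartiles shows the labels
transposed, and this package reports what the quartiles imply.  Note also
that at 15 weeks the quartile range is only 18 g, so integer rounding of
the printed table moves this coefficient by up to about $\pm 0.06$ — the
early-GA asymmetry is printed-precision noise as much as signal.

## The bundled WHO tables

`who_chart_bundle()` loads the published weekly tables (BPD, HC, AC, FL,
HL, EFW overall and by fetal sex, FL/HC, FL/BPD for weeks 14–40;
birthweight by neonatal sex for weeks 37–42) from plain CSV copies checked
against an MD5 manifest, so provenance is auditable.  `chart_value()` is
an exact cell lookup; `percentile_of()` places a measurement continuously:
linear interpolation in GA between week rows, then monotone
piecewise-linear inversion across percentile columns.  Choices worth
knowing:

* Outside the printed percentile range the placement is **clamped and
  flagged** (`below_min` / `above_max`), never extrapolated: tail
  extrapolation from a printed grid is statistically indefensible.
* Where integer printing ties adjacent columns (e.g. BPD at week 14 has
  identical 5th and 10th percentiles), inversion returns the midpoint of
  the tied percentile range — no single answer can round-trip both tied
  columns.
* The z-equivalent $\Phi^{-1}(p/100)$ is a reporting convenience only; the
  charts are distribution-free.
* GA interpolation is the default; `snap_weeks = TRUE` snaps to the
  completed-week row for table-faithful placement.  Both modes exist
  because the clinical convention is unspecified.
* Across-week monotonicity is *not* asserted anywhere: the printed HL
  2.5th percentile genuinely decreases from week 39 to 40.

The per-country enrolment and preterm counts are bundled likewise, and
`study_rates()` aggregates them (3.6% consent withdrawal, 7.5% preterm).

## The simulator and what passing tests mean

`simulate_cohort()` emulates the study design: ten countries × 140 women,
visits scheduled at 14/18/24/28/32/36/40 weeks with uniform ±1 week
jitter, triplicate measurements with 2% coefficient of variation reduced
to their median, ~10% missed visits, 3.6% withdrawal and 3.2% loss to
follow-up.  Maternal covariates are drawn from normal/log-normal families
calibrated to the study's printed quartiles (age median 28, IQR 25–31;
height 163, 157–168; weight 61, 55–68; 42% parous; 53.2% male) — only
quartiles are published, so the families are a documented choice.

On the log scale the generative quantile function is
$$\log Q(\tau, t) = m(t) + \sigma(t)\,z + \gamma(t)\,z^2
  + \textstyle\sum_j \beta_j(\tau) x_j + \text{country},
  \qquad z = \Phi^{-1}(\tau),$$
with $t$ the GA centred at 27 weeks.  The median curve $m$ (cubic) and the
spread $\sigma$ (quadratic) are calibrated once to the bundled EFW chart's
median and quartile columns (the cubic reproduces the printed medians to
within 0.3%).  The skew term $\gamma$ is solved *exactly* per GA from a
linear Bowley-asymmetry target running from $-0.02$ at 15 weeks to $+0.11$
at 40 weeks — the left-then-right drift the source describes — via
$\gamma = -\log(\cosh a - b \sinh a)/z_{75}^2$ with $a = \sigma z_{75}$,
so the Bowley coefficient of the true quartiles equals the target to
machine precision.  (As discussed above, the printed week-15 quartiles
imply the opposite sign; we follow the described drift and treat the
printed early-GA skew as rounding noise.)  The quantile function is
strictly increasing in $\tau$ for $|z| < \sigma/2|\gamma| \approx 4.5$,
i.e. for all ranks in $(10^{-5}, 1 - 10^{-5})$; ranks are drawn uniformly,
where this bound is never met in practice.

Covariate effect profiles are two-point percent effects per conventional
unit, linear in $\tau$: fetal sex 3.5% → 4.5% (male vs female), maternal
age 2.5% → 0.5% per 10 y, height 2% → 1% per 10 cm, weight 0.5% → 1.25%
per 10 kg, parity 1.25% → 0.25% (parous vs nulliparous).  These follow the
reported pattern — sex gaps widen with quantile; age, height and parity
effects concentrate in the lower tail; weight in the upper.  The parity
magnitude is reported inconsistently in the source (1–1.5% in one place,
1–3% in another); the default uses the smaller range.  Country effects
default to an illustrative ±5% spread; they are not estimates of the
published country contrasts, and country-recovery tests set them
explicitly.

Each subject keeps one latent uniform rank across visits — longitudinal
centile tracking — with `rank_tracking = FALSE` available to draw
independent ranks per visit.  Biometry is decomposed from the target EFW:
HC, FL, BPD and HL follow their bundled median GA profiles scaled
allometrically (exponents 0.25 for head, 0.30 for limb measurements, the
order of length-versus-weight scaling), and AC is then solved exactly
through the Hadlock formula, so the stored biometry reproduces the
intended EFW before measurement noise.

**What the recovery tests show, and what they do not.**  The pipeline
closure test simulates 1,400 subjects × 7 visits with covariate and
country effects set to zero and checks that `construct_chart()` recovers
the true 10th/50th/90th EFW curves within 2%/1.5%/2% at every week (the
observed maxima across seeds are 0.4–1.6%; Monte-Carlo error at this size
is a few tenths of a percent).  Effects are zeroed because a chart fitted
without covariates estimates the cohort's *marginal* quantiles, which sit
2–3% above the reference-covariate truth when effects are active — that
offset is a property of marginal charts, not an estimation error, and
covariate recovery is tested separately (a cohort with a constant 4% sex
and 2%/10 y age effect returns `covariate_effect_table()` estimates within
±0.8 percentage points at the same size).  Null-calibration runs use
independent ranks per visit, because the interval theory assumes
independent observations; with full centile tracking the effective sample
size is closer to the number of subjects than of scans, and intervals from
the i.i.d. theory would be honest only with cluster-robust variances,
which are out of scope.  The simulator also does not emulate real
measurement-protocol failures, digit preference, GA-dating error, or
non-random missingness — passing tests demonstrate internal consistency
of the method, not field validity of any chart fitted to real data.

The null-calibration and recovery runs use cohorts of 250–1,400 subjects
and 300–500 replicates; these sizes put the asymptotic approximations in
their working range while keeping the full suite around two minutes.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)
chart <- construct_chart(cohort$scans, cohort$subjects,
                         chart_spec("efw", taus = c(0.1, 0.5, 0.9)))
chart
plot(chart)

# clinical lookup against the bundled WHO chart
percentile_of("efw", 3475, ga_days = 280)

# the published 84 g sex gap at week 37
b <- who_chart_bundle()
sex_median_difference(b$efw_male, b$efw_female, 37)
```

## Known limitations

* Standard errors assume i.i.d. errors; no cluster-robust or bootstrap
  variance for repeated measures (charts themselves are unaffected, only
  intervals and tests).
* No conditional (velocity) charts from repeated measures, and no
  parametric LMS/GAMLSS alternatives.
* Smoothness across weeks is inherited from the GA polynomial; no spline
  or nonparametric quantile smoothing.
* Country-versus-global contrasts define "global" as the equal-weight
  average over the fitted countries within the joint model (a leave-one-out
  global is a documented alternative, not implemented).
* No multiple-testing adjustment anywhere, mirroring the source analyses;
  outputs carry the corresponding caveat.
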