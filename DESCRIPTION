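Package: fetalgrowth
Title: Quantile-Regression Fetal Growth Charts and WHO Reference Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Construction of fetal growth reference charts by quantile
    regression, together with the published WHO fetal growth charts for
    clinical percentile lookup.  Provides a from-scratch pinball-loss
    quantile-regression estimator with asymptotic standard errors and Wald
    tests; Hadlock formula-3 estimated fetal weight and the FL/HC and
    FL/BPD head ratios; a chart-construction pipeline (analysis-set
    filtering, log-scale polynomial fitting with optional maternal
    covariates and gestational-age-by-country interaction terms,
    retransformation, non-crossing enforcement); country-versus-global and
    covariate-effect comparisons with delta-method confidence intervals;
    and a longitudinal multi-country cohort simulator with closed-form
    true quantiles for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
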