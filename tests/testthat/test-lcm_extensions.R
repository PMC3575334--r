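test_that("odds ratios from risks match hand computation and invariances", {
  # worked example: risks 0.090 vs 0.050
  o <- odds_ratio_from_risks(0.090, 0.050, 0.015, 0.017)
  expect_equal(o$or, (0.09 / 0.91) / (0.05 / 0.95), tolerance = 1e-12)
  expect_equal(round(o$or, 1), 1.9)      # published as 1.89 (unrounded risks)
  expect_true(o$conf_low < o$or & o$or < o$conf_high)
  expect_equal(odds_ratio_from_risks(0.054, 0.050)$or,
               (0.054 / 0.946) / (0.05 / 0.95), tolerance = 1e-12)
  # identity and reciprocity
  expect_equal(odds_ratio_from_risks(0.3, 0.3)$or, 1)
  ab <- odds_ratio_from_risks(0.2, 0.07)$or
  ba <- odds_ratio_from_risks(0.07, 0.2)$or
  expect_equal(ab * ba, 1, tolerance = 1e-12)
  expect_error(odds_ratio_from_risks(0, 0.1), "boundary")
  # log-scale option gives a positive interval
  lg <- odds_ratio_from_risks(0.090, 0.050, 0.015, 0.017, scale = "log")
  expect_gt(lg$conf_low, 0)
})

test_that("outcome model recovers per-class risks and degrades to Model 1", {
  def <- p53_defaults()
  sim <- simulate_panel(n = 8000, seed = 2718)
  fit <- suppressWarnings(fit_lcm_outcome(sim, control = lcm_control(n_restarts = 5)))
  expect_s3_class(fit, "lcm_outcome_fit")
  expect_lt(max(abs(fit$rho - def$outcome_risks)), 0.02)
  expect_equal(fit$odds_ratios$or[3], 1)        # reference class
  expect_true(all(fit$odds_ratios$or[1:2] > 0))
  expect_true(all(is.finite(fit$se_rho)))
  # equal risks across classes push every odds ratio toward 1
  eqsim <- simulate_panel(n = 8000, outcome_risks = c(0.07, 0.07, 0.07),
                          seed = 31416)
  eqfit <- suppressWarnings(fit_lcm_outcome(eqsim, control = quick_ctl(se = TRUE)))
  expect_lt(max(abs(eqfit$odds_ratios$or[1:2] - 1)), 0.5)
  expect_true(all(eqfit$odds_ratios$conf_low[1:2] < eqfit$odds_ratios$or[1:2] &
                    eqfit$odds_ratios$or[1:2] < eqfit$odds_ratios$conf_high[1:2]))
  # no outcome column: exactly the Model 1 fit
  m1 <- fit_lcm(sim, control = quick_ctl())
  m1b <- fit_lcm_outcome(sim, outcome = NULL, control = quick_ctl())
  expect_identical(m1$loglik, m1b$loglik)
  expect_identical(m1$thetas, m1b$thetas)
})

test_that("stratified accuracy model separates strata and flags thin ones", {
  # same accuracy in both strata: LRT against the pooled model stays quiet
  sim <- simulate_panel(n = 4000, outcome_risks = c(0.5, 0.5, 0.5), seed = 123)
  pool <- fit_lcm(sim, control = quick_ctl())
  strat <- fit_lcm_stratified(sim, control = quick_ctl())
  expect_true(strat$converged)
  lrt <- likelihood_ratio_test(pool, strat)
  expect_gt(lrt$p_value, 0.05)
  expect_equal(lrt$df, strat$n_params - pool$n_params)

  # genuinely different accuracy: per-stratum estimates recover both truths
  def <- p53_defaults()
  th_shift <- def$thetas
  th_shift$DHPLC[, 1] <- c(0.964 - 0.15, 0.028 + 0.15, 0.008)
  s1 <- simulate_panel(n = 5000, outcome_risks = c(0, 0, 0), seed = 61)
  s2 <- simulate_panel(n = 5000, thetas = th_shift,
                       outcome_risks = c(1, 1, 1), seed = 62)
  both <- geno_panel(dplyr::bind_rows(s1, s2), tests = def$test_names,
                     outcome = "cytology")
  sf <- fit_lcm_stratified(both, control = quick_ctl(n_restarts = 5))
  expect_true(sf$converged)
  err1 <- max(mapply(function(a, b) max(abs(a - b)),
                     sf$thetas[["1"]], def$thetas))
  err2 <- max(mapply(function(a, b) max(abs(a - b)),
                     sf$thetas[["2"]], th_shift))
  expect_lt(err1, 0.04)
  expect_lt(err2, 0.04)

  # a stratum too thin to support its parameters is flagged, not fatal
  tiny <- simulate_panel(n = 200, outcome_risks = c(0.05, 0.05, 0.05), seed = 3)
  expect_warning(st <- fit_lcm_stratified(tiny, control = quick_ctl()),
                 "cannot support")
  expect_false(st$converged)
  expect_error(fit_lcm_stratified(simulate_panel(n = 50, outcome_risks = c(0, 0, 0),
                                                 seed = 4),
                                  control = quick_ctl()),
               "two non-empty strata")
})

test_that("dependence model reduces to independence at lambda = 0", {
  sim <- simulate_panel(n = 1500, outcome_risks = NULL, seed = 5)
  base <- fit_lcm(sim, control = quick_ctl())
  dep0 <- fit_lcm_dependent(sim, dep_pairs = c("DHPLC", "DBH"),
                            lambda_fixed = 0, start = base,
                            control = quick_ctl())
  expect_equal(dep0$loglik, base$loglik, tolerance = 1e-9)
  expect_equal(dep0$n_params, base$n_params)
  # free-lambda fit can only improve the likelihood, by construction
  dep <- fit_lcm_dependent(sim, dep_pairs = c("DHPLC", "DBH"), start = base,
                           control = quick_ctl())
  expect_gte(dep$loglik, base$loglik - 1e-6)
  expect_equal(dep$n_params, base$n_params + 1)
  expect_error(fit_lcm_dependent(sim, dep_pairs = list(c("DHPLC", "DBH"),
                                                       c("DBH", "RFLP1"))),
               "at most one")
})

test_that("dependence LRT detects a strong within-class association", {
  th <- matrix(0.075, 3, 3); diag(th) <- 0.85
  ths <- list(A = th, B = th, C = th, D = th)
  hits <- 0; lams <- numeric(0)
  for (r in 1:8) {
    dp <- data.frame(test1 = "A", test2 = "B", lambda = 1.5)
    sim <- simulate_panel(n = 5000, prevalence = c(0.38, 0.45, 0.17),
                          thetas = ths, outcome_risks = NULL, dependence = dp,
                          seed = 3000 + r)
    base <- fit_lcm(sim, control = quick_ctl(n_restarts = 2))
    dep <- fit_lcm_dependent(sim, dep_pairs = c("A", "B"), start = base,
                             control = quick_ctl(n_restarts = 2))
    lams <- c(lams, dep$lambda)
    hits <- hits + (likelihood_ratio_test(base, dep)$p_value < 0.05)
  }
  expect_gte(hits, 7)                      # >= 80% detection
  expect_equal(mean(lams), 1.5, tolerance = 0.25)
})

test_that("dependence screen covers all pairs with Bonferroni adjustment", {
  sim <- simulate_panel(n = 1200, outcome_risks = NULL, seed = 1001)
  scr <- dependence_screen(sim, control = quick_ctl(n_restarts = 2))
  expect_equal(nrow(scr), 6L)
  expect_true(all(scr$p_adjusted >= scr$p_value))
  expect_equal(scr$p_adjusted, pmin(scr$p_value * 6, 1))
  expect_true(all(scr$df == 1L))
})

test_that("likelihood ratio test contracts", {
  sim <- simulate_panel(n = 2000, outcome_risks = NULL, seed = 313)
  eq <- fit_lcm(sim, constraint = "equal_accuracy", control = quick_ctl())
  fr <- fit_lcm(sim, control = quick_ctl())
  lrt <- likelihood_ratio_test(eq, fr)
  expect_equal(lrt$df, 18)
  expect_gte(lrt$statistic, 0)
  # equal log-likelihoods: statistic 0, p 1
  richer <- fr
  richer$n_params <- fr$n_params + 1L
  same <- likelihood_ratio_test(fr, richer)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # reversed nesting must error loudly
  expect_error(likelihood_ratio_test(fr, eq), "more free parameters")
  # different data is refused
  other <- fit_lcm(simulate_panel(n = 500, outcome_risks = NULL, seed = 9),
                   control = quick_ctl())
  expect_error(likelihood_ratio_test(eq, other), "different numbers of subjects")
})
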