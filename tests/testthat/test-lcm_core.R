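test_that("subject likelihood matches closed forms and the brute-force oracle", {
  # identity test: likelihood of observing category 2 is the class-2 prevalence
  id3 <- diag(3)
  expect_equal(subject_likelihood(2L, c(0.5, 0.3, 0.2), list(id3)), 0.3)
  # full symmetry: uniform prevalence and uniform thetas
  unif <- matrix(1 / 3, 3, 3)
  expect_equal(subject_likelihood(c(1L, 3L, 2L, 1L), rep(1 / 3, 3),
                                  list(unif, unif, unif, unif)),
               (1 / 3)^4)
  # property: random parameters, calls with missing entries
  set.seed(2024)
  for (rep in 1:25) {
    C <- sample(2:4, 1)
    T <- sample(3:5, 1)
    pi <- rand_simplex(C)
    thetas <- replicate(T, rand_theta(C, C), simplify = FALSE)
    calls <- sample(seq_len(C), T, replace = TRUE)
    calls[sample(T, sample(0:(T - 1), 1))] <- NA
    expect_equal(subject_likelihood(calls, pi, thetas),
                 brute_subject_lik(calls, pi, thetas), tolerance = 1e-12)
  }
  expect_warning(out <- subject_likelihood(c(NA, NA, NA), rand_simplex(3),
                                           replicate(3, rand_theta(3, 3),
                                                     simplify = FALSE)),
                 "all calls missing")
  expect_equal(out, 1)
})

test_that("dataset log-likelihood is additive and aggregation-invariant", {
  id3 <- diag(3)
  d1 <- geno_panel(data.frame(A = 3L, B = 3L, C = 3L), tests = c("A", "B", "C"))
  expect_equal(loglik_dataset(d1, c(0.5, 0.3, 0.2), list(id3, id3, id3)),
               log(0.2))
  sim <- simulate_panel(n = 60, outcome_risks = NULL, seed = 5)
  pi <- rand_simplex(3)
  thetas <- replicate(4, rand_theta(3, 3), simplify = FALSE)
  ll1 <- loglik_dataset(sim, pi, thetas)
  trip <- geno_panel(dplyr::bind_rows(sim, sim, sim),
                     tests = panel_tests(sim))
  expect_equal(loglik_dataset(trip, pi, thetas), 3 * ll1, tolerance = 1e-10)
  # grouped representation: expanding the pattern table reproduces the value
  pt <- pattern_table(sim)
  regrouped <- pt[rep(seq_len(nrow(pt)), pt$count),
                  panel_tests(sim), drop = FALSE]
  regrouped <- geno_panel(regrouped, tests = panel_tests(sim))
  expect_equal(loglik_dataset(regrouped, pi, thetas), ll1, tolerance = 1e-10)
})

test_that("perfect tests are recovered as (near) identity matrices", {
  id3 <- diag(3)
  sim <- simulate_panel(n = 2000, prevalence = c(0.4, 0.45, 0.15),
                        thetas = list(A = id3, B = id3, C = id3, D = id3),
                        outcome_risks = NULL, seed = 31)
  fit <- fit_lcm(sim, control = quick_ctl())
  emp <- as.numeric(table(factor(sim$true_class, levels = 1:3)) / nrow(sim))
  expect_lt(max(abs(fit$prevalence - emp)), 1e-4)
  for (th in fit$thetas) expect_lt(max(abs(th - id3)), 0.01)
  expect_true(fit$converged)
})

test_that("Model 1 recovers generating parameters from simulated panels", {
  def <- p53_defaults()
  sim <- simulate_panel(n = 3000, outcome_risks = NULL, seed = 414)
  fit <- fit_lcm(sim, control = quick_ctl(n_restarts = 5))
  expect_true(fit$converged)
  theta_err <- max(mapply(function(a, b) max(abs(a - b)),
                          fit$thetas, def$thetas))
  expect_lt(theta_err, 0.04)
  expect_lt(max(abs(fit$prevalence - def$prevalence)), 0.03)
})

test_that("two-class three-test accuracies are identified without a standard", {
  thetas <- list(T1 = matrix(c(0.85, 0.15, 0.10, 0.90), 2, 2),
                 T2 = matrix(c(0.90, 0.10, 0.20, 0.80), 2, 2),
                 T3 = matrix(c(0.80, 0.20, 0.05, 0.95), 2, 2))
  sim <- simulate_panel(n = 10000, prevalence = c(0.7, 0.3), thetas = thetas,
                        outcome_risks = NULL, categories = c("neg", "pos"),
                        seed = 99)
  fit <- fit_lcm(sim, n_classes = 2, control = quick_ctl())
  for (tn in names(thetas)) {
    expect_lt(max(abs(fit$thetas[[tn]] - thetas[[tn]])), 0.03)
  }
  expect_lt(abs(fit$prevalence[2] - 0.3), 0.02)
})

test_that("EM log-likelihood never decreases and fits are seed-deterministic", {
  sim <- simulate_panel(n = 900, seed = 8)
  f1 <- fit_lcm(sim, control = quick_ctl())
  f2 <- fit_lcm(sim, control = quick_ctl())
  expect_gte(min(diff(f1$trace)), -1e-7)
  expect_identical(f1$prevalence, f2$prevalence)
  expect_identical(f1$thetas, f2$thetas)
})

test_that("fitting grouped patterns equals fitting subject-level rows", {
  sim <- simulate_panel(n = 700, outcome_risks = NULL, seed = 55,
                        missing_rates = 0.05)
  pt <- pattern_table(sim)
  expanded <- pt[rep(seq_len(nrow(pt)), pt$count), panel_tests(sim),
                 drop = FALSE]
  expanded <- geno_panel(expanded, tests = panel_tests(sim))
  f1 <- fit_lcm(sim, control = quick_ctl())
  f2 <- fit_lcm(expanded, control = quick_ctl())
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  expect_equal(f1$prevalence, f2$prevalence, tolerance = 1e-9)
  expect_equal(f1$thetas, f2$thetas, tolerance = 1e-9)
})

test_that("posterior membership matches the brute-force enumeration", {
  sim <- simulate_panel(n = 1200, outcome_risks = NULL, seed = 17)
  fit <- fit_lcm(sim, control = quick_ctl())
  # certainty under near-perfect tests
  post <- posterior_class(fit, c(2L, 2L, 2L, 2L))
  expect_gt(post[[2]][1], 0.999)
  expect_equal(sum(post[1, ]), 1, tolerance = 1e-12)
  # brute-force cross-check on random call vectors (incl. missing)
  set.seed(66)
  for (rep in 1:10) {
    calls <- sample(1:3, 4, replace = TRUE)
    calls[sample(4, sample(0:2, 1))] <- NA
    p <- as.numeric(posterior_class(fit, calls))
    brute <- vapply(1:3, function(c) {
      term <- fit$prevalence[c]
      for (t in 1:4) {
        if (!is.na(calls[t])) term <- term * fit$thetas[[t]][calls[t], c]
      }
      term
    }, numeric(1))
    expect_equal(p, unname(brute / sum(brute)), tolerance = 1e-10)
  }
  # all-missing subjects fall back to the prior
  expect_equal(as.numeric(posterior_class(fit, rep(NA_integer_, 4))),
               unname(fit$prevalence), tolerance = 1e-12)
})

test_that("standard errors behave like 1/sqrt(n)", {
  ctl <- quick_ctl(se = TRUE)
  s1 <- simulate_panel(n = 1500, outcome_risks = NULL, seed = 21)
  s4 <- simulate_panel(n = 6000, outcome_risks = NULL, seed = 22)
  f1 <- suppressWarnings(fit_lcm(s1, control = ctl))
  f4 <- suppressWarnings(fit_lcm(s4, control = ctl))
  se1 <- unlist(f1$se_thetas); se4 <- unlist(f4$se_thetas)
  keep <- se1 > 1e-4 & se4 > 1e-4      # exclude boundary-flagged entries
  ratio <- median(se4[keep] / se1[keep])
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})

test_that("input contracts: too few tests, bad class counts", {
  sim <- simulate_panel(n = 100, outcome_risks = NULL, seed = 1)
  expect_error(fit_lcm(sim, tests = c("DHPLC", "DBH")), "three tests")
  expect_error(fit_lcm(sim, n_classes = 1), "n_classes")
  # equal-accuracy constraint is allowed with fewer tests
  eq <- fit_lcm(sim, tests = c("DHPLC", "DBH", "RFLP1"),
                constraint = "equal_accuracy", control = quick_ctl())
  expect_identical(eq$thetas$DHPLC, eq$thetas$DBH)
  expect_equal(eq$n_params, 2 + 6)
})
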