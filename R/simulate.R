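#' Representative parameter values for the p53 codon 72 panel
#'
#' Default generating parameters for [simulate_panel()], emulating the
#' motivating study's structure: four laboratory methods (DHPLC, DBH, RFLP-1,
#' RFLP-2) calling a 3-level genotype (Arg/Arg, Arg/Pro, Pro/Pro), each with
#' its estimated classification-probability matrix; genotype prevalences in
#' the range observed among outcome-negative women; per-genotype two-year
#' cumulative SIL risks of 0.090 / 0.054 / 0.050; and the study's scale of
#' 911 women. Classification matrices are column-normalised so each column is
#' an exact simplex at full precision.
#'
#' @return A list with `n`, `prevalence`, `thetas`, `outcome_risks`,
#'   `test_names` and `categories`.
#' @export
p53_defaults <- function() {
  cats <- c("Arg/Arg", "Arg/Pro", "Pro/Pro")
  th <- list(
    DHPLC = matrix(c(0.964, 0.028, 0.008,
                     0.006, 0.994, 0.000,
                     0.040, 0.037, 0.923), 3, 3),
    DBH   = matrix(c(0.997, 0.020, 0.006,
                     0.011, 0.978, 0.012,
                     0.000, 0.026, 0.974), 3, 3),
    RFLP1 = matrix(c(0.957, 0.037, 0.006,
                     0.023, 0.977, 0.000,
                     0.013, 0.102, 0.886), 3, 3),
    RFLP2 = matrix(c(0.839, 0.138, 0.023,
                     0.000, 0.978, 0.022,
                     0.006, 0.014, 0.980), 3, 3))
  th <- lapply(th, function(m) {
    dimnames(m) <- list(cats, cats)
    sweep(m, 2, colSums(m), "/")
  })
  list(n = 911L,
       prevalence = stats::setNames(c(0.38, 0.45, 0.17), cats),
       thetas = th,
       outcome_risks = stats::setNames(c(0.090, 0.054, 0.050), cats),
       test_names = names(th),
       categories = cats)
}

#' Simulate a multi-test genotype panel
#'
#' Draws data from the latent class model the fitters assume: each subject's
#' true class from `Categorical(prevalence)`; an optional binary outcome from
#' `Bernoulli(outcome_risks[class])` coded 1/2; each test's call from the
#' class-conditional column of its classification matrix, independently
#' across tests except for flagged dependent pairs, which are drawn jointly
#' from the product form times `exp(lambda)` on the agreement diagonal,
#' renormalised (the same parameterization [fit_lcm_dependent()] estimates);
#' then MCAR masking of calls at per-test rates. The true class is returned
#' in a `true_class` column so recovery can be measured; fitters never read
#' it.
#'
#' Defaults reproduce the motivating study's assumed data-generating process
#' at its own scale (911 women, about 61 expected cases); see
#' [p53_defaults()].
#'
#' @param n Number of subjects.
#' @param prevalence Latent class prevalences (simplex).
#' @param thetas Named list of column-stochastic classification matrices.
#' @param outcome_risks Per-class outcome probabilities, or `NULL` for no
#'   outcome column.
#' @param dependence Optional data frame with columns `test1`, `test2`,
#'   `lambda` flagging within-class pairwise associations (each test in at
#'   most one pair).
#' @param missing_rates Per-test MCAR missingness probabilities (recycled).
#' @param seed Optional integer seed; the draw is deterministic given it and
#'   the global RNG state is left untouched.
#' @param categories Category labels.
#' @return A [geno_panel] tibble with `subject_id`, `true_class`, one column
#'   per test, and (if risks were given) a `cytology` outcome column.
#' @export
#' @examples
#' sim <- simulate_panel(n = 50, seed = 1)
#' table(sim$true_class, sim$DHPLC)
simulate_panel <- function(n = p53_defaults()$n,
                           prevalence = p53_defaults()$prevalence,
                           thetas = p53_defaults()$thetas,
                           outcome_risks = p53_defaults()$outcome_risks,
                           dependence = NULL, missing_rates = 0, seed = NULL,
                           categories = p53_defaults()$categories) {
  C <- length(prevalence)
  if (abs(sum(prevalence) - 1) > 1e-8 || any(prevalence < 0)) {
    abort_input("prevalence must be a simplex vector")
  }
  for (th in thetas) {
    if (ncol(th) != C || any(th < 0) || any(abs(colSums(th) - 1) > 1e-8)) {
      abort_input("each theta must be column-stochastic with C columns")
    }
  }
  if (!is.null(outcome_risks) &&
      (length(outcome_risks) != C || any(outcome_risks < 0 | outcome_risks > 1))) {
    abort_input("outcome_risks must be C probabilities")
  }
  T <- length(thetas)
  test_names <- names(thetas) %||% paste0("test", seq_len(T))
  missing_rates <- rep(missing_rates, length.out = T)
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    abort_input("missing_rates must lie in [0, 1)")
  }
  dep_idx <- NULL
  if (!is.null(dependence)) {
    dep_idx <- resolve_pairs(
      lapply(seq_len(nrow(dependence)),
             function(i) c(dependence$test1[i], dependence$test2[i])),
      test_names)
  }
  if (!is.null(seed)) local_seed_restore(as.integer(seed))

  x <- sample.int(C, n, replace = TRUE, prob = prevalence)
  calls <- matrix(NA_integer_, n, T, dimnames = list(NULL, test_names))
  indep <- setdiff(seq_len(T), unlist(dep_idx))
  for (t in indep) {
    K <- nrow(thetas[[t]])
    for (c in seq_len(C)) {
      idx <- which(x == c)
      if (length(idx)) {
        calls[idx, t] <- sample.int(K, length(idx), replace = TRUE,
                                    prob = thetas[[t]][, c])
      }
    }
  }
  if (!is.null(dep_idx)) {
    for (k in seq_along(dep_idx)) {
      v1 <- dep_idx[[k]][1]; v2 <- dep_idx[[k]][2]
      lam <- dependence$lambda[k]
      K <- nrow(thetas[[v1]])
      for (c in seq_len(C)) {
        idx <- which(x == c)
        if (!length(idx)) next
        J <- outer(thetas[[v1]][, c], thetas[[v2]][, c]) * exp(lam * diag(K))
        cell <- sample.int(K * K, length(idx), replace = TRUE,
                           prob = as.numeric(J / sum(J)))
        calls[idx, v1] <- ((cell - 1L) %% K) + 1L
        calls[idx, v2] <- ((cell - 1L) %/% K) + 1L
      }
    }
  }
  for (t in seq_len(T)) {
    if (missing_rates[t] > 0) {
      calls[stats::runif(n) < missing_rates[t], t] <- NA_integer_
    }
  }
  out <- tibble::tibble(subject_id = sprintf("sim%06d", seq_len(n)),
                        true_class = x)
  for (t in seq_len(T)) out[[test_names[t]]] <- calls[, t]
  outcome_col <- NULL
  if (!is.null(outcome_risks)) {
    out$cytology <- 1L + (stats::runif(n) < outcome_risks[x])
    outcome_col <- "cytology"
  }
  geno_panel(out, tests = test_names, outcome = outcome_col,
             categories = categories[seq_len(max(vapply(thetas, nrow, 1L)))],
             id = "subject_id")
}
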