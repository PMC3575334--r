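#' Latent class model with accuracy stratified by an outcome
#'
#' Relaxes the assumption that test accuracy is independent of the binary
#' outcome by giving every test a separate classification matrix in each
#' outcome stratum. Prevalences may be shared across strata (default) or
#' estimated per stratum (`share_prevalence = FALSE`, which fits each stratum
#' independently). The joint log-likelihood supports a likelihood ratio test
#' against the pooled [fit_lcm()] model.
#'
#' Doubling the accuracy parameters is demanding: when a stratum's observed
#' response patterns cannot support its parameters (fewer distinct patterns
#' than free parameters, the typical situation for a small case stratum) the
#' maximum is not unique and the fit is reported with `converged = FALSE`
#' rather than failing.
#'
#' @inheritParams fit_lcm
#' @param stratum Name of the binary stratifying column (usually the
#'   outcome); must be non-missing for every subject.
#' @param share_prevalence Share latent class prevalences across strata?
#' @return An object of class `lcm_strat_fit`: per-stratum `thetas` (a named
#'   list of [fit_lcm()]-style theta lists), `prevalence` (one vector, or one
#'   per stratum), joint `loglik`, `n_params`, `converged`, and per-stratum
#'   diagnostic flags.
#' @export
fit_lcm_stratified <- function(data, tests = panel_tests(data),
                               stratum = panel_outcome(data), n_classes = 3L,
                               share_prevalence = TRUE,
                               control = lcm_control()) {
  C <- as.integer(n_classes)
  T <- length(tests)
  if (T < 3L) abort_input("the stratified model requires at least three tests")
  if (is.null(stratum)) abort_input("a stratifying column is required")
  s_vals <- data[[stratum]]
  if (anyNA(s_vals)) abort_input("stratifying column must be non-missing")
  levs <- sort(unique(s_vals))
  if (length(levs) < 2L) abort_input("stratification needs at least two non-empty strata")
  S <- length(levs)
  n_per <- vapply(levs, function(l) sum(s_vals == l), integer(1))
  if (any(n_per == 0L)) abort_input("empty stratum")

  # distinct observed patterns per stratum, for the support check
  pat_per <- vapply(levs, function(l) {
    nrow(pattern_table(data[s_vals == l, , drop = FALSE], tests = tests))
  }, integer(1))
  per_stratum_params <- T * C * (C - 1L) + if (share_prevalence) 0L else (C - 1L)
  supported <- pat_per - 1L >= per_stratum_params
  if (any(!supported)) {
    warning(sprintf(paste0("stratum %s: %d distinct response patterns cannot ",
                           "support %d stratum-specific parameters; the fit ",
                           "is reported as non-converged"),
                    paste(levs[!supported], collapse = ", "),
                    min(pat_per[!supported]), per_stratum_params),
            call. = FALSE)
  }

  if (!share_prevalence) {
    fits <- lapply(levs, function(l) {
      fit_lcm(data[s_vals == l, , drop = FALSE], tests = tests, n_classes = C,
              control = control)
    })
    names(fits) <- as.character(levs)
    out <- structure(list(
      strata = as.character(levs), tests = tests, n_classes = C,
      share_prevalence = FALSE,
      prevalence = lapply(fits, `[[`, "prevalence"),
      thetas = lapply(fits, `[[`, "thetas"),
      se_thetas = lapply(fits, `[[`, "se_thetas"),
      boundary = lapply(fits, `[[`, "boundary"),
      fits = fits,
      loglik = sum(vapply(fits, `[[`, numeric(1), "loglik")),
      n_params = sum(vapply(fits, function(f) as.numeric(f$n_params), numeric(1))),
      n_subjects = sum(vapply(fits, `[[`, numeric(1), "n_subjects")),
      converged = all(vapply(fits, `[[`, logical(1), "em_converged")) &&
        all(supported),
      supported = stats::setNames(supported, as.character(levs))),
      class = "lcm_strat_fit")
    return(out)
  }

  # shared prevalences: one EM over stratum-specific pseudo-variables
  wide <- tibble::as_tibble(data[tests])
  cols <- list()
  for (s in seq_len(S)) {
    for (tn in tests) {
      v <- wide[[tn]]
      v[s_vals != levs[s]] <- NA_integer_
      cols[[paste0(tn, "@", levs[s])]] <- v
    }
  }
  df <- tibble::as_tibble(cols)
  pt <- dplyr::count(df, dplyr::across(dplyr::everything()), name = "count")
  Y <- as.matrix(pt[setdiff(names(pt), "count")]); storage.mode(Y) <- "integer"
  fr <- list(Y = Y, w = pt$count, ncat = rep(C, S * T), n = sum(pt$count))
  blocks <- seq_len(S * T)
  block_ncat <- rep(C, S * T)
  n_params <- (C - 1L) + S * T * C * (C - 1L)

  local_seed_restore(control$seed)
  em <- em_multistart(fr$Y, fr$w, fr$ncat, C, blocks, control$n_restarts,
                      control$max_iter, control$rel_tol)
  al <- align_classes(em$pi, em$thetas, block_ncat, C)
  st <- par_struct(C, block_ncat)
  se_thetas <- NULL
  if (control$se && all(supported)) {
    se <- engine_se(list(pi = al$pi, thetas = al$thetas), fr$Y, fr$w, blocks, st)
    sp <- split_se(se$se, C, block_ncat)
    se_thetas <- sp$thetas
  }
  get_theta <- function(s, t) al$thetas[[(s - 1L) * T + t]]
  thetas <- lapply(seq_len(S), function(s) {
    out <- lapply(seq_len(T), function(t) get_theta(s, t))
    names(out) <- tests
    out
  })
  names(thetas) <- as.character(levs)
  bnd <- lapply(thetas, function(ths) lapply(ths, function(th) th < 1e-6))
  structure(list(
    strata = as.character(levs), tests = tests, n_classes = C,
    share_prevalence = TRUE,
    prevalence = al$pi,
    thetas = thetas,
    se_thetas = se_thetas,
    boundary = bnd,
    loglik = em$loglik, trace = em$trace,
    n_params = n_params, n_subjects = fr$n,
    converged = em$converged && all(supported),
    em_converged = em$converged,
    supported = stats::setNames(supported, as.character(levs))),
    class = "lcm_strat_fit")
}

resolve_pairs <- function(dep_pairs, tests) {
  if (is.matrix(dep_pairs)) {
    dep_pairs <- lapply(seq_len(nrow(dep_pairs)), function(i) dep_pairs[i, ])
  }
  if (is.character(dep_pairs)) dep_pairs <- list(dep_pairs)
  pairs <- lapply(dep_pairs, function(p) {
    idx <- match(p, tests)
    if (length(p) != 2L || anyNA(idx)) {
      abort_input(paste("each dependence pair must name two distinct tests;",
                        "got:", paste(p, collapse = ", ")))
    }
    sort(idx)
  })
  flat <- unlist(pairs)
  if (anyDuplicated(flat)) {
    abort_input("a test may appear in at most one dependence pair")
  }
  pairs
}

#' Latent class model with pairwise conditional dependence
#'
#' Relaxes conditional independence for selected test pairs: within each
#' latent class the flagged pair's joint cell probabilities are the
#' independence product multiplied by `exp(lambda)` on the agreement diagonal
#' and renormalised, a one-parameter log-linear association per pair
#' (optionally one per pair and class). With every `lambda = 0` the model
#' reduces exactly to [fit_lcm()].
#'
#' Fitting starts from the conditional-independence EM solution (with
#' `lambda = 0`) and maximises the full likelihood by quasi-Newton (BFGS) in
#' the minimal parameterization, so the dependent fit's log-likelihood is
#' never materially below the independence fit's.
#'
#' @inheritParams fit_lcm
#' @param dep_pairs A character vector of two test names, or a list of such
#'   pairs (each test in at most one pair).
#' @param per_class One association parameter per pair and class instead of
#'   one per pair.
#' @param lambda_fixed Optional fixed value(s) for the association
#'   parameter(s); when supplied, `lambda` is held there (0 recovers the
#'   independence model) and is not counted as a free parameter.
#' @param start Optional [fit_lcm()] result on the same data used as the
#'   starting point (avoids refitting the independence model).
#' @return An `lcm_fit` whose `lambda`/`se_lambda` hold the association
#'   estimates (log odds-ratio scale) and whose `n_params` counts them.
#' @export
fit_lcm_dependent <- function(data, tests = panel_tests(data), n_classes = 3L,
                              dep_pairs, per_class = FALSE,
                              lambda_fixed = NULL, start = NULL,
                              control = lcm_control()) {
  C <- as.integer(n_classes)
  T <- length(tests)
  if (T < 3L) abort_input("the dependence model requires at least three tests")
  pairs <- resolve_pairs(dep_pairs, tests)
  K <- length(pairs)
  if (!is.null(lambda_fixed) && all(lambda_fixed == 0)) {
    # exact reduction: lambda = 0 is the conditional-independence model
    fit <- if (is.null(start)) {
      fit_lcm(data, tests = tests, n_classes = C, control = control)
    } else {
      start
    }
    attr(pairs, "per_class") <- per_class
    fit$lambda <- rep(0, K * (if (per_class) C else 1L))
    fit$se_lambda <- NULL
    fit$dep_pairs <- pairs
    fit$lambda_fixed <- 0
    fit$dep_pair_names <- lapply(pairs, function(p) tests[p])
    return(fit)
  }
  n_lambda_free <- if (is.null(lambda_fixed)) K * (if (per_class) C else 1L) else 0L
  fr <- build_frame(data, tests, C)
  blocks <- seq_len(T)
  block_ncat <- rep(C, T)
  n_params <- (C - 1L) + T * C * (C - 1L) + n_lambda_free
  identifiable <- check_identifiable(n_params, fr$ncat, fr$Y, fr$w)

  if (is.null(start)) {
    start <- fit_lcm(data, tests = tests, n_classes = C,
                     control = utils::modifyList(control, list(se = FALSE)))
  }
  attr(pairs, "per_class") <- per_class
  st <- par_struct(C, block_ncat, n_lambda = K, lambda_per_class = per_class)
  nl_total <- K * (if (per_class) C else 1L)
  lam0 <- if (is.null(lambda_fixed)) rep(0, nl_total) else
    rep(lambda_fixed, length.out = nl_total)
  start_thetas <- lapply(tests, function(tn) start$thetas[[tn]])
  par_full0 <- par_pack(start$prevalence, start_thetas, lam0, st)
  negll <- make_negll(fr$Y, fr$w, blocks, st, pairs)
  np <- length(par_full0)
  lam_idx <- (np - nl_total + 1L):np

  if (is.null(lambda_fixed)) {
    # lambda is boxed at +/- 8 (odds multipliers up to ~3000): beyond that the
    # profile likelihood is flat to machine precision and unbounded drift in a
    # boundary direction would be reported as a spuriously extreme association
    lower <- rep(-Inf, np); upper <- rep(Inf, np)
    lower[lam_idx] <- -8; upper[lam_idx] <- 8
    opt <- stats::optim(par_full0, negll, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 2000L, factr = 1e6))
    par_hat <- opt$par
  } else {
    negll_sub <- function(p) negll(c(p, lam0))
    opt <- stats::optim(par_full0[-lam_idx], negll_sub, method = "BFGS",
                        control = list(maxit = 2000L, reltol = 1e-12))
    par_hat <- c(opt$par, lam0)
  }
  u <- par_unpack(par_hat, st)
  al <- align_classes(u$pi, u$thetas, block_ncat, C)
  # permute per-class lambdas consistently with the class relabelling
  lambda <- u$lambda
  if (per_class && K > 0) {
    lambda <- as.numeric(matrix(lambda, C, K)[al$perm, , drop = FALSE])
  }
  em_like <- list(loglik = -opt$value, trace = -opt$value,
                  n_iter = as.integer(opt$counts[["function"]]),
                  converged = opt$convergence == 0L)
  ctl <- control
  if (!is.null(lambda_fixed)) ctl$se <- FALSE   # lambda held fixed: SEs of the
                                                # constrained fit are not the
                                                # free-model SEs
  fit <- finish_lcm_fit(al, em_like, fr, blocks, block_ncat, C, tests,
                        "none", n_params - n_lambda_free, identifiable, ctl,
                        categories = panel_categories(data),
                        lambda = lambda, dep_pairs = pairs)
  fit$n_params <- n_params
  fit$lambda_fixed <- lambda_fixed
  fit$dep_pair_names <- lapply(pairs, function(p) tests[p])
  fit
}

fit_loglik <- function(x) x$loglik
fit_npar <- function(x) x$n_params
fit_nsub <- function(x) x$n_subjects
fit_boundary_any <- function(x) {
  b <- x$boundary
  if (is.null(b)) return(FALSE)
  any(unlist(b))
}

#' Likelihood ratio test between nested latent class fits
#'
#' `stat = 2 (loglik_alt - loglik_null)` referred to a chi-square with
#' degrees of freedom equal to the difference in free parameter counts. The
#' caller is responsible for nesting and for fitting both models to the same
#' data (subject counts are checked). When either fit has parameters on the
#' boundary the chi-square reference is only approximate and the result
#' carries `boundary_warning = TRUE`.
#'
#' @param null_fit,alt_fit Fitted models (`lcm_fit`, `lcm_outcome_fit` or
#'   `lcm_strat_fit`), null nested in alternative.
#' @return An object of class `lcm_lrt`: `statistic`, `df`, `p_value`,
#'   `boundary_warning`, and the two log-likelihoods.
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit) {
  ll0 <- fit_loglik(null_fit); ll1 <- fit_loglik(alt_fit)
  df <- fit_npar(alt_fit) - fit_npar(null_fit)
  if (df < 1L) abort_input("alternative must have more free parameters than the null")
  if (fit_nsub(null_fit) != fit_nsub(alt_fit)) {
    abort_input("fits use different numbers of subjects; LRT requires the same data")
  }
  stat <- 2 * (ll1 - ll0)
  if (stat < -1e-6 * max(1, abs(ll1))) {
    stop(sprintf(paste("inconsistent fits: null log-likelihood (%.6f) exceeds",
                       "alternative (%.6f); an optimizer failed to find the",
                       "maximum"), ll0, ll1), call. = FALSE)
  }
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 boundary_warning = fit_boundary_any(null_fit) ||
                   fit_boundary_any(alt_fit),
                 loglik_null = ll0, loglik_alt = ll1),
            class = "lcm_lrt")
}

#' @export
print.lcm_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (x$boundary_warning) {
    cat("note: boundary parameters present; chi-square reference is approximate\n")
  }
  invisible(x)
}

#' Screen all test pairs for conditional dependence
#'
#' Fits, for each pair of tests, the one-parameter dependence model of
#' [fit_lcm_dependent()] and tests it against the shared
#' conditional-independence fit. Because `T (T - 1) / 2` pairwise tests are
#' performed, Bonferroni-adjusted p-values are reported alongside the raw
#' ones.
#'
#' @inheritParams fit_lcm
#' @return A tibble with one row per pair: `first_test`, `second_test`,
#'   `lambda`, `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
dependence_screen <- function(data, tests = panel_tests(data), n_classes = 3L,
                              control = lcm_control()) {
  base <- fit_lcm(data, tests = tests, n_classes = n_classes, control =
                    utils::modifyList(control, list(se = FALSE)))
  pairs <- utils::combn(tests, 2L)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    alt <- fit_lcm_dependent(data, tests = tests, n_classes = n_classes,
                             dep_pairs = pairs[, k], start = base,
                             control = utils::modifyList(control, list(se = FALSE)))
    lrt <- likelihood_ratio_test(base, alt)
    tibble::tibble(first_test = pairs[1, k], second_test = pairs[2, k],
                   lambda = alt$lambda, statistic = lrt$statistic,
                   df = lrt$df, p_value = lrt$p_value)
  })
  rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "bonferroni")
  rows
}
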