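#' Control parameters for latent class model fitting
#'
#' @param max_iter Maximum EM iterations per start.
#' @param rel_tol Relative log-likelihood change declaring EM convergence.
#' @param n_restarts Number of random restarts in addition to the
#'   moment-style start; the best local maximum is kept. Latent class
#'   likelihoods are multimodal, so restarts are the main defence against
#'   spurious local optima.
#' @param seed Integer seed from which all restart randomness derives.
#' @param se Compute delta-method standard errors from the numerically
#'   observed information (skip in large simulation loops for speed).
#' @return A list of class `lcm_control`.
#' @export
lcm_control <- function(max_iter = 5000L, rel_tol = 1e-8, n_restarts = 20L,
                        seed = 20130218L, se = TRUE) {
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 se = isTRUE(se)),
            class = "lcm_control")
}

# assemble the pattern-level model frame used by every fitter
build_frame <- function(data, tests, n_classes, outcome = NULL,
                        stratum = NULL) {
  pt <- pattern_table(data, tests = tests, outcome = c(outcome, stratum))
  Y <- as.matrix(pt[tests])
  storage.mode(Y) <- "integer"
  list(pt = pt, Y = Y, w = pt$count, ncat = rep(n_classes, length(tests)),
       n = sum(pt$count))
}

check_identifiable <- function(n_params, ncat, Y, w) {
  max_cells <- prod(ncat) - 1
  ok <- n_params <= max_cells
  if (!ok) {
    warning(sprintf(paste0("model not identifiable from cell counts: %d free ",
                           "parameters but only %d identifiable cells"),
                    n_params, max_cells), call. = FALSE)
  }
  ok
}

# permute latent classes to maximise total correct-classification mass over
# the square (genotype) variables; ties broken by descending prevalence
align_classes <- function(pi, thetas, ncat_blocks, C, use = NULL) {
  sq <- use %||% which(ncat_blocks == C)
  if (!length(sq) || C > 6) return(list(perm = seq_len(C), pi = pi, thetas = thetas))
  pm <- perms_of(C)
  score <- apply(pm, 1, function(perm) {
    s <- sum(vapply(sq, function(b) sum(thetas[[b]][cbind(seq_len(C), perm)]),
                    numeric(1)))
    s + 1e-9 * sum(pi[perm] * (C - seq_len(C)))   # tie-break: descending pi
  })
  perm <- pm[which.max(score), ]
  list(perm = perm, pi = pi[perm],
       thetas = lapply(thetas, function(th) th[, perm, drop = FALSE]))
}

# delta-method SEs on the probability scale from the numerical observed
# information in the minimal log-ratio parameterization
engine_se <- function(est, Y, w, blocks, st, dep_pairs = NULL) {
  negll <- make_negll(Y, w, blocks, st, dep_pairs)
  par <- par_pack(est$pi, est$thetas, est$lambda %||% numeric(0), st)
  H <- pracma::hessian(negll, par)
  rank_ok <- TRUE
  Vpar <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Vpar) || any(!is.finite(Vpar)) || any(diag(Vpar) < -1e-8)) {
    rank_ok <- FALSE
    Vpar <- tryCatch(pracma::pinv(H), error = function(e) matrix(NA_real_,
                                                                 length(par),
                                                                 length(par)))
  }
  pfun <- function(p) {
    u <- par_unpack(p, st)
    c(u$pi, unlist(u$thetas), u$lambda)
  }
  J <- pracma::jacobian(pfun, par)
  Vp <- J %*% Vpar %*% t(J)
  se <- sqrt(pmax(diag(Vp), 0))
  nl <- st$n_lambda * if (st$lambda_per_class) st$C else 1L
  se_lambda <- if (nl > 0) utils::tail(se, nl) else numeric(0)
  list(se = se, vcov = Vp, rank_ok = rank_ok, se_lambda = se_lambda)
}

split_se <- function(se_vec, C, block_ncat) {
  se_pi <- se_vec[seq_len(C)]
  pos <- C
  se_thetas <- vector("list", length(block_ncat))
  for (b in seq_along(block_ncat)) {
    K <- block_ncat[b]
    se_thetas[[b]] <- matrix(se_vec[pos + seq_len(K * C)], K, C)
    pos <- pos + K * C
  }
  list(pi = se_pi, thetas = se_thetas)
}

#' Fit a latent class model to a multi-test panel (Model 1)
#'
#' Maximum-likelihood estimation of the latent class model in which an
#' unobserved `n_classes`-level true genotype generates the observed calls of
#' each test independently (conditional independence), each test `t` having
#' its own classification-probability matrix `theta_t[r, c] = P(call r | true
#' class c)`. No test is treated as a gold standard; with `n_classes`-level
#' tests the model is identifiable from three or more tests. Estimation is by
#' EM with a closed-form M-step, multiple restarts, and missing calls skipped
#' in each subject's likelihood contribution (missingness assumed MCAR).
#'
#' Standard errors come from the numerically observed information in a
#' minimal log-ratio parameterization, delta-transformed to the probability
#' scale. Probabilities estimated on the boundary (0) are reported as 0 with
#' standard error 0 and flagged, since the information-matrix approximation
#' breaks down there. After fitting, latent classes are permuted so that the
#' total correct-classification mass across tests is maximal, which labels
#' class `c` as "true category `c`".
#'
#' @param data A [geno_panel] or data frame with integer-coded test columns.
#' @param tests Test columns to model (at least 3 under `constraint =
#'   "none"`).
#' @param n_classes Number of latent classes `C` (>= 2).
#' @param constraint `"none"`, or `"equal_accuracy"` to force one shared
#'   classification matrix across all tests.
#' @param control An [lcm_control()] list.
#' @return An object of class `lcm_fit` with components `prevalence`,
#'   `se_prevalence`, `thetas` (named list of `C x C` matrices, per test),
#'   `se_thetas`, `boundary` (logical structure flagging estimates at 0),
#'   `loglik`, `trace`, `n_iter`, `converged`, `identifiable`, `n_params`,
#'   `n_subjects`, and bookkeeping used by [likelihood_ratio_test()] and the
#'   extension fitters.
#' @seealso [fit_lcm_outcome()], [fit_lcm_dependent()],
#'   [fit_lcm_stratified()], [posterior_class()]
#' @export
#' @examples
#' sim <- simulate_panel(n = 400, seed = 7)
#' fit <- fit_lcm(sim, control = lcm_control(n_restarts = 3, se = FALSE))
#' fit$prevalence
fit_lcm <- function(data, tests = panel_tests(data), n_classes = 3L,
                    constraint = c("none", "equal_accuracy"),
                    control = lcm_control()) {
  constraint <- match.arg(constraint)
  C <- as.integer(n_classes)
  if (C < 2L) abort_input("n_classes must be >= 2")
  T <- length(tests)
  if (constraint == "none" && T < 3L) {
    abort_input("the unconstrained model requires at least three tests")
  }
  fr <- build_frame(data, tests, C)
  blocks <- if (constraint == "equal_accuracy") rep(1L, T) else seq_len(T)
  block_ncat <- rep(C, max(blocks))
  n_params <- (C - 1L) + sum((block_ncat - 1L) * C)
  identifiable <- check_identifiable(n_params, fr$ncat, fr$Y, fr$w)

  local_seed_restore(control$seed)
  em <- em_multistart(fr$Y, fr$w, fr$ncat, C, blocks, control$n_restarts,
                      control$max_iter, control$rel_tol)
  al <- align_classes(em$pi, em$thetas, block_ncat, C)

  finish_lcm_fit(al, em, fr, blocks, block_ncat, C, tests, constraint,
                 n_params, identifiable, control,
                 categories = panel_categories(data))
}

# shared assembly of an lcm_fit object (also used by the extension fitters)
finish_lcm_fit <- function(al, em, fr, blocks, block_ncat, C, tests,
                           constraint, n_params, identifiable, control,
                           categories, lambda = NULL, dep_pairs = NULL,
                           extra_class = character(0)) {
  st <- par_struct(C, block_ncat,
                   n_lambda = length(dep_pairs),
                   lambda_per_class = isTRUE(attr(dep_pairs, "per_class")))
  boundary_tol <- 1e-6
  bnd_thetas <- lapply(al$thetas, function(th) th < boundary_tol)
  bnd_pi <- al$pi < boundary_tol
  se <- NULL
  se_pi <- rep(NA_real_, C)
  se_thetas <- lapply(block_ncat, function(K) matrix(NA_real_, K, C))
  se_ok <- NA
  vcov_prob <- NULL
  se_lambda <- NULL
  if (control$se) {
    se <- engine_se(list(pi = al$pi, thetas = al$thetas, lambda = lambda),
                    fr$Y, fr$w, blocks, st, dep_pairs)
    sp <- split_se(se$se, C, block_ncat)
    se_pi <- sp$pi
    se_thetas <- sp$thetas
    se_ok <- se$rank_ok
    vcov_prob <- se$vcov
    se_lambda <- se$se_lambda
    if (!se$rank_ok && identifiable) {
      warning(paste("observed information is rank-deficient (boundary or",
                    "weakly identified parameters); SEs use a pseudo-inverse"),
              call. = FALSE)
    }
    se_pi[bnd_pi] <- 0
    for (b in seq_along(se_thetas)) se_thetas[[b]][bnd_thetas[[b]]] <- 0
  }
  # expand block-level estimates to per-test views
  thetas_test <- lapply(seq_along(tests), function(v) {
    th <- al$thetas[[blocks[v]]]
    dimnames(th) <- list(categories[seq_len(nrow(th))],
                         categories[seq_len(C)])
    th
  })
  se_test <- lapply(seq_along(tests), function(v) se_thetas[[blocks[v]]])
  bnd_test <- lapply(seq_along(tests), function(v) bnd_thetas[[blocks[v]]])
  names(thetas_test) <- names(se_test) <- names(bnd_test) <- tests

  structure(list(
    test_names = tests, categories = categories, n_classes = C,
    constraint = constraint,
    prevalence = stats::setNames(al$pi, categories[seq_len(C)]),
    se_prevalence = se_pi,
    thetas = thetas_test, se_thetas = se_test,
    boundary = list(prevalence = bnd_pi, thetas = bnd_test),
    lambda = lambda, se_lambda = se_lambda, dep_pairs = dep_pairs,
    loglik = em$loglik, trace = em$trace, n_iter = em$n_iter,
    converged = em$converged && identifiable,
    em_converged = em$converged,
    identifiable = identifiable, se_ok = se_ok,
    n_params = n_params + st$n_lambda *
      if (st$lambda_per_class) C else 1L,
    n_subjects = fr$n, n_patterns = nrow(fr$Y),
    vcov_prob = vcov_prob,
    engine = list(Y = fr$Y, w = fr$w, blocks = blocks,
                  block_ncat = block_ncat, st = st,
                  thetas_block = al$thetas),
    control = control),
    class = c(extra_class, "lcm_fit"))
}

#' Likelihood of one subject's calls under given parameters
#'
#' The mixture likelihood `sum_c pi_c * prod_t theta_t[r_t | c]` with missing
#' calls skipped. With every call missing the subject is uninformative and
#' contributes likelihood 1 (with a warning).
#'
#' @param calls Integer vector of length T (NA = missing).
#' @param prevalence Latent class prevalences (simplex of length C).
#' @param thetas List of T classification matrices (`n_cat x C`).
#' @return A single probability.
#' @export
subject_likelihood <- function(calls, prevalence, thetas) {
  stopifnot(length(calls) == length(thetas))
  if (all(is.na(calls))) {
    warning("all calls missing: subject contributes likelihood 1", call. = FALSE)
    return(1)
  }
  Y <- matrix(as.integer(calls), 1L)
  sum(lik_matrix(Y, prevalence, thetas))
}

#' Log-likelihood of a dataset under given parameters
#'
#' Sum over subjects of the log of [subject_likelihood()], computed on the
#' grouped pattern representation. Zero-probability patterns are floored at
#' `1e-300` (with the resulting very negative contribution) rather than
#' returning `-Inf`.
#'
#' @param data A [geno_panel] or data frame.
#' @param prevalence,thetas Parameters as in [subject_likelihood()]; `thetas`
#'   may be named by test.
#' @param tests Test columns, defaulting to the panel attribute.
#' @return The log-likelihood (a scalar, `<= 0` for non-degenerate data).
#' @export
loglik_dataset <- function(data, prevalence, thetas,
                           tests = panel_tests(data)) {
  stopifnot(length(thetas) == length(tests))
  fr <- build_frame(data, tests, length(prevalence))
  pattern_loglik(fr$Y, fr$w, prevalence, thetas, seq_along(thetas))
}

#' Posterior class membership given a fitted model
#'
#' `P(true class = c | calls) \\propto pi_c * prod_t theta_t[r_t | c]`. For a
#' subject with every call missing the prior prevalences are returned.
#'
#' @param fit An [fit_lcm()] result.
#' @param calls An integer vector of length T, or a data frame / matrix with
#'   the fit's test columns.
#' @return A tibble with one row per subject and one `posterior` column per
#'   class (rows sum to 1).
#' @export
posterior_class <- function(fit, calls) {
  stopifnot(inherits(fit, "lcm_fit"))
  if (is.data.frame(calls)) {
    Y <- as.matrix(calls[fit$test_names])
  } else if (is.matrix(calls)) {
    Y <- calls
  } else {
    Y <- matrix(as.integer(calls), 1L)
  }
  storage.mode(Y) <- "integer"
  stopifnot(ncol(Y) == length(fit$test_names))
  A <- lik_matrix(Y, fit$prevalence, fit$thetas, seq_along(fit$thetas),
                  dep = fit_dep_list(fit))
  post <- A / rowSums(A)
  colnames(post) <- fit$categories[seq_len(fit$n_classes)]
  tibble::as_tibble(post)
}

# dependence structure of a fit in lik_matrix() form (NULL if independent)
fit_dep_list <- function(fit) {
  if (is.null(fit$dep_pairs) || !length(fit$dep_pairs)) return(NULL)
  per_class <- isTRUE(attr(fit$dep_pairs, "per_class"))
  lapply(seq_along(fit$dep_pairs), function(k) {
    lam <- if (per_class) {
      fit$lambda[(k - 1) * fit$n_classes + seq_len(fit$n_classes)]
    } else {
      fit$lambda[k]
    }
    list(vars = fit$dep_pairs[[k]], lambda = lam)
  })
}
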