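#' Odds ratios from per-class outcome risks
#'
#' Converts cumulative risks into the odds ratio against a reference risk,
#' `OR = [rho / (1 - rho)] / [rho_ref / (1 - rho_ref)]`, with a delta-method
#' standard error and confidence interval. The default interval is symmetric
#' on the OR scale (matching the reporting convention of the motivating
#' study); `scale = "log"` gives the usual log-scale Wald interval instead.
#'
#' @param rho Risk(s) in (0, 1) for the index class(es); vectorised.
#' @param rho_ref Reference-class risk in (0, 1).
#' @param se_rho,se_ref Standard errors (default `NA`: point estimate only).
#' @param cov Covariance(s) between `rho` and `rho_ref` (default 0).
#' @param level Confidence level.
#' @param scale `"linear"` (symmetric on the OR scale) or `"log"`.
#' @return A tibble with `or`, `se_or`, `conf_low`, `conf_high`.
#' @export
#' @examples
#' odds_ratio_from_risks(0.090, 0.050, 0.015, 0.017)
odds_ratio_from_risks <- function(rho, rho_ref, se_rho = NA_real_,
                                  se_ref = NA_real_, cov = 0, level = 0.95,
                                  scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (any(rho <= 0 | rho >= 1) || rho_ref <= 0 || rho_ref >= 1) {
    abort_input("risks must lie strictly inside (0, 1); boundary risks give an undefined odds ratio")
  }
  or <- (rho / (1 - rho)) / (rho_ref / (1 - rho_ref))
  g1 <- or / (rho * (1 - rho))
  g2 <- -or / (rho_ref * (1 - rho_ref))
  v <- g1^2 * se_rho^2 + g2^2 * se_ref^2 + 2 * g1 * g2 * cov
  se_or <- sqrt(pmax(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (scale == "linear") {
    lo <- or - z * se_or
    hi <- or + z * se_or
  } else {
    se_log <- se_or / or
    lo <- exp(log(or) - z * se_log)
    hi <- exp(log(or) + z * se_log)
  }
  tibble::tibble(or = or, se_or = se_or, conf_low = lo, conf_high = hi)
}

#' Latent class model with a linked binary outcome (Model 2)
#'
#' Extends [fit_lcm()] by modelling, jointly with the test panel, the
#' probability `rho_c` that a subject in latent class `c` experiences the
#' binary outcome (here, the two-year cumulative risk of SIL). The outcome
#' enters the likelihood as one more conditionally independent binary
#' variable, so test accuracy is assumed independent of outcome status. The
#' fit reports the per-class risks with standard errors and the
#' misclassification-corrected odds ratios of each class against a reference
#' class (Pro/Pro, the last class, by default).
#'
#' With `outcome = NULL` the model degrades exactly to Model 1: the result
#' equals `fit_lcm(data, tests, ...)`.
#'
#' @inheritParams fit_lcm
#' @param outcome Name of the binary outcome column (1 = negative, 2 = case).
#' @param ref_class Reference class for odds ratios (default: last class).
#' @param or_scale Confidence-interval convention passed to
#'   [odds_ratio_from_risks()].
#' @return An object of class `lcm_outcome_fit` (inheriting from `lcm_fit`):
#'   the embedded Model 1 quantities plus `rho`, `se_rho`, `vcov_rho`,
#'   `ref_class` and `odds_ratios` (a tibble with one row per class).
#' @export
fit_lcm_outcome <- function(data, tests = panel_tests(data),
                            outcome = panel_outcome(data), n_classes = 3L,
                            constraint = c("none", "equal_accuracy"),
                            ref_class = n_classes,
                            or_scale = c("linear", "log"),
                            control = lcm_control()) {
  constraint <- match.arg(constraint)
  or_scale <- match.arg(or_scale)
  if (is.null(outcome)) {
    return(fit_lcm(data, tests, n_classes, constraint, control))
  }
  C <- as.integer(n_classes)
  T <- length(tests)
  if (constraint == "none" && T < 3L) {
    abort_input("the unconstrained model requires at least three tests")
  }
  vars <- c(tests, outcome)
  pt <- pattern_table(data, tests = tests, outcome = outcome)
  Y <- as.matrix(pt[vars]); storage.mode(Y) <- "integer"
  fr <- list(pt = pt, Y = Y, w = pt$count,
             ncat = c(rep(C, T), 2L), n = sum(pt$count))
  geno_blocks <- if (constraint == "equal_accuracy") rep(1L, T) else seq_len(T)
  blocks <- c(geno_blocks, max(geno_blocks) + 1L)
  block_ncat <- c(rep(C, max(geno_blocks)), 2L)
  n_params <- (C - 1L) + sum((block_ncat - 1L) * C)
  identifiable <- check_identifiable(n_params, fr$ncat, fr$Y, fr$w)

  local_seed_restore(control$seed)
  em <- em_multistart(fr$Y, fr$w, fr$ncat, C, blocks, control$n_restarts,
                      control$max_iter, control$rel_tol)
  al <- align_classes(em$pi, em$thetas, block_ncat, C,
                      use = which(seq_along(block_ncat) < length(block_ncat) &
                                    block_ncat == C))

  fit <- finish_lcm_fit(al, em, fr, blocks, block_ncat, C, vars, constraint,
                        n_params, identifiable, control,
                        categories = panel_categories(data),
                        extra_class = "lcm_outcome_fit")
  ob <- length(block_ncat)              # outcome block index (last)
  rho <- al$thetas[[ob]][2L, ]
  se_rho <- fit$se_thetas[[outcome]][2L, ]
  # covariance of the rho vector from the probability-scale vcov
  vcov_rho <- matrix(NA_real_, C, C)
  if (!is.null(fit$vcov_prob)) {
    off <- C + sum(block_ncat[-ob] * C)
    idx <- off + (seq_len(C) - 1L) * 2L + 2L
    vcov_rho <- fit$vcov_prob[idx, idx, drop = FALSE]
  }
  boundary_rho <- fit$boundary$thetas[[outcome]][2L, ]
  ors <- purrr::map_dfr(seq_len(C), function(c) {
    if (c == ref_class) {
      return(tibble::tibble(class = c, or = 1, se_or = NA_real_,
                            conf_low = NA_real_, conf_high = NA_real_))
    }
    if (boundary_rho[c] || boundary_rho[ref_class] ||
        rho[c] <= 0 || rho[c] >= 1 || rho[ref_class] <= 0 ||
        rho[ref_class] >= 1) {
      warning("outcome risk at boundary: odds ratio undefined for class ",
              c, call. = FALSE)
      return(tibble::tibble(class = c, or = NA_real_, se_or = NA_real_,
                            conf_low = NA_real_, conf_high = NA_real_))
    }
    o <- odds_ratio_from_risks(rho[c], rho[ref_class], se_rho[c],
                               se_rho[ref_class],
                               cov = vcov_rho[c, ref_class], scale = or_scale)
    tibble::tibble(class = c, or = o$or, se_or = o$se_or,
                   conf_low = o$conf_low, conf_high = o$conf_high)
  })
  ors$genotype <- fit$categories[ors$class]
  ors$reference <- ors$class == ref_class

  # strip the outcome pseudo-test from the per-test views
  keep <- tests
  fit$thetas <- fit$thetas[keep]
  fit$se_thetas <- fit$se_thetas[keep]
  fit$boundary$thetas <- fit$boundary$thetas[keep]
  fit$test_names <- tests
  fit$outcome <- outcome
  fit$rho <- stats::setNames(rho, fit$categories[seq_len(C)])
  fit$se_rho <- se_rho
  fit$boundary_rho <- boundary_rho
  fit$vcov_rho <- vcov_rho
  fit$ref_class <- ref_class
  fit$odds_ratios <- ors[, c("genotype", "class", "reference", "or", "se_or",
                             "conf_low", "conf_high")]
  fit
}
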