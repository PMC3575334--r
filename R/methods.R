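#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @export
print.lcm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Latent class model: %d classes, %d tests, n = %d\n",
              x$n_classes, length(x$test_names), x$n_subjects))
  cat(sprintf("log-likelihood %.3f on %d free parameters; %s after %d EM iterations\n",
              x$loglik, x$n_params,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("\nClass prevalences:\n")
  print(round(x$prevalence, digits))
  for (tn in x$test_names) {
    cat(sprintf("\n%s: P(call | true class)%s\n", tn,
                if (any(x$boundary$thetas[[tn]])) "  [* boundary at 0]" else ""))
    m <- matrix(sprintf(paste0("%.", digits, "f (%.", digits, "f)%s"),
                        x$thetas[[tn]], x$se_thetas[[tn]],
                        ifelse(x$boundary$thetas[[tn]], "*", "")),
                nrow(x$thetas[[tn]]), dimnames = dimnames(x$thetas[[tn]]))
    print(m, quote = FALSE)
  }
  if (inherits(x, "lcm_outcome_fit")) {
    cat("\nPer-class outcome risk and odds ratios:\n")
    df <- x$odds_ratios
    df$rho <- x$rho[df$class]
    df$se_rho <- x$se_rho[df$class]
    print(as.data.frame(df[c("genotype", "rho", "se_rho", "or",
                             "conf_low", "conf_high")]), digits = digits)
  }
  if (!is.null(x$lambda)) {
    cat("\nDependence parameters (log-linear agreement terms):\n")
    for (k in seq_along(x$dep_pair_names)) {
      cat(sprintf("  %s-%s: %.4f\n", x$dep_pair_names[[k]][1],
                  x$dep_pair_names[[k]][2], x$lambda[k]))
    }
  }
  invisible(x)
}

#' Tidy a latent class fit
#'
#' One row per estimated probability: prevalence rows (`parameter =
#' "prevalence"`), classification-probability rows (`parameter = "theta"`,
#' with `test`, `category` = reported call, `true_class`), and, for outcome
#' fits, per-class outcome risks (`parameter = "risk"`) and odds ratios
#' (`parameter = "odds_ratio"`).
#'
#' @param x An `lcm_fit` or `lcm_outcome_fit`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `test`, `category`,
#'   `true_class`, `estimate`, `std_error`, `boundary`.
#' @method tidy lcm_fit
#' @export
tidy.lcm_fit <- function(x, ...) {
  C <- x$n_classes
  cats <- x$categories[seq_len(C)]
  prev <- tibble::tibble(parameter = "prevalence", test = NA_character_,
                         category = NA_character_, true_class = cats,
                         estimate = as.numeric(x$prevalence),
                         std_error = x$se_prevalence,
                         boundary = x$boundary$prevalence)
  th <- purrr::map_dfr(x$test_names, function(tn) {
    m <- x$thetas[[tn]]
    tibble::tibble(parameter = "theta", test = tn,
                   category = rep(rownames(m), C),
                   true_class = rep(cats, each = nrow(m)),
                   estimate = as.numeric(m),
                   std_error = as.numeric(x$se_thetas[[tn]]),
                   boundary = as.logical(x$boundary$thetas[[tn]]))
  })
  out <- dplyr::bind_rows(prev, th)
  if (inherits(x, "lcm_outcome_fit")) {
    risk <- tibble::tibble(parameter = "risk", test = NA_character_,
                           category = NA_character_, true_class = cats,
                           estimate = as.numeric(x$rho),
                           std_error = x$se_rho,
                           boundary = x$boundary_rho)
    ors <- tibble::tibble(parameter = "odds_ratio", test = NA_character_,
                          category = NA_character_,
                          true_class = x$odds_ratios$genotype,
                          estimate = x$odds_ratios$or,
                          std_error = x$odds_ratios$se_or,
                          boundary = FALSE)
    out <- dplyr::bind_rows(out, risk, ors)
  }
  if (!is.null(x$lambda)) {
    lam <- tibble::tibble(parameter = "lambda",
                          test = vapply(x$dep_pair_names, paste,
                                        character(1), collapse = ":"),
                          category = NA_character_, true_class = NA_character_,
                          estimate = x$lambda,
                          std_error = x$se_lambda %||% NA_real_,
                          boundary = FALSE)
    out <- dplyr::bind_rows(out, lam)
  }
  out
}

#' One-line model summary
#'
#' @param x An `lcm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `loglik`, `n_params`, `df_residual` (identifiable
#'   cells minus parameters), `n`, `n_patterns`, `converged`, `identifiable`,
#'   `n_boundary`, `n_iter`.
#' @method glance lcm_fit
#' @export
glance.lcm_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_params = x$n_params,
                 n = x$n_subjects, n_patterns = x$n_patterns,
                 converged = x$converged, identifiable = x$identifiable,
                 n_boundary = sum(unlist(x$boundary)),
                 n_iter = x$n_iter)
}

#' @method tidy lcm_lrt
#' @export
tidy.lcm_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 boundary_warning = x$boundary_warning,
                 loglik_null = x$loglik_null, loglik_alt = x$loglik_alt)
}

#' @method glance lcm_lrt
#' @export
glance.lcm_lrt <- function(x, ...) tidy.lcm_lrt(x)

#' Plot classification probabilities of a latent class fit
#'
#' Heatmap of `P(reported category | true class)` per test, with boundary
#' estimates marked.
#'
#' @param object An `lcm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcm_fit
#' @export
autoplot.lcm_fit <- function(object, ...) {
  df <- dplyr::filter(tidy.lcm_fit(object), .data$parameter == "theta")
  df$category <- factor(df$category, levels = rev(object$categories))
  df$true_class <- factor(df$true_class, levels = object$categories)
  ggplot2::ggplot(df, ggplot2::aes(.data$true_class, .data$category,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f%s", .data$estimate,
                      ifelse(.data$boundary, "*", ""))), size = 3) +
    ggplot2::facet_wrap(~test) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "firebrick3") +
    ggplot2::labs(x = "true class", y = "reported category",
                  fill = "P(call | class)",
                  caption = "* estimate on the boundary (reported 0, SE 0)") +
    ggplot2::theme_minimal()
}

#' Forest plot of misclassification-corrected odds ratios
#'
#' @param object An `lcm_outcome_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcm_outcome_fit
#' @export
autoplot.lcm_outcome_fit <- function(object, ...) {
  df <- object$odds_ratios
  df$genotype <- factor(df$genotype, levels = rev(df$genotype))
  ggplot2::ggplot(df, ggplot2::aes(.data$or, .data$genotype)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "odds ratio of outcome (vs. reference class)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.lcm_strat_fit <- function(x, ...) {
  cat(sprintf("Stratified-accuracy latent class model: %d classes, %d tests, strata %s\n",
              x$n_classes, length(x$tests), paste(x$strata, collapse = ", ")))
  cat(sprintf("joint log-likelihood %.3f on %d parameters; %s\n",
              x$loglik, x$n_params,
              if (x$converged) "converged" else "NOT converged"))
  if (any(!x$supported)) {
    cat("unsupported strata (patterns < parameters):",
        paste(names(x$supported)[!x$supported], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method glance lcm_strat_fit
#' @export
glance.lcm_strat_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_params = x$n_params, n = x$n_subjects,
                 converged = x$converged,
                 n_unsupported_strata = sum(!x$supported))
}
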