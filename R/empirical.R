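#' Empirical genotype prevalences by outcome group
#'
#' The no-latent-variable comparator: for one test, the observed proportion
#' of each call category among cases and non-cases, ignoring the possibility
#' of test error. Subjects missing this test's call are excluded for this
#' test only (no listwise deletion across tests), so different tests may use
#' different denominators. Standard errors are binomial,
#' `sqrt(p (1 - p) / n)`.
#'
#' @param data A [geno_panel] with an outcome column.
#' @param test Name of the test column.
#' @param outcome Name of the binary outcome column (1 = non-case, 2 = case).
#' @return A tibble with one row per category and group: `test`, `category`,
#'   `group` (`"case"` / `"noncase"`), `count`, `n`, `prevalence`, `se`.
#' @export
empirical_prevalence <- function(data, test, outcome = panel_outcome(data)) {
  if (is.null(outcome)) abort_input("an outcome column is required")
  if (!test %in% names(data)) abort_input(paste("unknown test label:", test))
  cats <- panel_categories(data)
  calls <- data[[test]]
  oc <- data[[outcome]]
  keep <- !is.na(calls) & !is.na(oc)
  calls <- calls[keep]; oc <- oc[keep]
  rows <- purrr::map_dfr(c(case = 2L, noncase = 1L), function(g) {
    sel <- calls[oc == g]
    n <- length(sel)
    if (n == 0L) abort_input("empty outcome group: prevalence undefined")
    cnt <- tabulate(sel, nbins = length(cats))
    p <- cnt / n
    tibble::tibble(category = cats, count = cnt, n = n, prevalence = p,
                   se = sqrt(p * (1 - p) / n))
  }, .id = "group")
  dplyr::bind_cols(tibble::tibble(test = test), rows)
}

#' Empirical odds ratio of the outcome for one test
#'
#' Odds ratio of being a case for subjects called `category` versus
#' `ref_category` by a single test, from the observed 2x2 table and ignoring
#' test error. The default confidence interval is symmetric on the OR scale
#' (the motivating study's reporting convention), using the delta-method
#' standard error `OR * sqrt(1/a + 1/b + 1/c + 1/d)`; `scale = "log"` gives
#' the standard log-scale Wald interval.
#'
#' @inheritParams empirical_prevalence
#' @param category Index of the exposure category of interest.
#' @param ref_category Reference category (default: last category, Pro/Pro
#'   under the standard coding).
#' @param level Confidence level.
#' @param scale `"linear"` or `"log"` interval convention.
#' @param correction Add 0.5 to every cell when a zero cell is present
#'   (otherwise a zero cell is an error).
#' @return A one-row tibble: `test`, `category`, `ref_category`, the four
#'   cell counts, `or`, `se_or`, `conf_low`, `conf_high`.
#' @export
empirical_or <- function(data, test, category,
                         ref_category = length(panel_categories(data)),
                         outcome = panel_outcome(data), level = 0.95,
                         scale = c("linear", "log"), correction = FALSE) {
  scale <- match.arg(scale)
  if (is.null(outcome)) abort_input("an outcome column is required")
  calls <- data[[test]]
  oc <- data[[outcome]]
  keep <- !is.na(calls) & !is.na(oc)
  calls <- calls[keep]; oc <- oc[keep]
  a <- sum(calls == category & oc == 2L)      # exposed cases
  b <- sum(calls == ref_category & oc == 2L)  # reference cases
  c_ <- sum(calls == category & oc == 1L)     # exposed non-cases
  d <- sum(calls == ref_category & oc == 1L)  # reference non-cases
  cells <- c(a, b, c_, d)
  if (any(cells == 0L)) {
    if (!correction) {
      abort_input(paste("zero cell in the 2x2 table; set correction = TRUE",
                        "for a 0.5 continuity correction"))
    }
    cells <- cells + 0.5
  }
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  se_log <- sqrt(sum(1 / cells))
  se_or <- or * se_log
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (scale == "linear") {
    lo <- or - z * se_or; hi <- or + z * se_or
  } else {
    lo <- exp(log(or) - z * se_log); hi <- exp(log(or) + z * se_log)
  }
  tibble::tibble(test = test, category = panel_categories(data)[category],
                 ref_category = panel_categories(data)[ref_category],
                 n_case_cat = a, n_case_ref = b,
                 n_noncase_cat = c_, n_noncase_ref = d,
                 or = or, se_or = se_or, conf_low = lo, conf_high = hi)
}

#' Empirical prevalence and odds-ratio summary for all tests
#'
#' Convenience wrapper running [empirical_prevalence()] and [empirical_or()]
#' for every test and non-reference category, mirroring the per-test
#' empirical comparison layout of the motivating study.
#'
#' @inheritParams empirical_prevalence
#' @param tests Test columns to summarise.
#' @param ref_category Reference category for odds ratios.
#' @return A tibble of class `genolcm_empirical`: one row per test and
#'   category with case/non-case prevalences (and SEs) and the OR with CI
#'   (reference rows have `or = 1` and `NA` intervals).
#' @export
empirical_table <- function(data, tests = panel_tests(data),
                            outcome = panel_outcome(data),
                            ref_category = length(panel_categories(data))) {
  cats <- panel_categories(data)
  rows <- purrr::map_dfr(tests, function(tn) {
    prev <- empirical_prevalence(data, tn, outcome)
    wide <- tidyr::pivot_wider(
      prev[c("category", "group", "prevalence", "se")],
      names_from = "group", values_from = c("prevalence", "se"))
    wide$test <- tn
    ors <- purrr::map_dfr(seq_along(cats), function(k) {
      if (k == ref_category) {
        return(tibble::tibble(category = cats[k], or = 1,
                              conf_low = NA_real_, conf_high = NA_real_))
      }
      o <- empirical_or(data, tn, k, ref_category, outcome)
      tibble::tibble(category = cats[k], or = o$or,
                     conf_low = o$conf_low, conf_high = o$conf_high)
    })
    dplyr::left_join(wide, ors, by = "category")
  })
  out <- rows[c("test", "category", "prevalence_case", "se_case",
                "prevalence_noncase", "se_noncase", "or",
                "conf_low", "conf_high")]
  class(out) <- c("genolcm_empirical", class(out))
  out
}
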