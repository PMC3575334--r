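#' Crude agreement for a test pair
#'
#' Proportion of subjects receiving identical calls from both tests, among
#' subjects with both calls observed (the missing margin is excluded).
#'
#' @param tab A `pair_xtab` from [crosstab_pair()], or a square count matrix.
#' @return A single proportion in `[0, 1]`, at full precision.
#' @export
crude_agreement <- function(tab) {
  m <- xtab_matrix(tab)
  n <- sum(m)
  if (n == 0) abort_input("crude agreement undefined: table has zero total")
  sum(diag(m)) / n
}

xtab_matrix <- function(tab) {
  m <- if (inherits(tab, "pair_xtab")) tab$counts else as.matrix(tab)
  if (nrow(m) != ncol(m)) abort_input("expected a square C x C count table")
  m
}

#' Cohen's kappa with optional Cicchetti-Allison linear weights
#'
#' Chance-corrected agreement for a pair of categorical tests. With
#' `weights = "linear"` the Cicchetti-Allison weights
#' \eqn{w_{ij} = 1 - |i - j| / (C - 1)} give partial credit to near-miss
#' disagreements (an Arg/Arg vs. Arg/Pro discrepancy is penalised half as
#' much as Arg/Arg vs. Pro/Pro). Asymptotic standard errors use the
#' large-sample variance of the weighted kappa of Fleiss, Cohen and Everitt;
#' the unweighted ASE is the same formula with identity weights.
#'
#' @inheritParams crude_agreement
#' @param weights `"none"` for the classical unweighted kappa, `"linear"` for
#'   Cicchetti-Allison weights.
#' @return A one-row tibble: `first_test`, `second_test`, `stratum`, `n`,
#'   `weights`, `crude`, `kappa`, `ase`.
#' @export
#' @examples
#' tab <- matrix(c(40, 5, 0, 5, 40, 5, 0, 5, 40), 3, 3)
#' cohen_kappa(tab)
#' cohen_kappa(tab, weights = "linear")
cohen_kappa <- function(tab, weights = c("none", "linear")) {
  weights <- match.arg(weights)
  m <- xtab_matrix(tab)
  n <- sum(m)
  if (n == 0) abort_input("kappa undefined: table has zero total")
  C <- nrow(m)
  w <- if (weights == "linear" && C > 1) {
    1 - abs(outer(seq_len(C), seq_len(C), "-")) / (C - 1)
  } else {
    diag(C)
  }
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (abs(1 - pe) < 1e-12) {
    abort_input("kappa undefined: degenerate marginals give expected agreement 1")
  }
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance (not assuming kappa = 0)
  wbar_r <- as.vector(w %*% pc)   # row-category weighted column margin
  wbar_c <- as.vector(pr %*% w)
  term <- (w * (1 - pe) - outer(wbar_r, rep(1, C)) * (1 - po) -
             outer(rep(1, C), wbar_c) * (1 - po))^2
  v <- (sum(p * term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  tibble::tibble(
    first_test = if (inherits(tab, "pair_xtab")) tab$first_test else NA_character_,
    second_test = if (inherits(tab, "pair_xtab")) tab$second_test else NA_character_,
    stratum = if (inherits(tab, "pair_xtab")) tab$stratum else NA_character_,
    n = n, weights = weights,
    crude = sum(diag(m)) / n,
    kappa = kap,
    ase = sqrt(max(v, 0)))
}

#' Pairwise agreement summary across all tests
#'
#' Crude agreement plus unweighted and linear-weighted kappa (with ASEs) for
#' every pair of tests, computed from subjects with both members of the pair
#' observed.
#'
#' @param data A [geno_panel] (or data frame plus `tests`).
#' @param tests Test columns to compare.
#' @return A tibble of class `genolcm_agreement`, one row per pair, with
#'   columns `first_test`, `second_test`, `n`, `crude`, `kappa`, `ase`,
#'   `kappa_weighted`, `ase_weighted`.
#' @export
agreement_table <- function(data, tests = panel_tests(data)) {
  pairs <- utils::combn(tests, 2L)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    tab <- crosstab_pair(data, pairs[1, k], pairs[2, k], stratify = FALSE)
    u <- cohen_kappa(tab, "none")
    w <- cohen_kappa(tab, "linear")
    tibble::tibble(first_test = pairs[1, k], second_test = pairs[2, k],
                   n = u$n, crude = u$crude,
                   kappa = u$kappa, ase = u$ase,
                   kappa_weighted = w$kappa, ase_weighted = w$ase)
  })
  class(rows) <- c("genolcm_agreement", class(rows))
  rows
}

#' Plot pairwise kappa agreement
#'
#' Tile plot of the weighted (or unweighted) kappa for every test pair.
#'
#' @param x An agreement table from [agreement_table()].
#' @param which `"weighted"` or `"unweighted"`.
#' @return A ggplot object.
#' @export
plot_agreement <- function(x, which = c("weighted", "unweighted")) {
  which <- match.arg(which)
  val <- if (which == "weighted") x$kappa_weighted else x$kappa
  df <- tibble::tibble(first_test = x$first_test, second_test = x$second_test,
                       kappa = val)
  ggplot2::ggplot(df, ggplot2::aes(.data$first_test, .data$second_test,
                                   fill = .data$kappa)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$kappa))) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue4") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (which == "weighted") "weighted\nkappa" else "kappa",
                  title = sprintf("Pairwise %s kappa", which)) +
    ggplot2::theme_minimal()
}

#' @method autoplot genolcm_agreement
#' @export
autoplot.genolcm_agreement <- function(object, ...) plot_agreement(object, ...)
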