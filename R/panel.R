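#' Multi-test genotype panels
#'
#' A `geno_panel` is an ordinary tibble with one row per subject, one integer
#' column per laboratory test (categories coded `1..C`, `NA` for a missing
#' call) and, optionally, a binary outcome column coded `1` (outcome-negative)
#' / `2` (case). The constructor validates the coding and records which
#' columns are tests, which column (if any) is the outcome, and the category
#' labels, so downstream functions need not be told again.
#'
#' The default coding follows the p53 codon 72 convention used throughout the
#' package: category 1 = Arg/Arg, 2 = Arg/Pro, 3 = Pro/Pro; outcome 1 =
#' negative cytology, 2 = any-grade squamous intraepithelial lesion (SIL).
#'
#' @param data A data frame with one row per subject.
#' @param tests Character vector naming the test columns, in order.
#' @param outcome Optional name of the binary outcome column.
#' @param categories Character vector of category labels; its length fixes the
#'   number of categories `C`.
#' @param id Optional name of a subject identifier column; checked for
#'   duplicates when given.
#'
#' @return A tibble of class `geno_panel` carrying `tests`, `outcome` and
#'   `categories` attributes.
#' @export
#' @examples
#' df <- data.frame(A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 2, 2))
#' geno_panel(df, tests = c("A", "B", "C"))
geno_panel <- function(data, tests, outcome = NULL,
                       categories = c("Arg/Arg", "Arg/Pro", "Pro/Pro"),
                       id = NULL) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(tests, outcome, id), names(data))
  if (length(missing_cols)) {
    abort_input(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  if (length(tests) < 1L) abort_input("at least one test column is required")
  C <- length(categories)
  out <- tibble::as_tibble(data)
  for (tn in tests) {
    v <- out[[tn]]
    vi <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(vi) | vi != as.numeric(v) | vi < 1L | vi > C))
    if (length(bad)) {
      abort_input(sprintf(
        "column '%s', row %d: value '%s' is not a category in 1..%d or missing",
        tn, bad[1], as.character(v[bad[1]]), C))
    }
    out[[tn]] <- vi
  }
  if (!is.null(outcome)) {
    v <- suppressWarnings(as.integer(out[[outcome]]))
    bad <- which(!is.na(out[[outcome]]) & (is.na(v) | !(v %in% c(1L, 2L))))
    if (length(bad)) {
      abort_input(sprintf("outcome column '%s', row %d: values must be 1, 2 or missing",
                          outcome, bad[1]))
    }
    out[[outcome]] <- v
  }
  if (!is.null(id) && anyDuplicated(out[[id]])) {
    abort_input(sprintf("duplicate subject identifier in column '%s': %s",
                        id, out[[id]][anyDuplicated(out[[id]])]))
  }
  attr(out, "tests") <- tests
  attr(out, "outcome") <- outcome
  attr(out, "categories") <- categories
  class(out) <- c("geno_panel", class(out))
  out
}

#' @export
print.geno_panel <- function(x, ...) {
  tests <- panel_tests(x)
  cat(sprintf("# geno_panel: %d subjects, %d tests (%s), %d categories%s\n",
              nrow(x), length(tests), paste(tests, collapse = ", "),
              length(panel_categories(x)),
              if (is.null(panel_outcome(x))) "" else
                sprintf(", outcome '%s'", panel_outcome(x))))
  miss <- vapply(tests, function(tn) sum(is.na(x[[tn]])), integer(1))
  if (any(miss > 0)) {
    cat("# missing calls:",
        paste(sprintf("%s=%d", names(miss)[miss > 0], miss[miss > 0]), collapse = ", "),
        "\n")
  }
  NextMethod()
}

#' @rdname geno_panel
#' @export
panel_tests <- function(data) attr(data, "tests") %||% abort_input(
  "not a geno_panel: supply `tests` explicitly or use geno_panel()/read_panel()")

#' @rdname geno_panel
#' @export
panel_outcome <- function(data) attr(data, "outcome")

#' @rdname geno_panel
#' @export
panel_categories <- function(data) attr(data, "categories") %||%
  as.character(seq_len(max(unlist(data[panel_tests(data)]), na.rm = TRUE)))

#' Read a subject-level test panel from CSV
#'
#' Reads a wide CSV (one row per subject, one column per test) and validates
#' it into a [geno_panel]. Blank cells and `NA` are treated as missing calls.
#' A short per-test missingness summary is printed as a message.
#'
#' @inheritParams geno_panel
#' @param path Path to the CSV file.
#' @param quiet Suppress the missingness summary message.
#' @return A [geno_panel] tibble.
#' @export
read_panel <- function(path, tests, outcome = NULL,
                       categories = c("Arg/Arg", "Arg/Pro", "Pro/Pro"),
                       id = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  out <- geno_panel(raw, tests = tests, outcome = outcome,
                    categories = categories, id = id)
  if (!quiet) {
    miss <- vapply(tests, function(tn) sum(is.na(out[[tn]])), integer(1))
    message(sprintf("read %d subjects; missing calls per test: %s",
                    nrow(out),
                    paste(sprintf("%s=%d", tests, miss), collapse = ", ")))
  }
  out
}

#' Collapse genotype categories
#'
#' Re-groups the `C` categories of every test into a coarser coding, e.g.
#' Arg/Arg vs. all others (`scheme = c(1, 2, 2)`) or Pro/Pro vs. all others
#' (`scheme = c(2, 2, 1)`). Missing calls are preserved. The map must be
#' surjective onto `1..C'`.
#'
#' @param data A [geno_panel] (or data frame plus `tests`).
#' @param scheme Integer vector of length `C`; `scheme[k]` is the new code of
#'   old category `k`.
#' @param tests Test columns; defaults to the panel attribute.
#' @param labels Optional labels for the collapsed categories.
#' @return A [geno_panel] with remapped calls and updated category labels.
#' @export
collapse_categories <- function(data, scheme, tests = panel_tests(data),
                                labels = NULL) {
  C <- length(panel_categories(data))
  if (length(scheme) != C) abort_input(sprintf("scheme must have length %d", C))
  scheme <- as.integer(scheme)
  Cp <- max(scheme)
  if (!setequal(unique(scheme), seq_len(Cp)) || Cp >= C || Cp < 2L) {
    abort_input("scheme must map onto 1..C' with 2 <= C' < C and no gaps")
  }
  old_labels <- panel_categories(data)
  if (is.null(labels)) {
    labels <- vapply(seq_len(Cp), function(k)
      paste(old_labels[scheme == k], collapse = "+"), character(1))
  }
  out <- data
  for (tn in tests) out[[tn]] <- scheme[data[[tn]]]
  geno_panel(out, tests = tests, outcome = panel_outcome(data),
             categories = labels)
}

#' Cross-tabulate a pair of tests
#'
#' Builds the C-by-C table of joint calls for two tests, optionally split by
#' the binary outcome. Subjects with the first test observed but the second
#' missing are reported in a separate margin; subjects missing the first test
#' do not contribute.
#'
#' @param data A [geno_panel] (or data frame plus `tests`/`outcome`).
#' @param t1,t2 Names of the two test columns (`t1 != t2`).
#' @param stratify If `TRUE`, return one table per outcome level plus the
#'   pooled table; otherwise the pooled table only.
#' @param outcome Outcome column used for stratification.
#' @return A `pair_xtab` object, or a named list of them (`"1"`, `"2"`,
#'   `"pooled"`) when `stratify = TRUE`.
#' @export
crosstab_pair <- function(data, t1, t2, stratify = FALSE,
                          outcome = panel_outcome(data)) {
  tests <- panel_tests(data)
  if (!all(c(t1, t2) %in% tests)) {
    abort_input(sprintf("unknown test label: %s",
                        paste(setdiff(c(t1, t2), tests), collapse = ", ")))
  }
  if (identical(t1, t2)) abort_input("t1 and t2 must differ")
  cats <- panel_categories(data)
  one <- function(rows, stratum) {
    a <- data[[t1]][rows]
    b <- data[[t2]][rows]
    keep <- !is.na(a)
    a <- a[keep]; b <- b[keep]
    counts <- table(factor(a[!is.na(b)], levels = seq_along(cats)),
                    factor(b[!is.na(b)], levels = seq_along(cats)))
    counts <- matrix(as.integer(counts), length(cats), length(cats),
                     dimnames = list(cats, cats))
    miss <- tabulate(a[is.na(b)], nbins = length(cats))
    names(miss) <- cats
    structure(list(first_test = t1, second_test = t2, counts = counts,
                   missing_second = miss, stratum = stratum,
                   n = sum(counts) + sum(miss)),
              class = "pair_xtab")
  }
  if (!stratify) return(one(seq_len(nrow(data)), "pooled"))
  if (is.null(outcome)) abort_input("stratify = TRUE requires an outcome column")
  lev <- sort(unique(stats::na.omit(data[[outcome]])))
  out <- lapply(lev, function(l) one(which(data[[outcome]] == l), as.character(l)))
  names(out) <- as.character(lev)
  out$pooled <- one(seq_len(nrow(data)), "pooled")
  out
}

#' @export
print.pair_xtab <- function(x, ...) {
  cat(sprintf("# pair_xtab: %s x %s (%s stratum), n = %d\n",
              x$first_test, x$second_test, x$stratum, x$n))
  print(x$counts)
  if (any(x$missing_second > 0)) {
    cat("missing second test:\n"); print(x$missing_second)
  }
  invisible(x)
}

#' Tabulate observed response patterns
#'
#' Collapses a panel to the grouped representation used by the fitters: one
#' row per distinct pattern of calls (missing is a distinct symbol), with its
#' count. Fitting on this representation is exactly equivalent to fitting on
#' subject-level rows.
#'
#' @param data A [geno_panel] (or data frame plus `tests`).
#' @param tests Test columns to include.
#' @param outcome Optional outcome column to include as an extra variable.
#' @return A tibble with the selected columns plus `count`.
#' @export
pattern_table <- function(data, tests = panel_tests(data), outcome = NULL) {
  cols <- c(tests, outcome)
  df <- tibble::as_tibble(data[cols])
  out <- dplyr::count(df, dplyr::across(dplyr::all_of(cols)), name = "count")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(cols)))
}

#' Packaged pairwise-consistent genotyping panel
#'
#' Returns the packaged subject-level panel of p53 codon 72 calls by the four
#' main laboratory methods (DHPLC, DBH, RFLP-1, RFLP-2) with cytology status:
#' 911 women, 850 outcome-negative and 61 with any-grade SIL, one woman with
#' a missing RFLP-2 call.
#'
#' Only the six pairwise cross-tabulations of these tests, by cytology
#' stratum, are published; the full four-way joint table is not. The packaged
#' panel is therefore a synthetic reconstruction: one subject-level dataset,
#' found once by integer constraint satisfaction and frozen, whose six
#' pairwise stratified cross-tabs reproduce the published counts exactly.
#' All pairwise statistics (agreement, kappa, empirical prevalences and odds
#' ratios) computed from it match the published data; latent class model fits
#' depend on the unpublished higher-order cells and are *not* expected to
#' reproduce the published model estimates.
#'
#' @return A [geno_panel] with tests `DHPLC`, `DBH`, `RFLP1`, `RFLP2` and
#'   outcome column `cytology`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_patterns.csv", package = "genolcm",
                      mustWork = TRUE)
  pat <- utils::read.csv(path, na.strings = "NA")
  idx <- rep(seq_len(nrow(pat)), pat$count)
  df <- pat[idx, c("DHPLC", "DBH", "RFLP1", "RFLP2", "cytology")]
  df$subject_id <- sprintf("S%04d", seq_len(nrow(df)))
  rownames(df) <- NULL
  geno_panel(df, tests = c("DHPLC", "DBH", "RFLP1", "RFLP2"),
             outcome = "cytology", id = "subject_id")
}
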