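# shared helpers for the test suite

# fast control for simulation-heavy tests
quick_ctl <- function(n_restarts = 3L, se = FALSE, seed = 20130218L) {
  lcm_control(n_restarts = n_restarts, se = se, seed = seed)
}

# independent brute-force mixture likelihood: explicit loop over classes,
# no shared code with the package's vectorised engine
brute_subject_lik <- function(calls, pi, thetas) {
  total <- 0
  for (c in seq_along(pi)) {
    term <- pi[c]
    for (t in seq_along(calls)) {
      if (!is.na(calls[t])) term <- term * thetas[[t]][calls[t], c]
    }
    total <- total + term
  }
  total
}

# random simplex / column-stochastic matrices for property tests
rand_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}
rand_theta <- function(n_cat, C) {
  m <- matrix(stats::rexp(n_cat * C), n_cat, C)
  sweep(m, 2, colSums(m), "/")
}

# Table of published pairwise counts (negative-cytology and SIL strata) used
# for the fixture round-trip checks
published_pair_counts <- function() {
  list(
    `DHPLC:DBH` = list(
      neg = matrix(c(308, 9, 3, 5, 365, 4, 8, 9, 139), 3, 3),
      sil = matrix(c(31, 1, 0, 0, 21, 0, 1, 1, 6), 3, 3)),
    `DHPLC:RFLP1` = list(
      neg = matrix(c(299, 18, 5, 15, 360, 15, 7, 5, 126), 3, 3),
      sil = matrix(c(30, 1, 0, 1, 21, 1, 1, 1, 5), 3, 3)),
    `DHPLC:RFLP2` = list(
      neg = matrix(c(258, 9, 4, 49, 361, 2, 13, 13, 140), 3, 3),
      sil = matrix(c(29, 0, 0, 1, 22, 0, 2, 1, 6), 3, 3)),
    `DBH:RFLP1` = list(
      neg = matrix(c(302, 16, 4, 16, 355, 19, 2, 3, 133), 3, 3),
      sil = matrix(c(31, 0, 0, 1, 21, 1, 0, 0, 7), 3, 3)),
    `DBH:RFLP2` = list(
      neg = matrix(c(262, 7, 2, 50, 354, 8, 7, 13, 146), 3, 3),
      sil = matrix(c(29, 0, 0, 2, 21, 0, 1, 0, 8), 3, 3)),
    `RFLP1:RFLP2` = list(
      neg = matrix(c(266, 3, 2, 46, 365, 1, 9, 22, 135), 3, 3),
      sil = matrix(c(28, 1, 0, 2, 21, 0, 1, 1, 7), 3, 3)))
}
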