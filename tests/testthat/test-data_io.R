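test_that("read_panel parses calls, blanks and ids, and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,A,B,C,D",
               "s1,1,1,1,1",
               "s2,2,2,2,2",
               "s3,3,3,3,"), path)
  d <- read_panel(path, tests = c("A", "B", "C", "D"), id = "id", quiet = TRUE)
  expect_s3_class(d, "geno_panel")
  expect_equal(nrow(d), 3L)
  expect_equal(unlist(d[1, c("A", "B", "C", "D")], use.names = FALSE),
               rep(1L, 4))
  expect_true(is.na(d$D[3]))
  expect_equal(sum(is.na(d[c("A", "B", "C")])), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,A,B,C", "s1,1,1,1", "s2,5,1,1"), bad)
  expect_error(read_panel(bad, tests = c("A", "B", "C"), id = "id",
                          quiet = TRUE),
               "column 'A', row 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,A,B,C", "s1,1,1,1", "s1,2,2,2"), dup)
  expect_error(read_panel(dup, tests = c("A", "B", "C"), id = "id",
                          quiet = TRUE),
               "duplicate")
})

test_that("packaged panel reproduces every published pairwise table exactly", {
  d <- load_table1_fixture()
  expect_equal(nrow(d), 911L)
  expect_equal(sum(d$cytology == 2L), 61L)
  expect_equal(sum(!is.na(d$DHPLC)), 911L)
  expect_equal(sum(is.na(d$RFLP2)), 1L)

  pub <- published_pair_counts()
  for (nm in names(pub)) {
    pair <- strsplit(nm, ":")[[1]]
    xt <- crosstab_pair(d, pair[1], pair[2], stratify = TRUE)
    expect_equal(unname(xt[["1"]]$counts), pub[[nm]]$neg, info = nm)
    expect_equal(unname(xt[["2"]]$counts), pub[[nm]]$sil, info = nm)
  }
  # the missing margin: the one woman without RFLP-2 was Arg/Arg elsewhere
  xt <- crosstab_pair(d, "DHPLC", "RFLP2", stratify = TRUE)
  expect_equal(unname(xt[["1"]]$missing_second), c(1L, 0L, 0L))
  expect_equal(unname(xt[["2"]]$missing_second), c(0L, 0L, 0L))
})

test_that("crosstab_pair is symmetric under swap and strata sum to pooled", {
  d <- load_table1_fixture()
  ab <- crosstab_pair(d, "DBH", "RFLP1")
  ba <- crosstab_pair(d, "RFLP1", "DBH")
  expect_equal(ab$counts, t(ba$counts))
  xt <- crosstab_pair(d, "DHPLC", "DBH", stratify = TRUE)
  expect_equal(xt[["1"]]$counts + xt[["2"]]$counts, xt$pooled$counts)
  expect_error(crosstab_pair(d, "DHPLC", "nope"), "unknown test")
  expect_error(crosstab_pair(d, "DHPLC", "DHPLC"), "must differ")
  # empty input gives an all-zero table
  empty <- crosstab_pair(d[0, ], "DHPLC", "DBH")
  expect_true(all(empty$counts == 0L))
})

test_that("collapse_categories remaps calls, keeps missing, checks scheme", {
  d <- geno_panel(data.frame(A = c(1, 2, 3, NA), B = c(1, 2, 3, 1),
                             C = c(1, 1, 2, 3)),
                  tests = c("A", "B", "C"))
  arg_vs_rest <- collapse_categories(d, c(1, 2, 2))
  expect_equal(arg_vs_rest$A, c(1L, 2L, 2L, NA))
  expect_equal(length(panel_categories(arg_vs_rest)), 2L)
  pro_vs_rest <- collapse_categories(d, c(2, 2, 1))
  expect_equal(pro_vs_rest$A, c(2L, 2L, 1L, NA))
  expect_error(collapse_categories(d, c(1, 1, 1)), "scheme")  # all-in-one grouping
  expect_error(collapse_categories(d, c(1, 3, 1)), "scheme")

  # collapsing the packaged panel: pooled DHPLC x DBH cell (1,1) = 308 + 31
  fx <- collapse_categories(load_table1_fixture(), c(1, 2, 2))
  tab <- crosstab_pair(fx, "DHPLC", "DBH")
  expect_equal(unname(tab$counts[1, 1]), 339L)
})

test_that("pattern_table groups subjects without losing any", {
  d <- geno_panel(data.frame(A = c(2, 2, 2), B = c(1, 1, 1), C = c(3, 3, 3)),
                  tests = c("A", "B", "C"))
  pt <- pattern_table(d)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$count, 3L)

  fx <- load_table1_fixture()
  pt2 <- pattern_table(fx)
  expect_equal(sum(pt2$count), 911L)
  expect_lte(nrow(dplyr::filter(pt2, !is.na(RFLP2))), 81L)
})
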