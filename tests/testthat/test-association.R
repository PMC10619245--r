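test_that("contingency counts follow set arithmetic on the fixture", {
  idx <- toy_index()
  tab <- contingency(idx, "alpha", "beta")
  # alpha hits {1,2,3}, beta hits {3,4}, N = 6
  expect_identical(tab$n_both, 1L)
  expect_identical(tab$n_x_only, 2L)
  expect_identical(tab$n_y_only, 1L)
  expect_identical(tab$n_neither, 2L)
  expect_identical(tab$n_total, 6L)
  expect_identical(tab$evidence[[1]], 3L)

  # disjoint terms
  expect_identical(contingency(idx, "alpha", "noise")$n_both, 0L)
  # identity: x = y gives a = n_x, b = c = 0
  self <- contingency(idx, "alpha", "alpha")
  expect_identical(self$n_both, self$n_x)
  expect_identical(self$n_x_only, 0L)
  expect_identical(self$n_y_only, 0L)
})

test_that("exact test reproduces hand-enumerable values", {
  # N=4, margins 2/2: only a=1 (prob 4/6) and a=2 (prob 1/6) are possible
  expect_equal(fisher_one_sided(2, 0, 0, 2), 1 / 6, tolerance = 1e-14)
  # a = 0 is the whole support: p = 1 exactly
  expect_identical(fisher_one_sided(0, 10, 10, 80), 1)
  expect_identical(fisher_one_sided(0, 0, 0, 0), 1)
  # tail summation against independent dhyper oracle
  expect_equal(fisher_one_sided(5, 5, 5, 85), sum(dhyper(5:10, 10, 90, 10)),
               tolerance = 1e-14)
})

test_that("exact test agrees with fisher.test one-sided greater", {
  tables <- list(c(3, 7, 2, 8), c(10, 0, 0, 10), c(1, 1, 1, 1),
                 c(12, 5, 9, 44), c(0, 3, 5, 2), c(7, 19, 3, 71))
  for (tb in tables) {
    ours <- fisher_one_sided(tb[1], tb[2], tb[3], tb[4])
    ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE),
                              alternative = "greater")$p.value
    expect_equal(ours, ref, tolerance = 1e-12,
                 label = paste(tb, collapse = ","))
  }
})

test_that("exact test is monotone in n_both, symmetric, and bounded", {
  # fixed N = 100, n_x = 20, n_y = 30
  ps <- vapply(0:20, function(a) {
    fisher_one_sided(a, 20 - a, 30 - a, 50 + a)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
  expect_identical(ps[1], 1)

  # transposing the table (swapping the terms) leaves p unchanged
  set.seed(42)
  for (i in 1:25) {
    tb <- as.vector(stats::rmultinom(1, size = sample(10:200, 1),
                                     prob = c(.1, .3, .2, .4)))
    expect_equal(fisher_one_sided(tb[1], tb[2], tb[3], tb[4]),
                 fisher_one_sided(tb[1], tb[3], tb[2], tb[4]),
                 tolerance = 1e-13)
  }
})

test_that("log-space tail stays accurate far below double underflow", {
  lp <- fisher_one_sided(500, 0, 0, 500, log = TRUE)
  # P = 1/choose(1000,500): |log p| ~ 690, representable only in log space
  expect_equal(lp, -lchoose(1000, 500), tolerance = 1e-9)
  deep <- fisher_one_sided(900, 0, 0, 900, log = TRUE)
  expect_lt(deep, -1100)               # p far below 2.2e-308
  expect_identical(fisher_one_sided(900, 0, 0, 900), 0)  # underflows to 0
  expect_identical(format_p(fisher_one_sided(900, 0, 0, 900)), "0")
})

test_that("invalid tables are rejected", {
  expect_error(fisher_one_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_one_sided(5, 2, 3, NA), "non-negative")
  expect_error(chi_square(-1, 2, 3, 4), "non-negative")
})

test_that("chi-square matches the hand-computed statistic and flags degenerate margins", {
  # perfect independence: statistic 0, p = 1
  expect_identical(as.numeric(chi_square(25, 25, 25, 25)), 1)

  p <- chi_square(20, 5, 5, 70)
  ref <- stats::chisq.test(matrix(c(20, 5, 5, 70), 2), correct = FALSE)$p.value
  expect_equal(as.numeric(p), ref, tolerance = 1e-12)
  expect_false(attr(p, "degenerate"))

  degen <- chi_square(0, 0, 5, 5)      # zero x margin
  expect_identical(as.numeric(degen), 1)
  expect_true(attr(degen, "degenerate"))
})

test_that("p-value display applies the 2.2e-308 floor and one significant figure", {
  expect_identical(format_p(1e-310), "0")
  expect_identical(format_p(2.3e-33), "2e-33")
  expect_identical(format_p(1), "1")
  expect_identical(format_p(0.17), "0.2")
  expect_identical(format_p(5.4e-6), "5e-6")
  expect_identical(format_p(c(0, 6.2e-24)), c("0", "6e-24"))
})

test_that("pair search crosses lists, sorts deterministically, and flags absent terms", {
  idx <- toy_index()
  res <- pair_search(idx, term_list("alpha"),
                     term_list("beta", "noise", "notpresent"))
  expect_identical(nrow(res), 3L)
  expect_true(!is.unsorted(res$p_value))
  absent <- res[res$y_label == "notpresent", ]
  expect_identical(absent$p_value, 1)
  expect_true(absent$term_absent)
  expect_identical(res$evidence[[match("beta", res$y_label)]], 3L)
  # ratio = n_both / n_y
  expect_equal(res$ratio, res$n_both / pmax(res$n_y, 1))

  # cutoff excluding every document: all tables empty, all p = 1
  res0 <- pair_search(idx, term_list("alpha"), term_list("beta"),
                      cutoff_year = 1700)
  expect_identical(res0$p_value, 1)
  expect_identical(res0$n_total, 0L)

  expect_error(pair_search(idx, term_list(), term_list("beta")), "non-empty")
})

test_that("pair results TSV round-trips the schema", {
  idx <- toy_index()
  res <- pair_search(idx, term_list("alpha"), term_list("beta", "noise"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_results(res, path)
  expect_identical(readLines(path)[1], "# litlinkr pair results v1")
  back <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(p_display = "c"))
  expect_identical(nrow(back), 2L)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-15)
  expect_identical(back$p_display, format_p(res$p_value))
})
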