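test_that("prediction score is the significance-gated B-C ratio", {
  expect_identical(prediction_score(1e-20, 1.0), 1.0)
  expect_identical(prediction_score(0.5, 0.9), 0)
  expect_equal(prediction_score(1e-12, 8 / 100), 0.08)
  # gate is strict at the threshold
  expect_identical(prediction_score(1e-5, 0.5, significance_threshold = 1e-5),
                   0)
  expect_identical(prediction_score(c(1e-8, 0.2), c(0.4, 0.4)), c(0.4, 0))
})

test_that("open discovery recovers a planted chain at rank 1", {
  fix <- chain_fixture(seed = 5L)
  tl <- chain_term_lists(fix$chain)
  hits <- open_discovery(fix$index, tl$a, tl$b, tl$c)
  expect_gt(nrow(hits), 0L)
  top <- hits[hits$rank == 1L, ]
  expect_identical(top$b_label, fix$chain$b)
  expect_identical(top$c_label, fix$chain$c)
  expect_lt(top$ab_p_value, 1e-5)
  expect_gt(top$prediction_score, 0.3)
  # ranks are 1-based, gapless, consistent with the score ordering
  expect_identical(hits$rank, seq_len(nrow(hits)))
  expect_true(!is.unsorted(-hits$prediction_score))
})

test_that("no hit is reported at or above the stage-1 threshold", {
  fix <- chain_fixture(seed = 13L)
  tl <- chain_term_lists(fix$chain)
  hits <- open_discovery(fix$index, tl$a, tl$b, tl$c)
  expect_true(all(hits$ab_p_value < 1e-5))

  # an unreachable threshold yields an empty (logged) result, not an error
  expect_message(
    none <- open_discovery(fix$index, tl$a, tl$b, tl$c,
                           ab_p_threshold = 1e-300),
    "no A-B pair"
  )
  expect_identical(nrow(none), 0L)

  expect_error(open_discovery(fix$index, tl$a, tl$b[0, ], tl$c), "non-empty")
})

test_that("the stage-1 cap keeps exactly the smallest p-values", {
  fix <- cap_corpus()
  idx <- build_corpus_index(fix$docs)
  ab <- pair_search(idx, fix$a, fix$b)
  sig <- ab[ab$p_value < 1e-5, ]
  expect_identical(nrow(sig), 400L)          # all pairs significant
  expected_b <- utils::head(sig$y_label, 300L)

  hits <- open_discovery(idx, fix$a, fix$b, fix$c)
  surviving_b <- unique(hits$b_label)
  expect_identical(length(surviving_b), 300L)
  expect_setequal(surviving_b, expected_b)
  # every surviving pair has p <= every dropped pair (with tie-break)
  dropped <- sig$p_value[301:400]
  expect_true(max(sig$p_value[1:300]) <= min(dropped))
})

test_that("closed discovery reports intermediates significant on both sides", {
  # B1 links A and C; B2 co-occurs only with A; B3 with neither
  n <- 120L
  mk <- function(i) {
    terms <- character(0)
    if (i <= 30L) terms <- c("aterm", "bone", "cterm")
    if (i > 30L && i <= 60L) terms <- c("aterm", "btwo")
    paste(c("filler", terms, "pad"), collapse = " ")
  }
  docs <- corpus_tibble(pmid = seq_len(n), title = "t",
                        abstract = vapply(seq_len(n), mk, character(1)),
                        year = 2000L)
  idx <- build_corpus_index(docs)
  b_terms <- term_list("bone", "btwo", "bthree")
  res <- closed_discovery(idx, term_list("aterm"), term_list("cterm"), b_terms)
  expect_identical(res$b_label, "bone")
  expect_lt(res$ab_p_value, 1e-5)
  expect_lt(res$bc_p_value, 1e-5)

  # A and C identical: every significant A-B pair reports bc == ab
  same <- closed_discovery(idx, term_list("aterm"), term_list("aterm"),
                           b_terms)
  expect_identical(same$ab_p_value, same$bc_p_value)

  # no B on both sides
  none <- closed_discovery(idx, term_list("btwo"), term_list("cterm"),
                           term_list("bthree"))
  expect_identical(nrow(none), 0L)
})

test_that("open and closed modes agree bit-exactly on shared pairs", {
  fix <- chain_fixture(seed = 21L)
  tl <- chain_term_lists(fix$chain)
  open <- open_discovery(fix$index, tl$a, tl$b, tl$c)
  closed <- closed_discovery(fix$index, tl$a,
                             term_list(fix$chain$c), tl$b)
  shared <- dplyr::inner_join(
    tibble::as_tibble(open)[, c("b_label", "c_label", "ab_p_value",
                                "bc_p_value")],
    tibble::as_tibble(closed)[, c("b_label", "c_label", "ab_p_value",
                                  "bc_p_value")],
    by = c("b_label", "c_label")
  )
  expect_gt(nrow(shared), 0L)
  expect_identical(shared$ab_p_value.x, shared$ab_p_value.y)
  expect_identical(shared$bc_p_value.x, shared$bc_p_value.y)
})

test_that("cutoff years restrict counting monotonically", {
  fix <- chain_fixture(seed = 9L, n_docs = 400L)
  n_both_at <- function(y) {
    contingency(fix$index, fix$chain$b, fix$chain$c, cutoff_year = y)$n_both
  }
  counts <- vapply(c(1985, 1995, 2005, 2020), n_both_at, integer(1))
  expect_true(!is.unsorted(counts))
  expect_identical(counts[4],
                   contingency(fix$index, fix$chain$b, fix$chain$c)$n_both)
})

test_that("multiple A terms run independently with per-A ranks, and self-links are suppressed", {
  fix <- chain_fixture(seed = 17L)
  ch <- fix$chain
  a2 <- term_list(ch$a, ch$decoys[1])
  tl <- chain_term_lists(ch)
  hits <- open_discovery(fix$index, a2, tl$b, tl$c)
  for (a in unique(hits$a_label)) {
    sub <- hits[hits$a_label == a, ]
    expect_identical(sub$rank, seq_len(nrow(sub)))
  }
  # decoys appear in both the B and C lists; b == c chains must be absent
  expect_false(any(hits$b_label == hits$c_label))

  # rerunning the identical query is deterministic
  hits2 <- open_discovery(fix$index, a2, tl$b, tl$c)
  expect_identical(tibble::as_tibble(hits)[names(hits) != "ab_evidence"],
                   tibble::as_tibble(hits2)[names(hits2) != "ab_evidence"])
  expect_identical(hits$ab_evidence, hits2$ab_evidence)
})

test_that("hits TSV writer round-trips through read_hits_tsv", {
  fix <- chain_fixture(seed = 5L, n_docs = 400L)
  tl <- chain_term_lists(fix$chain)
  hits <- open_discovery(fix$index, tl$a, tl$b, tl$c)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, path)
  back <- read_hits_tsv(path)
  expect_identical(back$a_label, hits$a_label)
  expect_identical(back$rank, hits$rank)
  expect_equal(back$ab_p_value, hits$ab_p_value, tolerance = 1e-15)
  expect_equal(back$prediction_score, hits$prediction_score,
               tolerance = 1e-15)
})
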