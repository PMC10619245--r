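test_that("index records positions in title-then-abstract order with a gap", {
  idx <- build_corpus_index(corpus_tibble(
    pmid = 9L, title = "fish oil", abstract = "", year = 1984L
  ))
  expect_identical(get("fish", envir = idx$postings), list(`9` = 0L))
  expect_identical(get("oil", envir = idx$postings), list(`9` = 1L))
  expect_identical(idx$n_docs, 1L)

  # abstract tokens start one past the title block: no phrase spans it
  idx2 <- build_corpus_index(corpus_tibble(
    pmid = 1L, title = "fish oil", abstract = "dietary fish oil", year = 1984L
  ))
  expect_identical(match_phrase(idx2, "oil dietary"), integer(0))
  expect_identical(match_phrase(idx2, "dietary fish oil"), 1L)
  expect_identical(get("fish", envir = idx2$postings)[["1"]], c(0L, 4L))
})

test_that("empty corpora and repeated tokens index correctly", {
  empty <- build_corpus_index(corpus_tibble())
  expect_identical(empty$n_docs, 0L)
  expect_identical(length(ls(empty$postings)), 0L)
  expect_identical(glance(empty)$n_postings, 0L)

  rep_idx <- build_corpus_index(corpus_tibble(
    pmid = 1L, title = "", abstract = "echo something echo", year = 2000L
  ))
  expect_identical(get("echo", envir = rep_idx$postings)[["1"]], c(1L, 3L))
})

test_that("phrase matching requires consecutive tokens in order", {
  idx <- build_corpus_index(corpus_tibble(
    pmid = 5L, title = "study",
    abstract = "dietary fish oil reduces blood viscosity", year = 1984L
  ))
  expect_identical(match_phrase(idx, "fish oil"), 5L)
  expect_identical(match_phrase(idx, "Fish-Oil!"), 5L)  # normalizer applies
  expect_identical(match_phrase(idx, "oil fish"), integer(0))
  expect_identical(match_phrase(idx, "fish viscosity"), integer(0))
  expect_identical(match_phrase(idx, "no such token"), integer(0))
  expect_error(match_phrase(idx, "!!!"), "zero tokens")
})

test_that("single-token containment: a phrase match implies its tokens match", {
  idx <- toy_index()
  phrases <- c("alpha study", "alpha meets beta", "background one")
  for (ph in phrases) {
    full <- match_phrase(idx, ph)
    for (tok in tokenize1(ph)) {
      expect_true(all(full %in% match_phrase(idx, tok)), label = paste(ph, tok))
    }
  }
})

test_that("term matching is a document-level union over synonyms", {
  idx <- toy_index()
  expect_identical(match_term(idx, c("alpha", "beta")), c(1L, 2L, 3L, 4L))
  # doc 3 contains both synonyms but is counted once
  expect_identical(sum(match_term(idx, c("alpha", "beta")) == 3L), 1L)
  expect_identical(match_term(idx, term_list(gone = c("absent", "missing"))),
                   integer(0))
  # synonym hit on one synonym only
  expect_identical(match_term(idx, c("unseen", "beta")), c(3L, 4L))
})

test_that("cutoff year is inclusive and excludes unknown-year documents", {
  idx <- toy_index()
  expect_identical(match_term(idx, "alpha", cutoff_year = 1985), c(1L, 2L))
  expect_identical(match_term(idx, "alpha", cutoff_year = 1979), integer(0))
  # pmid 6 has unknown year: returned without a cutoff, never with one
  expect_true(6L %in% match_phrase(idx, "noise"))
  expect_false(6L %in% match_phrase(idx, "noise", cutoff_year = 2100))
  expect_identical(n_docs_eligible(idx), 6L)
  expect_identical(n_docs_eligible(idx, 1990), 3L)
})

test_that("querying with a cutoff equals querying an index of the restricted corpus", {
  fix <- chain_fixture(seed = 11L, n_docs = 300L)
  docs <- fix$corpus$docs
  probes <- c(fix$chain$a, fix$chain$b, fix$chain$c, "bg0001", "bg0002")
  for (cutoff in c(1990, 2005)) {
    restricted <- build_corpus_index(docs[!is.na(docs$year) &
                                            docs$year <= cutoff, ])
    for (probe in probes) {
      expect_identical(match_term(fix$index, probe, cutoff_year = cutoff),
                       match_term(restricted, probe),
                       label = paste(probe, cutoff))
    }
    expect_identical(n_docs_eligible(fix$index, cutoff), restricted$n_docs)
  }
})

test_that("save/load round trip answers every probe identically", {
  fix <- chain_fixture(seed = 3L, n_docs = 60L)
  path <- withr::local_tempfile(fileext = ".json")
  save_corpus_index(fix$index, path)
  reloaded <- load_corpus_index(path)
  probes <- c(fix$chain$a, fix$chain$b, fix$chain$c, fix$chain$decoys,
              sprintf("bg%04d", 1:5), "synthetic record")
  for (probe in probes) {
    expect_identical(match_term(reloaded, probe), match_term(fix$index, probe),
                     label = probe)
    expect_identical(match_term(reloaded, probe, cutoff_year = 2000),
                     match_term(fix$index, probe, cutoff_year = 2000),
                     label = probe)
  }
  expect_identical(reloaded$n_docs, fix$index$n_docs)
})

test_that("loading rejects wrong or corrupted index files", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "something-else", "version": 1}', bad)
  expect_error(load_corpus_index(bad), "not a version")

  corrupt <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "litlinkr-ind', corrupt)
  expect_error(load_corpus_index(corrupt))
})
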