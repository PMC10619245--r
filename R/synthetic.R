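# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Specify a synthetic corpus
#'
#' Describes a corpus of pseudo-abstracts with a Zipf-distributed
#' background vocabulary, uniform publication years, and planted term
#' structure: pairwise co-occurrence patterns (`planted_pairs`) and/or a
#' three-term A-B-C chain (`planted_chain`). Generation is a pure function
#' of the spec, including its seed.
#'
#' Planted terms may be single tokens or multi-token phrases (spaces in
#' the term string); phrases are inserted as consecutive tokens, which
#' exercises positional phrase matching.
#'
#' @param n_docs Number of documents.
#' @param vocab_size Background vocabulary size; background tokens are
#'   drawn i.i.d. with Zipf weights `1/k^1.1`.
#' @param tokens_per_doc Length-2 integer range of background tokens per
#'   document (uniform).
#' @param year_range Length-2 integer range of publication years
#'   (uniform).
#' @param planted_pairs Optional tibble with columns `term_x`, `term_y`,
#'   `p_joint`, `p_x_only`, `p_y_only`: per document, the pair lands in
#'   the both/x-only/y-only/neither category with those probabilities.
#' @param planted_chain Optional chain description from [planted_chain()].
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_docs = 1000L, vocab_size = 500L,
                        tokens_per_doc = c(40L, 80L),
                        year_range = c(1975L, 2020L),
                        planted_pairs = NULL, planted_chain = NULL,
                        seed = 1L) {
  stopifnot(n_docs >= 0, vocab_size >= 1, length(tokens_per_doc) == 2L,
            tokens_per_doc[1] >= 1, tokens_per_doc[2] >= tokens_per_doc[1],
            length(year_range) == 2L, year_range[1] <= year_range[2])
  if (!is.null(planted_pairs)) {
    p <- planted_pairs
    stopifnot(all(c("term_x", "term_y", "p_joint", "p_x_only", "p_y_only")
                  %in% names(p)))
    probs <- cbind(p$p_joint, p$p_x_only, p$p_y_only)
    if (any(probs < 0) || any(probs > 1) || any(rowSums(probs) > 1)) {
      stop("planted pair probabilities must be in [0,1] with ",
           "p_joint + p_x_only + p_y_only <= 1", call. = FALSE)
    }
  }
  structure(
    list(n_docs = as.integer(n_docs), vocab_size = as.integer(vocab_size),
         tokens_per_doc = as.integer(tokens_per_doc),
         year_range = as.integer(year_range),
         planted_pairs = planted_pairs, planted_chain = planted_chain,
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Describe a planted A-B-C chain
#'
#' Per document, the (A, B) pair co-occurs with probability `p_ab_joint`
#' (A alone with `p_a_only`, B alone with `p_b_only`), and independently
#' the (B, C) pair co-occurs with probability `p_bc_joint` (C alone with
#' `p_c_only`). `n_decoys` decoy terms each occur independently with
#' probability `p_decoy`, so they carry no real association with B; they
#' populate the candidate B and C lists as negatives. The defaults give a
#' strongly linked chain in a 1000-document corpus: about 50 A-B and 50
#' B-C co-occurrences against single-digit expectations under
#' independence, and a B-C ratio near 0.7 versus about 0.1 for decoys.
#'
#' @param a,b,c Term strings (single tokens or phrases).
#' @param p_ab_joint,p_a_only,p_b_only Stage-1 occurrence probabilities.
#' @param p_bc_joint,p_c_only Stage-2 occurrence probabilities.
#' @param n_decoys Number of decoy terms.
#' @param p_decoy Per-document occurrence probability of each decoy.
#' @return A `planted_chain` list.
#' @export
planted_chain <- function(a = "condalpha", b = "phenobeta", c = "druggamma",
                          p_ab_joint = 0.05, p_a_only = 0.02,
                          p_b_only = 0.02, p_bc_joint = 0.05,
                          p_c_only = 0.02, n_decoys = 10L, p_decoy = 0.05) {
  probs <- c(p_ab_joint, p_a_only, p_b_only, p_bc_joint, p_c_only, p_decoy)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p_ab_joint + p_a_only + p_b_only <= 1,
            p_bc_joint + p_c_only <= 1, n_decoys >= 0)
  structure(
    list(a = a, b = b, c = c, p_ab_joint = p_ab_joint, p_a_only = p_a_only,
         p_b_only = p_b_only, p_bc_joint = p_bc_joint, p_c_only = p_c_only,
         n_decoys = as.integer(n_decoys), p_decoy = p_decoy,
         decoys = sprintf("decoyterm%02d", seq_len(n_decoys))),
    class = "planted_chain"
  )
}

#' Generate a synthetic corpus with ground truth
#'
#' Draws the corpus described by a [corpus_spec()]: per document, a
#' uniform publication year, i.i.d. Zipf background tokens from a
#' vocabulary disjoint from all planted terms, and planted terms inserted
#' at random non-adjacent gaps of the background sequence. The manifest
#' records the exact per-document placements, so contingency tables
#' computed from the index can be checked against ground truth exactly.
#'
#' @param spec A `corpus_spec`.
#' @return A list with `docs` (corpus tibble), `manifest` (tibble of
#'   `pmid`, `term` rows, one per planted placement), and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_docs
  if (n == 0L) {
    return(list(docs = corpus_tibble(),
                manifest = tibble::tibble(pmid = integer(), term = character()),
                spec = spec))
  }
  with_local_seed(spec$seed, {
    vocab <- sprintf("bg%04d", seq_len(spec$vocab_size))
    zipf <- 1 / seq_len(spec$vocab_size)^1.1
    years <- sample(seq(spec$year_range[1], spec$year_range[2]), n,
                    replace = TRUE)
    lens <- sample(seq(spec$tokens_per_doc[1], spec$tokens_per_doc[2]), n,
                   replace = TRUE)

    # per-document planted term sets
    planted <- replicate(n, character(0), simplify = FALSE)
    add_term <- function(docs_idx, term) {
      for (i in docs_idx) planted[[i]] <<- c(planted[[i]], term)
    }
    if (!is.null(spec$planted_pairs)) {
      pp <- spec$planted_pairs
      for (j in seq_len(nrow(pp))) {
        cat_draw <- sample.int(4L, n, replace = TRUE,
                               prob = c(pp$p_joint[j], pp$p_x_only[j],
                                        pp$p_y_only[j],
                                        1 - pp$p_joint[j] - pp$p_x_only[j] -
                                          pp$p_y_only[j]))
        add_term(which(cat_draw %in% c(1L, 2L)), pp$term_x[j])
        add_term(which(cat_draw %in% c(1L, 3L)), pp$term_y[j])
      }
    }
    if (!is.null(spec$planted_chain)) {
      ch <- spec$planted_chain
      ab <- sample.int(4L, n, replace = TRUE,
                       prob = c(ch$p_ab_joint, ch$p_a_only, ch$p_b_only,
                                1 - ch$p_ab_joint - ch$p_a_only - ch$p_b_only))
      bc <- sample.int(3L, n, replace = TRUE,
                       prob = c(ch$p_bc_joint, ch$p_c_only,
                                1 - ch$p_bc_joint - ch$p_c_only))
      add_term(which(ab %in% c(1L, 2L)), ch$a)
      add_term(unique(c(which(ab %in% c(1L, 3L)), which(bc == 1L))), ch$b)
      add_term(which(bc %in% c(1L, 2L)), ch$c)
      for (d in ch$decoys) {
        add_term(which(stats::runif(n) < ch$p_decoy), d)
      }
    }

    abstracts <- character(n)
    for (i in seq_len(n)) {
      bg <- sample(vocab, lens[i], replace = TRUE, prob = zipf)
      terms_i <- planted[[i]]
      if (length(terms_i) > 0L) {
        # one distinct gap (0..len) per planted term keeps them non-adjacent;
        # if planted terms outnumber gaps, gaps are reused (adjacency allowed)
        gaps <- sort(sample.int(lens[i] + 1L, length(terms_i),
                                replace = length(terms_i) > lens[i] + 1L) - 1L)
        out <- character(0)
        prev <- 0L
        for (k in seq_along(gaps)) {
          out <- c(out, bg[seq_len(gaps[k] - prev) + prev], terms_i[k])
          prev <- gaps[k]
        }
        bg <- c(out, bg[seq_len(lens[i] - prev) + prev])
      }
      abstracts[i] <- paste(bg, collapse = " ")
    }

    docs <- corpus_tibble(
      pmid = seq_len(n),
      title = sprintf("synthetic record %d", seq_len(n)),
      abstract = abstracts,
      year = years
    )
    manifest <- tibble::tibble(
      pmid = rep(seq_len(n), lengths(planted)),
      term = unlist(planted, use.names = FALSE)
    )
    list(docs = docs, manifest = manifest, spec = spec)
  })
}

#' Write the full fixture set for a generated corpus
#'
#' Emits the corpus in both supported dialects (MEDLINE-style XML and
#' JSONL), term-list TSVs for the planted chain terms plus decoys (both
#' present decoys and one never-planted absent decoy per list), and a
#' relation-triples TSV linking the chain terms (A POS_ASSOCIATION B;
#' C TREATS B) with the co-occurrence pmids from the manifest as
#' evidence.
#'
#' @param corpus The list returned by [generate_corpus()]; its spec must
#'   carry a planted chain for the term-list and relations fixtures.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
emit_fixtures <- function(corpus, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    corpus_xml = file.path(out_dir, "corpus.xml"),
    corpus_jsonl = file.path(out_dir, "corpus.jsonl")
  )
  write_pubmed_xml(corpus$docs, files[["corpus_xml"]])
  write_corpus_jsonl(corpus$docs, files[["corpus_jsonl"]])

  ch <- corpus$spec$planted_chain
  if (!is.null(ch)) {
    a_tl <- term_list(ch$a)
    b_tl <- do.call(term_list, as.list(c(ch$b, ch$decoys, "absentdecoyb")))
    c_tl <- do.call(term_list, as.list(c(ch$c, ch$decoys, "absentdecoyc")))
    files[["terms_a"]] <- file.path(out_dir, "terms_a.tsv")
    files[["terms_b"]] <- file.path(out_dir, "terms_b.tsv")
    files[["terms_c"]] <- file.path(out_dir, "terms_c.tsv")
    write_term_list(a_tl, files[["terms_a"]])
    write_term_list(b_tl, files[["terms_b"]])
    write_term_list(c_tl, files[["terms_c"]])

    man <- corpus$manifest
    docs_with <- function(term) sort(unique(man$pmid[man$term == term]))
    ab_ev <- intersect(docs_with(ch$a), docs_with(ch$b))
    bc_ev <- intersect(docs_with(ch$b), docs_with(ch$c))
    rel <- tibble::tibble(
      subject = c(ch$a, ch$c),
      subject_type = c("CONDITION", "DRUG"),
      relation = c("POS_ASSOCIATION", "TREATS"),
      object = c(ch$b, ch$b),
      object_type = c("CONDITION", "CONDITION"),
      pmids = c(paste(ab_ev, collapse = ","), paste(bc_ev, collapse = ","))
    )
    rel <- rel[nzchar(rel$pmids), , drop = FALSE]
    files[["relations"]] <- file.path(out_dir, "relations.tsv")
    write_tsv_versioned(rel, files[["relations"]],
                        "# litlinkr relations v1")
  }
  invisible(files)
}

#' Null-calibration battery for the exact test
#'
#' Plants `n_pairs` term pairs whose occurrences are independent by
#' construction (the joint probability factorizes as `p_x * p_y`) in one
#' synthetic corpus, then computes the one-sided Fisher's exact test
#' p-value for every pair against the built index. Under this null the
#' p-values should stochastically dominate Uniform(0,1) — the exact test
#' is conservative — so the fraction below 0.05 stays near or below 0.05.
#'
#' @param n_pairs Number of independent pairs.
#' @param n_docs Corpus size.
#' @param p_x,p_y Marginal per-document occurrence probabilities.
#' @param seed Integer seed.
#' @return A tibble with one row per pair: `term_x`, `term_y`, the 2x2
#'   counts, and `p_value`.
#' @export
null_pair_battery <- function(n_pairs = 200L, n_docs = 2000L,
                              p_x = 0.05, p_y = 0.05, seed = 1L) {
  pairs <- tibble::tibble(
    term_x = sprintf("nullx%03d", seq_len(n_pairs)),
    term_y = sprintf("nully%03d", seq_len(n_pairs)),
    p_joint = p_x * p_y,
    p_x_only = p_x * (1 - p_y),
    p_y_only = (1 - p_x) * p_y
  )
  spec <- corpus_spec(n_docs = n_docs, vocab_size = 200L,
                      tokens_per_doc = c(60L, 100L),
                      planted_pairs = pairs, seed = seed)
  corpus <- generate_corpus(spec)
  index <- build_corpus_index(corpus$docs)
  tabs <- dplyr::bind_rows(lapply(seq_len(n_pairs), function(j) {
    contingency(index, pairs$term_x[j], pairs$term_y[j])[, 1:7]
  }))
  out <- dplyr::bind_cols(pairs[, c("term_x", "term_y")], tabs)
  out$p_value <- fisher_one_sided(out)
  out
}
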