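# Shared in-code fixtures. Everything is built programmatically so tests
# run without any external data.

# Six documents with controlled term occurrences:
# "alpha" hits pmids 1,2,3; "beta" hits pmids 3,4; 5 and 6 are background.
toy_docs <- function() {
  corpus_tibble(
    pmid = 1:6,
    title = c("alpha study", "alpha report", "alpha meets beta",
              "beta only", "background one", "background two"),
    abstract = c("some filler text", "more filler", "joint mention here",
                 "another filler", "noise tokens", "yet more noise"),
    year = c(1980L, 1985L, 1990L, 1995L, 2000L, NA)
  )
}

toy_index <- function() build_corpus_index(toy_docs())

# A corpus engineered so that exactly `n_b` A-B pairs are significant at
# 1e-5, with graded p-values: B term i occurs in k_i = 20 + (i mod 6)
# documents, all inside the 250-document A set, out of 500 total.
# P(X >= k) = choose(250, k) / choose(500, k) < 1e-5 for every k >= 20.
cap_corpus <- function(n_b = 400L, n_docs = 500L, n_a = 250L) {
  b_labels <- sprintf("bt%03d", seq_len(n_b))
  doc_terms <- replicate(n_docs, character(0), simplify = FALSE)
  for (d in seq_len(n_a)) doc_terms[[d]] <- "aterm"
  for (i in seq_len(n_b)) {
    k <- 20L + (i %% 6L)
    in_docs <- ((i * 7L + seq_len(k) - 1L) %% n_a) + 1L
    for (d in unique(in_docs)) {
      doc_terms[[d]] <- c(doc_terms[[d]], b_labels[i])
    }
  }
  # one C term co-occurring with everything a little
  for (d in seq(1L, n_docs, by = 5L)) {
    doc_terms[[d]] <- c(doc_terms[[d]], "cterm")
  }
  docs <- corpus_tibble(
    pmid = seq_len(n_docs),
    title = sprintf("cap doc %d", seq_len(n_docs)),
    abstract = vapply(doc_terms, function(t) {
      paste(c("filler", t, "filler"), collapse = " ")
    }, character(1)),
    year = 2000L
  )
  list(docs = docs, a = term_list("aterm"),
       b = do.call(term_list, as.list(b_labels)), c = term_list("cterm"))
}

# Small planted-chain corpus + index for engine tests.
chain_fixture <- function(seed = 7L, n_docs = 800L) {
  spec <- corpus_spec(n_docs = n_docs, vocab_size = 300L,
                      tokens_per_doc = c(30L, 60L),
                      planted_chain = planted_chain(), seed = seed)
  corpus <- generate_corpus(spec)
  list(corpus = corpus, index = build_corpus_index(corpus$docs),
       chain = spec$planted_chain)
}

chain_term_lists <- function(chain) {
  list(
    a = term_list(chain$a),
    b = do.call(term_list, as.list(c(chain$b, chain$decoys))),
    c = do.call(term_list, as.list(c(chain$c, chain$decoys)))
  )
}

# Worked-example corpus: migraine/epilepsy and epilepsy/sodium-valproate
# strongly co-occur; plus unrelated background documents.
migraine_docs <- function() {
  n_ab <- 15L; n_bc <- 15L; n_bg <- 30L
  corpus_tibble(
    pmid = seq_len(n_ab + n_bc + n_bg),
    title = c(rep("migraine and epilepsy comorbidity", n_ab),
              rep("sodium valproate therapy in epilepsy", n_bc),
              rep("unrelated background article", n_bg)),
    abstract = c(rep("patients with migraine and epilepsy were studied", n_ab),
                 rep("sodium valproate controls epileptic seizures", n_bc),
                 rep("this text mentions neither condition nor drug", n_bg)),
    year = 1975L
  )
}

migraine_graph <- function() {
  kg_from_tibble(tibble::tibble(
    subject = c("Migraine", "Sodium Valproate"),
    subject_type = c("CONDITION", "DRUG"),
    relation = c("POS_ASSOCIATION", "TREATS"),
    object = c("Epilepsy", "Epilepsy"),
    object_type = c("CONDITION", "CONDITION"),
    pmids = c("101,102", "201")
  ))
}
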