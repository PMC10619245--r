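#' Build a positional inverted index over a corpus
#'
#' Every token occurrence in each document (title first, then abstract) is
#' recorded as (pmid, position). Title and abstract are separated by a gap
#' of one unused position so a phrase can never match across the boundary.
#' The index also stores each document's publication year and the total
#' document count, which is the `N` of every contingency table built from
#' the index.
#'
#' @param docs A corpus tibble (see [corpus_tibble()]). Duplicate pmids are
#'   resolved last-record-wins with a warning before indexing.
#' @return A `corpus_index` object.
#' @examples
#' idx <- build_corpus_index(corpus_tibble(
#'   pmid = 1L, title = "Fish oil", abstract = "Reduces blood viscosity."
#' ))
#' match_phrase(idx, "blood viscosity")
#' @export
build_corpus_index <- function(docs) {
  docs <- validate_corpus(docs)
  tt <- tokenize_text(docs$title)
  ta <- tokenize_text(docs$abstract)
  nt <- lengths(tt)
  na <- lengths(ta)

  token <- c(unlist(tt, use.names = FALSE), unlist(ta, use.names = FALSE))
  pmid <- c(rep(docs$pmid, nt), rep(docs$pmid, na))
  # abstract positions start one past the end of the title block
  pos <- c(sequence(nt) - 1L, sequence(na) - 1L + rep(nt + 1L, na))

  postings <- new.env(parent = emptyenv(), hash = TRUE,
                      size = max(16L, length(unique(token))))
  if (length(token) > 0L) {
    by_token <- split(seq_along(token), token)
    for (tok in names(by_token)) {
      i <- by_token[[tok]]
      # within each (token, pmid) the title block precedes the abstract
      # block and each block is in reading order, so positions are sorted
      assign(tok, split(pos[i], as.character(pmid[i])), envir = postings)
    }
  }

  years <- docs$year
  names(years) <- as.character(docs$pmid)
  structure(
    list(postings = postings, years = years, n_docs = nrow(docs)),
    class = "corpus_index"
  )
}

#' @export
print.corpus_index <- function(x, ...) {
  known <- x$years[!is.na(x$years)]
  cat("<corpus_index>\n")
  cat("  documents: ", x$n_docs, "\n", sep = "")
  cat("  distinct tokens: ", length(ls(x$postings)), "\n", sep = "")
  if (length(known) > 0L) {
    cat("  years: ", min(known), "-", max(known),
        " (", length(known), " known)\n", sep = "")
  } else {
    cat("  years: none known\n")
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' Summarize a corpus index
#'
#' @param x A `corpus_index`.
#' @param ... Unused.
#' @return A one-row tibble: document count, distinct-token and posting
#'   counts, and publication-year coverage.
#' @method glance corpus_index
#' @export
glance.corpus_index <- function(x, ...) {
  toks <- ls(x$postings)
  n_post <- if (length(toks) == 0L) 0L else {
    sum(vapply(toks, function(t) sum(lengths(get(t, envir = x$postings))),
               integer(1)))
  }
  known <- x$years[!is.na(x$years)]
  tibble::tibble(
    n_docs = x$n_docs,
    n_tokens = length(toks),
    n_postings = n_post,
    n_year_known = length(known),
    year_min = if (length(known)) min(known) else NA_integer_,
    year_max = if (length(known)) max(known) else NA_integer_
  )
}

# pmids eligible under an (inclusive) cutoff year; documents with unknown
# year are excluded whenever a cutoff is active.
eligible_pmids <- function(index, cutoff_year = NULL) {
  if (is.null(cutoff_year)) return(names(index$years))
  names(index$years)[!is.na(index$years) & index$years <= cutoff_year]
}

#' Number of documents eligible under a cutoff year
#'
#' @param index A `corpus_index`.
#' @param cutoff_year Optional inclusive year cutoff.
#' @return Integer count; with no cutoff, the full corpus size.
#' @export
n_docs_eligible <- function(index, cutoff_year = NULL) {
  if (is.null(cutoff_year)) return(index$n_docs)
  sum(!is.na(index$years) & index$years <= cutoff_year)
}

#' Find documents containing an exact phrase
#'
#' Matching is case- and punctuation-insensitive: the phrase is normalized
#' by [tokenize_text()] and a document matches if its token stream contains
#' the phrase tokens at consecutive positions (titles and abstracts are
#' separate streams; phrases do not span the boundary).
#'
#' @param index A `corpus_index`.
#' @param phrase A string; must normalize to at least one token.
#' @param cutoff_year Optional inclusive cutoff; only documents with a
#'   known year `<=` the cutoff are returned.
#' @return Sorted integer vector of matching pmids.
#' @export
match_phrase <- function(index, phrase, cutoff_year = NULL) {
  toks <- tokenize1(phrase)
  if (length(toks) == 0L) {
    stop("phrase ", deparse(phrase), " normalizes to zero tokens",
         call. = FALSE)
  }
  plists <- lapply(toks, function(t) {
    if (exists(t, envir = index$postings, inherits = FALSE)) {
      get(t, envir = index$postings)
    } else {
      NULL
    }
  })
  if (any(vapply(plists, is.null, logical(1)))) return(integer(0))
  cand <- names(plists[[1L]])
  for (i in seq_along(plists)[-1L]) {
    cand <- cand[cand %in% names(plists[[i]])]
    if (length(cand) == 0L) return(integer(0))
  }
  cand <- cand[cand %in% eligible_pmids(index, cutoff_year)]
  if (length(cand) == 0L) return(integer(0))
  hit <- vapply(cand, function(pm) {
    cur <- plists[[1L]][[pm]]
    for (i in seq_along(plists)[-1L]) {
      cur <- cur[(cur + (i - 1L)) %in% plists[[i]][[pm]]]
      if (length(cur) == 0L) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(as.integer(cand[hit]))
}

#' Find documents matching a term (any synonym)
#'
#' Document-level OR over the term's synonyms: a document counts once no
#' matter how many synonyms (or occurrences) hit.
#'
#' @param index A `corpus_index`.
#' @param term A character vector of synonyms, or a one-row term-list
#'   tibble (see [term_list()]).
#' @param cutoff_year Optional inclusive cutoff year.
#' @return Sorted integer vector of matching pmids.
#' @export
match_term <- function(index, term, cutoff_year = NULL) {
  syns <- term_synonyms(term)
  hits <- lapply(syns, function(s) match_phrase(index, s, cutoff_year))
  sort(unique(unlist(hits, use.names = FALSE)))
}

term_synonyms <- function(term) {
  if (is.data.frame(term)) {
    stopifnot(nrow(term) == 1L, "synonyms" %in% names(term))
    term$synonyms[[1L]]
  } else {
    as.character(term)
  }
}

INDEX_FORMAT <- "litlinkr-index"
INDEX_VERSION <- 1L

#' Save and load a corpus index
#'
#' The on-disk layout is a versioned JSON container: a header with the
#' format name, version, and document count, the pmid-to-year table, and
#' the postings as token -> pmid -> position arrays. The layout is not
#' guaranteed bit-stable across versions; the contract is that
#' `load_corpus_index(save_corpus_index(x, p))` answers every query
#' identically to `x`. Loading refuses files whose header does not carry
#' the expected format name and version.
#'
#' @param index A `corpus_index`.
#' @param path File path (conventionally `.json`).
#' @return `save_corpus_index()` returns `path` invisibly;
#'   `load_corpus_index()` returns a `corpus_index`.
#' @export
save_corpus_index <- function(index, path) {
  stopifnot(inherits(index, "corpus_index"))
  toks <- sort(ls(index$postings))
  postings <- lapply(toks, function(t) get(t, envir = index$postings))
  names(postings) <- toks
  years <- as.list(index$years)
  years[is.na(index$years)] <- list(NULL)
  payload <- list(
    format = INDEX_FORMAT,
    version = INDEX_VERSION,
    n_docs = index$n_docs,
    years = years,
    postings = postings
  )
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(
    jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", digits = NA),
    con, useBytes = TRUE
  )
  invisible(path)
}

#' @rdname save_corpus_index
#' @export
load_corpus_index <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot read index file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(payload$format, INDEX_FORMAT) ||
      !identical(as.integer(payload$version), INDEX_VERSION)) {
    stop("file ", path, " is not a version-", INDEX_VERSION,
         " ", INDEX_FORMAT, " file", call. = FALSE)
  }
  years <- vapply(payload$years,
                  function(y) if (is.null(y)) NA_integer_ else as.integer(y),
                  integer(1))
  names(years) <- names(payload$years)
  postings <- new.env(parent = emptyenv(), hash = TRUE,
                      size = max(16L, length(payload$postings)))
  for (tok in names(payload$postings)) {
    pl <- lapply(payload$postings[[tok]],
                 function(p) as.integer(unlist(p, use.names = FALSE)))
    assign(tok, pl, envir = postings)
  }
  structure(
    list(postings = postings, years = years,
         n_docs = as.integer(payload$n_docs)),
    class = "corpus_index"
  )
}
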