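#' Normalize and tokenize text
#'
#' The single normalization rule used everywhere in litlinkr: text is
#' NFC-normalized, lowercased, and split on maximal runs of non-word
#' characters (a word character is a Unicode letter, digit, or underscore).
#' Empty tokens are discarded. No stemming or lemmatization is performed;
#' matching is exact at the token level, so indexing, phrase matching, and
#' knowledge-graph name lookup are all provably consistent.
#'
#' @param text Character vector. Each element is tokenized independently.
#' @return A list of character vectors, one per input element; an empty
#'   input element yields `character(0)`.
#' @examples
#' tokenize_text("Raynaud's Disease")
#' tokenize_text(c("IL-17/p38", ""))
#' @export
tokenize_text <- function(text) {
  if (length(text) == 0L) return(list())
  x <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(as.character(text)))
  out <- stringi::stri_split_regex(x, "\\W+", omit_empty = TRUE)
  # stri_split returns character(NA) for NA input; treat NA as empty text
  lapply(out, function(t) if (length(t) == 1L && is.na(t)) character(0) else t)
}

#' @rdname tokenize_text
#' @details `tokenize1()` is the scalar convenience form: one string in, one
#'   character vector of tokens out.
#' @export
tokenize1 <- function(text) {
  stopifnot(length(text) == 1L)
  tokenize_text(text)[[1L]]
}

# Canonical normalized form of a phrase: its tokens re-joined by single
# spaces. Used as the key for knowledge-graph entity names.
normalize_phrase <- function(text) {
  vapply(tokenize_text(text), paste, character(1), collapse = " ")
}
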