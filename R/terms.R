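#' Term lists
#'
#' A term is a labelled concept with a non-empty synonym set; matching is
#' phrase-level, case-insensitive, and punctuation-insensitive (every
#' synonym is run through the same normalizer as the corpus). A term list
#' is a tibble with columns `label` (character) and `synonyms` (list of
#' character vectors). A document matches a term if it matches any synonym;
#' it is counted once however many synonyms hit.
#'
#' `term_list()` builds one in code: named arguments supply synonym
#' vectors, unnamed character arguments become terms whose only synonym is
#' the label itself.
#'
#' @param ... Named character vectors (label = synonyms) and/or bare
#'   character strings.
#' @return A term-list tibble.
#' @examples
#' term_list("migraine",
#'           valproate = c("valproate", "sodium valproate", "valproic acid"))
#' @export
term_list <- function(...) {
  args <- list(...)
  nms <- names(args)
  if (is.null(nms)) nms <- rep("", length(args))
  labels <- character(length(args))
  syns <- vector("list", length(args))
  for (i in seq_along(args)) {
    v <- as.character(args[[i]])
    if (nzchar(nms[i])) {
      labels[i] <- nms[i]
      syns[[i]] <- v
    } else {
      if (length(v) != 1L) {
        stop("unnamed term-list entries must be single strings", call. = FALSE)
      }
      labels[i] <- v
      syns[[i]] <- v
    }
  }
  validate_term_list(tibble::tibble(label = labels, synonyms = syns))
}

validate_term_list <- function(terms) {
  if (!all(c("label", "synonyms") %in% names(terms))) {
    stop("a term list needs `label` and `synonyms` columns", call. = FALSE)
  }
  if (nrow(terms) == 0L) return(tibble::as_tibble(terms))
  ok <- vapply(terms$synonyms, function(s) {
    length(s) > 0L && all(lengths(tokenize_text(s)) > 0L)
  }, logical(1))
  if (!all(ok)) {
    stop("term(s) with a synonym that normalizes to zero tokens: ",
         paste(terms$label[!ok], collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(terms)
}

#' Read a term list from TSV
#'
#' Two tab-separated columns: `label` and a pipe-separated synonym set. A
#' line with a single bare word is a term whose only synonym is itself.
#' Lines starting with `#` and blank lines are ignored; a header line
#' `label<TAB>synonyms` is ignored if present.
#'
#' @param path File path.
#' @return A term-list tibble (see [term_list()]).
#' @export
read_term_list <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) > 0L && identical(tolower(lines[[1L]]), "label\tsynonyms")) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    return(tibble::tibble(label = character(), synonyms = list()))
  }
  parts <- stringi::stri_split_fixed(lines, "\t")
  labels <- vapply(parts, function(p) trimws(p[[1L]]), character(1))
  syns <- lapply(parts, function(p) {
    if (length(p) >= 2L && nzchar(trimws(p[[2L]]))) {
      trimws(stringi::stri_split_fixed(p[[2L]], "|")[[1L]])
    } else {
      trimws(p[[1L]])
    }
  })
  validate_term_list(tibble::tibble(label = labels, synonyms = syns))
}

#' Write a term list as TSV
#'
#' @param terms A term-list tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_list <- function(terms, path) {
  terms <- validate_term_list(terms)
  lines <- c(
    "label\tsynonyms",
    vapply(seq_len(nrow(terms)), function(i) {
      paste0(terms$label[i], "\t", paste(terms$synonyms[[i]], collapse = "|"))
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
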