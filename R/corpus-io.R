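#' Corpus documents
#'
#' A corpus is an ordinary tibble with one row per abstract record and
#' columns `pmid` (positive integer, unique), `title` (character),
#' `abstract` (character, possibly empty), and `year` (integer publication
#' year, `NA` when unknown). All readers return this shape and all indexing
#' functions consume it.
#'
#' @param pmid Integer vector of document identifiers.
#' @param title,abstract Character vectors (recycled if length 1).
#' @param year Integer vector of publication years; `NA` = unknown.
#' @return A corpus tibble.
#' @export
corpus_tibble <- function(pmid = integer(), title = character(),
                          abstract = "", year = NA_integer_) {
  docs <- tibble::tibble(
    pmid = as.integer(pmid),
    title = as.character(title),
    abstract = as.character(abstract),
    year = as.integer(year)
  )
  validate_corpus(docs)
}

validate_corpus <- function(docs, dedupe = TRUE) {
  req <- c("pmid", "title", "abstract", "year")
  missing <- setdiff(req, names(docs))
  if (length(missing) > 0L) {
    stop("corpus is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(docs$pmid) || any(docs$pmid <= 0L)) {
    stop("every document needs a positive integer pmid", call. = FALSE)
  }
  bad_year <- !is.na(docs$year) & (docs$year < 1500L | docs$year > 2100L)
  if (any(bad_year)) {
    stop("publication years must lie in [1500, 2100] when known", call. = FALSE)
  }
  if (dedupe && anyDuplicated(docs$pmid)) {
    dup <- unique(docs$pmid[duplicated(docs$pmid)])
    warning("duplicate pmid(s) ", paste(utils::head(dup, 5L), collapse = ", "),
            if (length(dup) > 5L) ", ..." else "",
            "; keeping the last record for each", call. = FALSE)
    docs <- docs[!duplicated(docs$pmid, fromLast = TRUE), , drop = FALSE]
  }
  tibble::as_tibble(docs)
}

#' Read MEDLINE-style citation XML
#'
#' Parses abstracts from the PubMed citation schema: one record per
#' `MedlineCitation`, reading `PMID`, `ArticleTitle`, `AbstractText`
#' (multiple sections are concatenated in order with a space), and
#' `PubDate/Year` (falling back to a leading four-digit year inside
#' `MedlineDate`). Citations lacking a PMID are skipped with a warning;
#' malformed XML is a hard parse error.
#'
#' @param path Path to an XML file (or anything `xml2::read_xml()` accepts).
#' @return A corpus tibble (see [corpus_tibble()]).
#' @export
read_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path)
  cites <- xml2::xml_find_all(doc, ".//MedlineCitation")
  recs <- lapply(cites, function(cite) {
    pmid_txt <- xml2::xml_text(xml2::xml_find_first(cite, "./PMID"))
    pmid <- suppressWarnings(as.integer(pmid_txt))
    if (is.na(pmid)) {
      warning("skipping citation without a parseable PMID", call. = FALSE)
      return(NULL)
    }
    title <- xml2::xml_text(xml2::xml_find_first(cite, ".//ArticleTitle"))
    if (is.na(title)) title <- ""
    abstract <- paste(
      xml2::xml_text(xml2::xml_find_all(cite, ".//Abstract/AbstractText")),
      collapse = " "
    )
    year_txt <- xml2::xml_text(xml2::xml_find_first(cite, ".//PubDate/Year"))
    year <- suppressWarnings(as.integer(year_txt))
    if (is.na(year)) {
      mdate <- xml2::xml_text(xml2::xml_find_first(cite, ".//PubDate/MedlineDate"))
      if (!is.na(mdate)) {
        m <- stringi::stri_extract_first_regex(mdate, "^\\d{4}")
        year <- suppressWarnings(as.integer(m))
      }
    }
    if (!is.na(year) && (year < 1500L || year > 2100L)) year <- NA_integer_
    tibble::tibble(pmid = pmid, title = title, abstract = abstract, year = year)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    return(corpus_tibble())
  }
  validate_corpus(dplyr::bind_rows(recs))
}

#' Write a corpus as MEDLINE-style citation XML
#'
#' Emits the subset of the PubMed citation schema that [read_pubmed_xml()]
#' consumes, so that write-then-read is the identity on document tibbles.
#'
#' @param docs A corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pubmed_xml <- function(docs, path) {
  docs <- validate_corpus(docs)
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(docs))) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    cite <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cite, "PMID", as.character(docs$pmid[i]))
    article <- xml2::xml_add_child(cite, "Article")
    xml2::xml_add_child(article, "ArticleTitle", docs$title[i])
    if (nzchar(docs$abstract[i])) {
      abst <- xml2::xml_add_child(article, "Abstract")
      xml2::xml_add_child(abst, "AbstractText", docs$abstract[i])
    }
    journal <- xml2::xml_add_child(article, "Journal")
    issue <- xml2::xml_add_child(journal, "JournalIssue")
    pubdate <- xml2::xml_add_child(issue, "PubDate")
    if (!is.na(docs$year[i])) {
      xml2::xml_add_child(pubdate, "Year", as.character(docs$year[i]))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read and write the JSONL corpus dialect
#'
#' One JSON object per line with fields `pmid` (integer), `title` (string),
#' `abstract` (string), and `year` (integer or null). `read_corpus_jsonl()`
#' resolves duplicate pmids by keeping the last record (with a warning);
#' a line without a pmid is a record-level error.
#'
#' @param path File path.
#' @param docs A corpus tibble.
#' @return `read_corpus_jsonl()` returns a corpus tibble;
#'   `write_corpus_jsonl()` returns `path` invisibly.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(corpus_tibble())
  recs <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
    if (is.null(rec$pmid) || is.na(suppressWarnings(as.integer(rec$pmid)))) {
      stop("line ", i, ": record has no pmid", call. = FALSE)
    }
    tibble::tibble(
      pmid = as.integer(rec$pmid),
      title = if (is.null(rec$title)) "" else as.character(rec$title),
      abstract = if (is.null(rec$abstract)) "" else as.character(rec$abstract),
      year = if (is.null(rec$year) || is.null(unlist(rec$year))) {
        NA_integer_
      } else {
        as.integer(rec$year)
      }
    )
  })
  validate_corpus(dplyr::bind_rows(recs))
}

#' @rdname read_corpus_jsonl
#' @export
write_corpus_jsonl <- function(docs, path) {
  docs <- validate_corpus(docs)
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    jsonlite::toJSON(
      list(pmid = docs$pmid[i], title = docs$title[i],
           abstract = docs$abstract[i],
           year = if (is.na(docs$year[i])) NULL else docs$year[i]),
      auto_unbox = TRUE, null = "null"
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus in either supported format
#'
#' @param path File path.
#' @param format `"auto"` (by file extension), `"xml"`, or `"jsonl"`.
#' @return A corpus tibble.
#' @export
read_corpus <- function(path, format = c("auto", "xml", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "jsonl"
  }
  switch(format, xml = read_pubmed_xml(path), jsonl = read_corpus_jsonl(path))
}
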