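#' Run a declarative query plan
#'
#' Executes a full search described by a configuration list or YAML/JSON
#' file and writes the result files. The configuration names either a
#' prebuilt index (`index`) or a corpus file (`corpus`, XML or JSONL),
#' the term-list files, the mode, and the search parameters:
#'
#' \describe{
#'   \item{mode}{`"km"` (single-stage pair search of A against B),
#'     `"open"`, or `"closed"`.}
#'   \item{a_terms, b_terms, c_terms}{Term-list TSV paths (`c_terms`
#'     unused in km mode).}
#'   \item{ab_p_threshold, max_b_pairs, bc_p_threshold, cutoff_year,
#'     association_measure, top_n}{Search parameters, all optional with
#'     the package defaults.}
#'   \item{relations}{Optional relation-triples TSV; open-mode hits are
#'     annotated with it.}
#'   \item{output}{Output stem; `<output>.tsv` is always written, and
#'     `<output>.json` additionally for open mode.}
#' }
#'
#' All referenced input paths are checked before any computation starts,
#' so a misconfigured run fails fast without partial outputs. The counts
#' at every filtering stage are logged.
#'
#' @param config A named list, or a path to a YAML or JSON file holding
#'   one.
#' @return Invisibly, a list with the result tibble and the paths
#'   written.
#' @export
run_query_plan <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  mode <- config$mode
  if (is.null(mode) ||
      !mode %in% c("km", "open", "closed", "skim-open", "skim-closed")) {
    stop("config: mode must be one of km, open, closed", call. = FALSE)
  }
  mode <- sub("^skim-", "", mode)
  if (is.null(config$output)) stop("config: output is required", call. = FALSE)

  need <- c("a_terms", "b_terms", if (mode != "km") "c_terms")
  src <- if (!is.null(config$index)) "index" else "corpus"
  if (is.null(config[[src]])) {
    stop("config: either index or corpus is required", call. = FALSE)
  }
  paths <- unlist(config[c(need, src,
                           if (!is.null(config$relations)) "relations")])
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("config: missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  index <- if (src == "index") {
    load_corpus_index(config$index)
  } else {
    build_corpus_index(read_corpus(config$corpus))
  }
  a_terms <- read_term_list(config$a_terms)
  b_terms <- read_term_list(config$b_terms)
  c_terms <- if (mode != "km") read_term_list(config$c_terms)
  message("loaded terms: ", nrow(a_terms), " A, ", nrow(b_terms), " B",
          if (mode != "km") paste0(", ", nrow(c_terms), " C"))

  par <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  measure <- par("association_measure", "fet")
  cutoff <- config$cutoff_year
  top_n <- config$top_n
  out_tsv <- paste0(config$output, ".tsv")
  files <- out_tsv

  result <- switch(mode,
    km = {
      res <- pair_search(index, a_terms, b_terms, cutoff_year = cutoff,
                         measure = measure)
      if (!is.null(top_n)) res <- utils::head(res, top_n)
      message("km: ", nrow(res), " pairs written")
      write_pair_results(res, out_tsv)
      res
    },
    open = {
      hits <- open_discovery(
        index, a_terms, b_terms, c_terms,
        ab_p_threshold = par("ab_p_threshold", 1e-5),
        max_b_pairs = par("max_b_pairs", 300L),
        bc_p_threshold = par("bc_p_threshold", 1e-5),
        cutoff_year = cutoff, measure = measure, top_n = top_n,
        verbose = TRUE
      )
      if (!is.null(config$relations)) {
        hits <- annotate_hits(hits, read_kg_relations(config$relations))
      }
      message("open: ", nrow(hits), " chains reported")
      write_hits(hits, out_tsv)
      out_json <- paste0(config$output, ".json")
      write_hits_json(hits, out_json)
      files <- c(files, out_json)
      hits
    },
    closed = {
      if (nrow(a_terms) != 1L || nrow(c_terms) < 1L) {
        stop("closed mode needs exactly one A term and at least one C term",
             call. = FALSE)
      }
      res <- dplyr::bind_rows(lapply(seq_len(nrow(c_terms)), function(i) {
        closed_discovery(
          index, a_terms, c_terms[i, ], b_terms,
          significance_threshold = par("ab_p_threshold", 1e-5),
          cutoff_year = cutoff, measure = measure
        )
      }))
      if (!is.null(top_n)) res <- utils::head(res, top_n)
      message("closed: ", nrow(res), " linking B terms reported")
      out <- tibble::tibble(
        a_label = res$a_label, b_label = res$b_label, c_label = res$c_label,
        ab_p = format(res$ab_p_value, digits = 17, trim = TRUE),
        ab_p_display = format_p(res$ab_p_value),
        bc_p = format(res$bc_p_value, digits = 17, trim = TRUE),
        bc_p_display = format_p(res$bc_p_value),
        ab_evidence_pmids = vapply(res$ab_evidence, function(e)
          paste(utils::head(e, 50L), collapse = ","), character(1)),
        bc_evidence_pmids = vapply(res$bc_evidence, function(e)
          paste(utils::head(e, 50L), collapse = ","), character(1))
      )
      write_tsv_versioned(out, out_tsv,
                          "# litlinkr closed-discovery results v1")
      res
    }
  )
  invisible(list(result = result, files = files))
}
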