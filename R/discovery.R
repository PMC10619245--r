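#' Prediction score for a linking pair
#'
#' The quantity used to rank candidate targets in open discovery. For a
#' B-C pair it combines statistical significance with coverage: if the
#' pair's p-value beats the significance threshold, the score is the ratio
#' of the B-and-C abstract count to the C abstract count (how much of the
#' C literature also mentions B); otherwise the score is 0. This
#' significance-gated ratio is this package's canonical instantiation of
#' the score; it is documented in the methods vignette as a design choice.
#'
#' @param p_value Numeric vector of pair p-values.
#' @param ratio Numeric vector, `n_both / n_c` for each pair.
#' @param significance_threshold Pairs at or above this p-value score 0.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
prediction_score <- function(p_value, ratio, significance_threshold = 1e-5) {
  ifelse(p_value < significance_threshold, ratio, 0)
}

#' Serial open discovery: A to B to C
#'
#' The two-stage search. Stage 1 pairs each A term with every B term and
#' keeps pairs with p-value strictly below `ab_p_threshold`; if more than
#' `max_b_pairs` survive, the `max_b_pairs` smallest by p-value are kept
#' (deterministic tie-break). Stage 2 pairs each surviving B with every C
#' term, scores each (A, B, C) chain with [prediction_score()] on the B-C
#' pair, and ranks chains by descending score (ties: ascending B-C
#' p-value, then labels). When several A terms are given, each is searched
#' independently and ranks are assigned within each A term.
#'
#' @param index A `corpus_index`.
#' @param a_terms,b_terms,c_terms Term-list tibbles (see [term_list()]).
#' @param ab_p_threshold Stage-1 significance threshold (strict `<`).
#' @param max_b_pairs Cap on surviving A-B pairs entering stage 2.
#' @param bc_p_threshold Significance threshold gating the prediction
#'   score of B-C pairs.
#' @param cutoff_year Optional inclusive cutoff year applied to all
#'   counting in both stages.
#' @param measure Association measure, `"fet"` or `"chi2"`.
#' @param top_n Optional cap on reported chains per A term.
#' @param verbose Log per-stage counts with [message()].
#' @return An `lbd_hits` tibble: one row per (A, B, C) chain with the A-B
#'   and B-C p-values and counts, `bc_ratio`, `prediction_score`, `rank`,
#'   and evidence pmid list-columns. Chains where the B and C labels
#'   coincide (trivial self-links) are suppressed.
#' @export
open_discovery <- function(index, a_terms, b_terms, c_terms,
                           ab_p_threshold = 1e-5, max_b_pairs = 300L,
                           bc_p_threshold = 1e-5, cutoff_year = NULL,
                           measure = c("fet", "chi2"), top_n = NULL,
                           verbose = FALSE) {
  measure <- match.arg(measure)
  a_terms <- validate_term_list(a_terms)
  b_terms <- validate_term_list(b_terms)
  c_terms <- validate_term_list(c_terms)
  if (nrow(a_terms) == 0L || nrow(b_terms) == 0L || nrow(c_terms) == 0L) {
    stop("open_discovery needs non-empty A, B, and C term lists",
         call. = FALSE)
  }
  check_params(ab_p_threshold, bc_p_threshold, max_b_pairs)

  per_a <- lapply(seq_len(nrow(a_terms)), function(i) {
    open_discovery_one(index, a_terms[i, ], b_terms, c_terms,
                       ab_p_threshold, max_b_pairs, bc_p_threshold,
                       cutoff_year, measure, top_n, verbose)
  })
  hits <- dplyr::bind_rows(per_a)
  hits <- new_lbd_hits(hits)
  attr(hits, "terms") <- list(a = a_terms, b = b_terms, c = c_terms)
  hits
}

check_params <- function(ab_p_threshold, bc_p_threshold, max_b_pairs) {
  stopifnot(ab_p_threshold > 0, ab_p_threshold <= 1,
            bc_p_threshold > 0, bc_p_threshold <= 1,
            max_b_pairs >= 1)
}

open_discovery_one <- function(index, a_term, b_terms, c_terms,
                               ab_p_threshold, max_b_pairs, bc_p_threshold,
                               cutoff_year, measure, top_n, verbose) {
  ab <- pair_search(index, a_term, b_terms, cutoff_year, measure)
  surviving <- ab[ab$p_value < ab_p_threshold, , drop = FALSE]
  n_sig <- nrow(surviving)
  if (n_sig > max_b_pairs) {
    # pair_search output is already sorted ascending by p with the
    # deterministic tie-break, so the head is the smallest-p subset
    surviving <- utils::head(surviving, max_b_pairs)
  }
  if (verbose) {
    message("A term '", a_term$label, "': ", nrow(ab), " A-B pairs tested, ",
            n_sig, " below p < ", format(ab_p_threshold), ", ",
            nrow(surviving), " after cap of ", max_b_pairs)
  }
  if (nrow(surviving) == 0L) {
    message("A term '", a_term$label,
            "': no A-B pair passed the threshold; empty result")
    return(empty_hits())
  }

  b_surv <- b_terms[match(surviving$y_label, b_terms$label), , drop = FALSE]
  bc <- pair_search(index, b_surv, c_terms, cutoff_year, measure)
  if (verbose) {
    message("A term '", a_term$label, "': ", nrow(bc), " B-C pairs tested")
  }
  bc <- bc[bc$x_label != bc$y_label, , drop = FALSE]  # suppress self-links

  ab_at <- match(bc$x_label, surviving$y_label)
  hits <- tibble::tibble(
    a_label = a_term$label,
    b_label = bc$x_label,
    c_label = bc$y_label,
    ab_p_value = surviving$p_value[ab_at],
    ab_n_both = surviving$n_both[ab_at],
    bc_p_value = bc$p_value,
    bc_n_both = bc$n_both,
    n_c = bc$n_y,
    n_total = bc$n_total,
    bc_ratio = bc$ratio,
    prediction_score = prediction_score(bc$p_value, bc$ratio, bc_p_threshold),
    ab_evidence = surviving$evidence[ab_at],
    bc_evidence = bc$evidence
  )
  ord <- order(-hits$prediction_score, hits$bc_p_value,
               hits$b_label, hits$c_label, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  if (!is.null(top_n)) hits <- utils::head(hits, top_n)
  hits[, c("a_label", "b_label", "c_label", "ab_p_value", "ab_n_both",
           "bc_p_value", "bc_n_both", "n_c", "n_total", "bc_ratio",
           "prediction_score", "rank", "ab_evidence", "bc_evidence")]
}

empty_hits <- function() {
  tibble::tibble(
    a_label = character(), b_label = character(), c_label = character(),
    ab_p_value = numeric(), ab_n_both = integer(),
    bc_p_value = numeric(), bc_n_both = integer(),
    n_c = integer(), n_total = integer(), bc_ratio = numeric(),
    prediction_score = numeric(), rank = integer(),
    ab_evidence = list(), bc_evidence = list()
  )
}

new_lbd_hits <- function(x) {
  class(x) <- c("lbd_hits", class(tibble::tibble()))
  x
}

#' Closed discovery: find B terms linking a given A and C
#'
#' For each candidate intermediate B, computes the A-B and B-C
#' associations and reports the B terms significant on both sides
#' (strictly below `significance_threshold`), sorted ascending by the
#' worse of the two p-values. The B-C p-value for any (B, C) pair is
#' computed by the same route as in [open_discovery()], so the two modes
#' agree bit-exactly on shared pairs.
#'
#' @param index A `corpus_index`.
#' @param a_term,c_term One-row term-list tibbles (or synonym vectors).
#' @param b_terms Term-list tibble of candidate intermediates.
#' @param significance_threshold Strict p-value threshold applied to both
#'   sides.
#' @param cutoff_year Optional inclusive cutoff year.
#' @param measure Association measure.
#' @return A tibble with one row per linking B term: both p-values,
#'   counts, and evidence list-columns.
#' @export
closed_discovery <- function(index, a_term, c_term, b_terms,
                             significance_threshold = 1e-5,
                             cutoff_year = NULL,
                             measure = c("fet", "chi2")) {
  measure <- match.arg(measure)
  a_term <- as_one_term(a_term)
  c_term <- as_one_term(c_term)
  b_terms <- validate_term_list(b_terms)
  if (nrow(b_terms) == 0L) {
    stop("closed_discovery needs a non-empty B term list", call. = FALSE)
  }
  stopifnot(significance_threshold > 0, significance_threshold <= 1)

  ab <- pair_search(index, a_term, b_terms, cutoff_year, measure)
  bc <- pair_search(index, b_terms, c_term, cutoff_year, measure)
  ab_at <- match(b_terms$label, ab$y_label)
  bc_at <- match(b_terms$label, bc$x_label)
  res <- tibble::tibble(
    a_label = a_term$label,
    b_label = b_terms$label,
    c_label = c_term$label,
    ab_p_value = ab$p_value[ab_at],
    ab_n_both = ab$n_both[ab_at],
    bc_p_value = bc$p_value[bc_at],
    bc_n_both = bc$n_both[bc_at],
    ab_evidence = ab$evidence[ab_at],
    bc_evidence = bc$evidence[bc_at]
  )
  res <- res[res$ab_p_value < significance_threshold &
               res$bc_p_value < significance_threshold, , drop = FALSE]
  worst <- pmax(res$ab_p_value, res$bc_p_value)
  res <- res[order(worst, res$b_label, method = "radix"), , drop = FALSE]
  res
}

as_one_term <- function(term) {
  if (is.data.frame(term)) {
    stopifnot(nrow(term) == 1L)
    validate_term_list(term)
  } else {
    # a bare synonym vector: label is the first synonym
    validate_term_list(tibble::tibble(label = as.character(term)[[1L]],
                                      synonyms = list(as.character(term))))
  }
}

#' Write open-discovery hits as TSV
#'
#' One row per chain with full-precision and display p-values, the B-C
#' ratio, prediction score, rank, and comma-separated evidence pmids.
#'
#' @param hits An `lbd_hits` tibble from [open_discovery()].
#' @param path Output path.
#' @param max_evidence Maximum evidence pmids written per side.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, max_evidence = 50L) {
  out <- tibble::tibble(
    a_label = hits$a_label, b_label = hits$b_label, c_label = hits$c_label,
    ab_p = format(hits$ab_p_value, digits = 17, trim = TRUE),
    ab_p_display = format_p(hits$ab_p_value),
    bc_p = format(hits$bc_p_value, digits = 17, trim = TRUE),
    bc_p_display = format_p(hits$bc_p_value),
    bc_ratio = format(hits$bc_ratio, digits = 17, trim = TRUE),
    prediction_score = format(hits$prediction_score, digits = 17, trim = TRUE),
    rank = hits$rank,
    ab_evidence_pmids = vapply(hits$ab_evidence, function(e)
      paste(utils::head(e, max_evidence), collapse = ","), character(1)),
    bc_evidence_pmids = vapply(hits$bc_evidence, function(e)
      paste(utils::head(e, max_evidence), collapse = ","), character(1))
  )
  write_tsv_versioned(out, path, "# litlinkr open-discovery results v1")
}
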