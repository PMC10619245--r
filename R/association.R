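#' One-sided Fisher's exact test for term co-occurrence
#'
#' Tests over-representation of two terms in the same abstracts. For a 2x2
#' table with `a = n_both` abstracts containing both terms, margins
#' `n_x = a + b`, `n_y = a + c`, and corpus size `N = a + b + c + d`, the
#' p-value is the enrichment (upper) tail of the hypergeometric
#' distribution, including the observed table:
#' \deqn{p = P(X \ge a), \quad X \sim \mathrm{Hypergeom}(N, n_x, n_y).}
#'
#' The tail is accumulated in log space (log-sum-exp over `lchoose` terms),
#' so p-values remain accurate far below 1e-300; values below the smallest
#' positive double underflow deterministically to 0, which [format_p()]
#' displays as `"0"` (the convention for p below 2.2e-308).
#'
#' @param n_both Abstract count containing both terms (`a`), or a data
#'   frame with columns `n_both`, `n_x_only`, `n_y_only`, `n_neither`
#'   (e.g. the output of [contingency()]), in which case the other count
#'   arguments are ignored.
#' @param n_x_only,n_y_only,n_neither The remaining cells (`b`, `c`, `d`).
#'   All four arguments are vectorized and recycled.
#' @param log If `TRUE`, return the natural log of the p-value (never
#'   underflows).
#' @return Numeric vector of p-values in `(0, 1]` (or log p-values).
#' @examples
#' fisher_one_sided(2, 0, 0, 2)   # 1/6: enumerate the 2x2 tables by hand
#' fisher_one_sided(0, 10, 10, 80)  # a = 0 is never enriched: p = 1
#' @export
fisher_one_sided <- function(n_both, n_x_only = NULL, n_y_only = NULL,
                             n_neither = NULL, log = FALSE) {
  if (is.data.frame(n_both)) {
    tab <- n_both
    a <- tab$n_both; b <- tab$n_x_only; c <- tab$n_y_only; d <- tab$n_neither
  } else {
    a <- n_both; b <- n_x_only; c <- n_y_only; d <- n_neither
  }
  k <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), k); b <- rep_len(as.numeric(b), k)
  c <- rep_len(as.numeric(c), k); d <- rep_len(as.numeric(d), k)
  if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0)) {
    stop("contingency counts must be non-negative and non-missing",
         call. = FALSE)
  }
  logp <- vapply(seq_len(k), function(i) {
    log_hyper_upper_tail(a[i], a[i] + b[i], a[i] + c[i],
                         a[i] + b[i] + c[i] + d[i])
  }, numeric(1))
  if (log) logp else exp(logp)
}

# log P(X >= a) for X ~ Hypergeom(N, n_x, n_y): sum the pmf over the upper
# support in log space. The support above a has at most min(n_x, n_y) - a + 1
# terms; for enrichment queries this tail is short.
log_hyper_upper_tail <- function(a, n_x, n_y, N) {
  if (a <= 0) return(0)                      # P(X >= 0) = 1
  if (n_x > n_y) { tmp <- n_x; n_x <- n_y; n_y <- tmp }  # transpose-invariant
  hi <- min(n_x, n_y)
  if (a > hi) stop("n_both exceeds a margin: invalid table", call. = FALSE)
  ks <- a:hi
  logs <- lchoose(n_x, ks) + lchoose(N - n_x, n_y - ks) - lchoose(N, n_y)
  m <- max(logs)
  if (!is.finite(m)) return(-Inf)
  min(m + log(sum(exp(logs - m))), 0)        # clamp tiny positive error at 1
}

#' Chi-square test of association (alternative measure)
#'
#' One-degree-of-freedom chi-square test on the 2x2 table, without
#' continuity correction. Provided as a non-canonical alternative to
#' [fisher_one_sided()]; it is unreliable when expected counts are small,
#' which is common for rare terms, so the exact test is the default
#' everywhere. A table with any zero margin has an undefined statistic and
#' returns p = 1 with the `degenerate` attribute set.
#'
#' @inheritParams fisher_one_sided
#' @return Numeric vector of p-values, with a logical attribute
#'   `degenerate` marking zero-margin tables.
#' @export
chi_square <- function(n_both, n_x_only = NULL, n_y_only = NULL,
                       n_neither = NULL) {
  if (is.data.frame(n_both)) {
    tab <- n_both
    a <- tab$n_both; b <- tab$n_x_only; c <- tab$n_y_only; d <- tab$n_neither
  } else {
    a <- n_both; b <- n_x_only; c <- n_y_only; d <- n_neither
  }
  k <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), k); b <- rep_len(as.numeric(b), k)
  c <- rep_len(as.numeric(c), k); d <- rep_len(as.numeric(d), k)
  if (any(c(a, b, c, d) < 0)) {
    stop("contingency counts must be non-negative", call. = FALSE)
  }
  N <- a + b + c + d
  degenerate <- (a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0
  stat <- ifelse(degenerate, 0,
                 N * (a * d - b * c)^2 /
                   ((a + b) * (c + d) * (a + c) * (b + d)))
  p <- ifelse(degenerate, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  attr(p, "degenerate") <- degenerate
  p
}

#' Format a p-value for display
#'
#' One-significant-figure scientific notation in the style used in results
#' tables (`2e-33` for 2.3e-33). A p-value below 2.2e-308 — including
#' values that underflowed to numeric 0 in log-space computation — is
#' displayed as `"0"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector.
#' @examples
#' format_p(c(1e-310, 2.3e-33, 0.17, 1))
#' @export
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 2.2e-308) return("0")
    if (pi >= 1e-3) {
      format(signif(pi, 1), scientific = FALSE, trim = TRUE)
    } else {
      sub("e([+-])0+(\\d)", "e\\1\\2", sprintf("%.0e", pi))
    }
  }, character(1))
}

#' Build the 2x2 co-occurrence table for a term pair
#'
#' Counts abstracts containing both terms, each term alone, and neither,
#' restricted (as is `N`) to documents eligible under the cutoff year.
#'
#' @param index A `corpus_index`.
#' @param term_x,term_y Synonym character vectors or one-row term-list
#'   tibbles.
#' @param cutoff_year Optional inclusive cutoff year.
#' @return A one-row tibble with columns `n_both`, `n_x_only`, `n_y_only`,
#'   `n_neither`, the margins `n_x`, `n_y`, the eligible corpus size
#'   `n_total`, and a list-column `evidence` holding the pmids that contain
#'   both terms.
#' @export
contingency <- function(index, term_x, term_y, cutoff_year = NULL) {
  x <- match_term(index, term_x, cutoff_year)
  y <- match_term(index, term_y, cutoff_year)
  N <- n_docs_eligible(index, cutoff_year)
  both <- intersect(x, y)
  a <- length(both)
  b <- length(x) - a
  c <- length(y) - a
  tibble::tibble(
    n_both = a, n_x_only = b, n_y_only = c, n_neither = N - a - b - c,
    n_x = length(x), n_y = length(y), n_total = N,
    evidence = list(sort(both))
  )
}

#' Single-stage pair search over two term lists
#'
#' Crosses every term in `x_terms` with every term in `y_terms`, builds
#' the 2x2 abstract-count table for each pair against the index, and
#' computes the association p-value. Results are sorted ascending by
#' p-value with a deterministic tie-break (descending `n_both`, then
#' lexicographic labels). A pair where either term matches no abstract is
#' kept with p = 1 and flagged `term_absent`.
#'
#' @param index A `corpus_index`.
#' @param x_terms,y_terms Term-list tibbles (see [term_list()]).
#' @param cutoff_year Optional inclusive cutoff year.
#' @param measure `"fet"` (one-sided Fisher's exact test, default) or
#'   `"chi2"`.
#' @return An `lbd_pairs` tibble: labels, counts, `n_total`, `p_value`,
#'   `ratio` (`n_both / n_y`, 0 when `n_y` is 0), `term_absent`, and an
#'   `evidence` list-column of co-occurrence pmids.
#' @export
pair_search <- function(index, x_terms, y_terms, cutoff_year = NULL,
                        measure = c("fet", "chi2")) {
  measure <- match.arg(measure)
  x_terms <- validate_term_list(x_terms)
  y_terms <- validate_term_list(y_terms)
  if (nrow(x_terms) == 0L || nrow(y_terms) == 0L) {
    stop("pair_search needs non-empty term lists on both sides", call. = FALSE)
  }
  x_hits <- lapply(x_terms$synonyms, match_term, index = index,
                   cutoff_year = cutoff_year)
  y_hits <- lapply(y_terms$synonyms, match_term, index = index,
                   cutoff_year = cutoff_year)
  N <- n_docs_eligible(index, cutoff_year)

  grid <- tidyr::expand_grid(xi = seq_len(nrow(x_terms)),
                             yi = seq_len(nrow(y_terms)))
  both <- purrr::map2(grid$xi, grid$yi,
                      function(i, j) intersect(x_hits[[i]], y_hits[[j]]))
  n_x <- lengths(x_hits)[grid$xi]
  n_y <- lengths(y_hits)[grid$yi]
  a <- lengths(both)
  res <- tibble::tibble(
    x_label = x_terms$label[grid$xi],
    y_label = y_terms$label[grid$yi],
    n_x = n_x, n_y = n_y, n_both = a, n_total = N,
    n_x_only = n_x - a, n_y_only = n_y - a,
    n_neither = N - n_x - n_y + a
  )
  absent <- res$n_x == 0L | res$n_y == 0L
  p <- switch(measure,
    fet = fisher_one_sided(res),
    chi2 = as.numeric(chi_square(res))
  )
  p[absent] <- 1
  res$p_value <- p
  res$ratio <- ifelse(res$n_y == 0L, 0, res$n_both / res$n_y)
  res$term_absent <- absent
  res$evidence <- lapply(both, sort)
  res <- res[, c("x_label", "y_label", "n_x", "n_y", "n_both", "n_total",
                 "p_value", "ratio", "term_absent", "evidence")]
  res <- res[order_pairs(res), , drop = FALSE]
  new_lbd_pairs(res)
}

# deterministic result ordering: ascending p, then descending n_both,
# then lexicographic labels (C locale via radix sort)
order_pairs <- function(res) {
  order(res$p_value, -res$n_both, res$x_label, res$y_label, method = "radix")
}

new_lbd_pairs <- function(x) {
  class(x) <- c("lbd_pairs", class(tibble::tibble()))
  x
}

#' Write pair-search results as TSV
#'
#' Tab-separated with a `#` schema-version header line. The `p_value`
#' column is full precision; `p_display` applies [format_p()]. Evidence
#' pmids are comma-separated and capped at `max_evidence` per row.
#'
#' @param pairs An `lbd_pairs` tibble from [pair_search()].
#' @param path Output path.
#' @param max_evidence Maximum evidence pmids written per row.
#' @return `path`, invisibly.
#' @export
write_pair_results <- function(pairs, path, max_evidence = 50L) {
  out <- tibble::tibble(
    x_label = pairs$x_label, y_label = pairs$y_label,
    n_x = pairs$n_x, n_y = pairs$n_y, n_both = pairs$n_both,
    N = pairs$n_total,
    p_value = format(pairs$p_value, digits = 17, trim = TRUE),
    p_display = format_p(pairs$p_value),
    ratio = format(pairs$ratio, digits = 17, trim = TRUE),
    evidence_pmids = vapply(pairs$evidence, function(e) {
      paste(utils::head(e, max_evidence), collapse = ",")
    }, character(1))
  )
  write_tsv_versioned(out, path, "# litlinkr pair results v1")
}
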