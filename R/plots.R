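#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot pair-search results
#'
#' Enrichment plot: each point is a term pair, placed by its coverage
#' ratio (`n_both / n_y`) and `-log10` p-value, with the significance
#' threshold drawn as a dashed line. P-values that underflowed to 0 are
#' drawn at the largest finite `-log10 p` in the data.
#'
#' @param object An `lbd_pairs` tibble from [pair_search()].
#' @param p_threshold Significance line (default 1e-5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lbd_pairs
#' @export
autoplot.lbd_pairs <- function(object, p_threshold = 1e-5, ...) {
  df <- tibble::as_tibble(object)
  nlp <- -log10(df$p_value)
  cap <- max(nlp[is.finite(nlp)], -log10(p_threshold), 1)
  df$neg_log10_p <- pmin(nlp, cap + 1)
  df$significant <- df$p_value < p_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$neg_log10_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "co-occurrence ratio (n_both / n_y)",
                  y = expression(-log[10] ~ p),
                  colour = paste0("p < ", format(p_threshold))) +
    ggplot2::theme_minimal()
}

#' Plot open-discovery hits
#'
#' Horizontal bars of the top-ranked chains by prediction score, labelled
#' "B -> C", faceted by A term when several were searched.
#'
#' @param object An `lbd_hits` tibble from [open_discovery()].
#' @param top_n Number of top chains per A term to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lbd_hits
#' @export
autoplot.lbd_hits <- function(object, top_n = 20L, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$a_label) |>
    dplyr::slice_min(.data$rank, n = top_n) |>
    dplyr::ungroup()
  df$chain <- paste(df$b_label, "→", df$c_label)
  df$chain <- stats::reorder(df$chain, df$prediction_score)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction_score,
                                        y = .data$chain)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::labs(x = "prediction score", y = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(df$a_label)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$a_label),
                                 scales = "free_y")
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy pair-search or discovery results
#'
#' Returns the result as a plain tibble with the evidence list-columns
#' replaced by evidence counts, convenient for printing and export.
#'
#' @param x An `lbd_pairs` or `lbd_hits` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lbd_pairs
#' @export
tidy.lbd_pairs <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_evidence <- lengths(out$evidence)
  out$evidence <- NULL
  out
}

#' @rdname tidy.lbd_pairs
#' @method tidy lbd_hits
#' @export
tidy.lbd_hits <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_ab_evidence <- lengths(out$ab_evidence)
  out$n_bc_evidence <- lengths(out$bc_evidence)
  out$ab_evidence <- NULL
  out$bc_evidence <- NULL
  for (col in c("ab_annotations", "bc_annotations")) {
    if (col %in% names(out)) {
      out[[paste0("n_", col)]] <- vapply(out[[col]], nrow, integer(1))
      out[[col]] <- NULL
    }
  }
  out
}
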