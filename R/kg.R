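#' Knowledge-graph entity and relation vocabularies
#'
#' The closed label sets for typed entities and typed directed relations.
#' `KG_SYMMETRIC_RELATIONS` are reported without a direction when a pair
#' is annotated, since their meaning does not depend on edge orientation.
#'
#' @format Character vectors.
#' @export
KG_ENTITY_TYPES <- c("GGP", "CONDITION", "CHEMICAL", "BIO_PROCESS", "DRUG")

#' @rdname KG_ENTITY_TYPES
#' @export
KG_RELATION_LABELS <- c(
  "ACTIVATES", "INHIBITS", "REGULATES", "POS_ASSOCIATION",
  "NEG_ASSOCIATION", "COREF", "BINDS", "DRUG_INTERACTION_WITH",
  "TREATS", "MUTATION_AFFECTS"
)

#' @rdname KG_ENTITY_TYPES
#' @export
KG_SYMMETRIC_RELATIONS <- c("COREF", "POS_ASSOCIATION", "NEG_ASSOCIATION")

#' Load a relation-triples file into a knowledge graph
#'
#' Reads a TSV with columns `subject`, `subject_type`, `relation`,
#' `object`, `object_type`, `pmids` (comma-separated integers). Entity
#' names are normalized with the same tokenizer used for corpus matching,
#' so graph lookup and abstract matching can never disagree on case or
#' punctuation. Rows with an unknown relation or entity type are skipped
#' with a warning; rows with no evidence pmids are skipped. Duplicate
#' (subject, relation, object) rows merge their evidence sets.
#'
#' @param path File path (a `#` header line is tolerated).
#' @return A `knowledge_graph` object.
#' @export
read_kg_relations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  req <- c("subject", "subject_type", "relation", "object", "object_type",
           "pmids")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    stop("relations file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  kg_from_tibble(tibble::as_tibble(df))
}

#' @rdname read_kg_relations
#' @param triples A tibble with the relations-file columns (`pmids` may be
#'   a character of comma-separated ids or a list of integer vectors).
#' @export
kg_from_tibble <- function(triples) {
  n <- nrow(triples)
  if (n == 0L) return(new_knowledge_graph(empty_kg_edges()))
  pmids <- triples$pmids
  if (!is.list(pmids)) {
    pmids <- lapply(stringi::stri_split_regex(as.character(pmids), "[,;\\s]+",
                                              omit_empty = TRUE),
                    function(p) sort(unique(as.integer(p))))
  }
  bad_rel <- !(triples$relation %in% KG_RELATION_LABELS)
  bad_type <- !(triples$subject_type %in% KG_ENTITY_TYPES) |
    !(triples$object_type %in% KG_ENTITY_TYPES)
  no_ev <- lengths(pmids) == 0L
  if (any(bad_rel)) {
    warning(sum(bad_rel), " row(s) with unknown relation label skipped (e.g. ",
            triples$relation[bad_rel][1L], ")", call. = FALSE)
  }
  if (any(bad_type & !bad_rel)) {
    warning(sum(bad_type & !bad_rel),
            " row(s) with unknown entity type skipped", call. = FALSE)
  }
  keep <- !bad_rel & !bad_type & !no_ev
  edges <- tibble::tibble(
    subject = normalize_phrase(triples$subject[keep]),
    subject_type = triples$subject_type[keep],
    relation = triples$relation[keep],
    object = normalize_phrase(triples$object[keep]),
    object_type = triples$object_type[keep],
    evidence = pmids[keep]
  )
  # merge duplicate triples, unioning evidence
  edges <- edges |>
    dplyr::group_by(.data$subject, .data$subject_type, .data$relation,
                    .data$object, .data$object_type) |>
    dplyr::summarise(
      evidence = list(sort(unique(unlist(.data$evidence)))),
      .groups = "drop"
    )
  new_knowledge_graph(edges)
}

empty_kg_edges <- function() {
  tibble::tibble(
    subject = character(), subject_type = character(),
    relation = character(), object = character(),
    object_type = character(), evidence = list()
  )
}

new_knowledge_graph <- function(edges) {
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(edges))) {
    for (nm in unique(c(edges$subject[i], edges$object[i]))) {
      lookup[[nm]] <- c(lookup[[nm]], i)
    }
  }
  structure(list(edges = edges, lookup = lookup), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph>\n")
  cat("  nodes: ", length(ls(x$lookup)), "\n", sep = "")
  cat("  edges: ", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' Look up typed relations between two terms
#'
#' Returns every edge whose endpoints match any synonym of `x` on one side
#' and any synonym of `y` on the other, in either direction. Matching is
#' exact on normalized names (same normalizer as corpus matching). The
#' `direction` column is `"forward"` (x as subject), `"reverse"` (y as
#' subject), or `"symmetric"` for relations whose orientation carries no
#' meaning (`KG_SYMMETRIC_RELATIONS`). An empty tibble means the pair
#' simply lacks annotations; it is not an error.
#'
#' @param graph A `knowledge_graph`.
#' @param x,y Synonym character vectors or one-row term-list tibbles.
#' @return A tibble with columns `direction`, `relation`, `subject`,
#'   `subject_type`, `object`, `object_type`, and an `evidence`
#'   list-column of pmids.
#' @export
annotate_pair <- function(graph, x, y) {
  xn <- unique(normalize_phrase(term_synonyms(x)))
  yn <- unique(normalize_phrase(term_synonyms(y)))
  idx <- unique(unlist(lapply(unique(c(xn, yn)), function(nm)
    graph$lookup[[nm]]), use.names = FALSE))
  if (length(idx) == 0L) return(empty_annotation())
  e <- graph$edges[sort(idx), , drop = FALSE]
  fwd <- e$subject %in% xn & e$object %in% yn
  bwd <- e$subject %in% yn & e$object %in% xn
  keep <- fwd | bwd
  if (!any(keep)) return(empty_annotation())
  e <- e[keep, , drop = FALSE]
  direction <- ifelse(e$relation %in% KG_SYMMETRIC_RELATIONS, "symmetric",
                      ifelse(fwd[keep], "forward", "reverse"))
  tibble::tibble(
    direction = direction, relation = e$relation,
    subject = e$subject, subject_type = e$subject_type,
    object = e$object, object_type = e$object_type,
    evidence = e$evidence
  )
}

empty_annotation <- function() {
  tibble::tibble(
    direction = character(), relation = character(),
    subject = character(), subject_type = character(),
    object = character(), object_type = character(),
    evidence = list()
  )
}

#' Annotate discovery hits with knowledge-graph relations
#'
#' Adds `ab_annotations` and `bc_annotations` list-columns to an open-
#' discovery result: each element is the [annotate_pair()] tibble for that
#' chain's A-B or B-C pair (possibly empty). Annotation is a pure
#' decoration — p-values, scores, ranks, and row order are unchanged.
#'
#' @param hits An `lbd_hits` tibble from [open_discovery()].
#' @param graph A `knowledge_graph`, or `NULL` for no annotations.
#' @param terms Optional list with term-list tibbles `a`, `b`, `c` mapping
#'   hit labels to synonym sets; defaults to the term lists the search was
#'   run with (carried on the hits object). Labels absent from the lists
#'   match as their own single synonym.
#' @return `hits` with the two annotation list-columns added.
#' @export
annotate_hits <- function(hits, graph, terms = attr(hits, "terms")) {
  syn_for <- function(label, which) {
    tl <- terms[[which]]
    if (!is.null(tl)) {
      i <- match(label, tl$label)
      if (!is.na(i)) return(tl$synonyms[[i]])
    }
    label
  }
  lookup1 <- function(xl, yl, wx, wy) {
    if (is.null(graph)) return(empty_annotation())
    annotate_pair(graph, syn_for(xl, wx), syn_for(yl, wy))
  }
  hits$ab_annotations <- purrr::map2(hits$a_label, hits$b_label,
                                     lookup1, wx = "a", wy = "b")
  hits$bc_annotations <- purrr::map2(hits$b_label, hits$c_label,
                                     lookup1, wx = "b", wy = "c")
  hits
}

#' Write (annotated) discovery hits as JSON
#'
#' The open-discovery result schema plus, when present, annotation arrays
#' of `{direction, label, pmids}` objects per side.
#'
#' @param hits An `lbd_hits` tibble, annotated or not.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_json <- function(hits, path) {
  ann_json <- function(ann) {
    if (is.null(ann) || nrow(ann) == 0L) return(list())
    lapply(seq_len(nrow(ann)), function(i) {
      list(direction = ann$direction[i], label = ann$relation[i],
           pmids = as.integer(ann$evidence[[i]]))
    })
  }
  recs <- lapply(seq_len(nrow(hits)), function(i) {
    rec <- list(
      a_label = hits$a_label[i], b_label = hits$b_label[i],
      c_label = hits$c_label[i],
      ab_p = hits$ab_p_value[i], ab_p_display = format_p(hits$ab_p_value[i]),
      bc_p = hits$bc_p_value[i], bc_p_display = format_p(hits$bc_p_value[i]),
      bc_ratio = hits$bc_ratio[i],
      prediction_score = hits$prediction_score[i],
      rank = hits$rank[i],
      ab_evidence_pmids = as.integer(hits$ab_evidence[[i]]),
      bc_evidence_pmids = as.integer(hits$bc_evidence[[i]])
    )
    rec$ab_annotations <- if ("ab_annotations" %in% names(hits)) {
      ann_json(hits$ab_annotations[[i]])
    } else list()
    rec$bc_annotations <- if ("bc_annotations" %in% names(hits)) {
      ann_json(hits$bc_annotations[[i]])
    } else list()
    rec
  })
  payload <- list(schema = "litlinkr-hits-v1", hits = recs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
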