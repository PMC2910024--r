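# TSV writers for the pipeline outputs. All numeric output uses the
# period as decimal separator regardless of locale.

#' Write a score matrix (and its absence mask) as TSV
#'
#' Writes `file` with the term x dataset values and, when `mask_file` is
#' given, a sibling TSV of the absence mask (`TRUE` where the term had
#' `x = 0` and the cell holds the placeholder).
#'
#' @param sm A `score_matrix`.
#' @param file Values TSV path.
#' @param mask_file Optional mask TSV path.
#' @export
write_score_matrix <- function(sm, file, mask_file = NULL) {
  df <- data.frame(term = rownames(sm$values), sm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mask_file)) {
    dm <- data.frame(term = rownames(sm$mask), sm$mask,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(dm, mask_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}

#' Read a score matrix written by [write_score_matrix()]
#' @param file Values TSV path.
#' @param mask_file Mask TSV path (required to restore the mask).
#' @param placeholder Placeholder value the matrix was built with.
#' @return A `score_matrix`.
#' @export
read_score_matrix <- function(file, mask_file, placeholder) {
  v <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(v[, -1, drop = FALSE])
  rownames(values) <- v[[1]]
  m <- utils::read.delim(mask_file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  mask <- as.matrix(m[, -1, drop = FALSE]) == "TRUE" |
    as.matrix(m[, -1, drop = FALSE]) == TRUE
  rownames(mask) <- m[[1]]
  structure(list(values = values, mask = mask, placeholder = placeholder,
                 standardized = FALSE, center = NULL, scale = NULL),
            class = "score_matrix")
}

#' Write the contribution table as TSV (percentages, 2 decimals)
#' @param ct Matrix from [contribution_table()].
#' @param file Output path.
#' @export
write_contribution <- function(ct, file) {
  df <- data.frame(fraction = rownames(ct),
                   format(round(ct, 2), nsmall = 2, trim = TRUE,
                          decimal.mark = "."),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write term groups as TSV (label, term, rank, score)
#' @param groups A `term_groups` data.frame.
#' @param file Output path.
#' @export
write_groups <- function(groups, file) {
  utils::write.table(groups, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write bi-plot coordinates as TSV
#' @param coords data.frame from [biplot_coords()].
#' @param file Output path.
#' @export
write_biplot <- function(coords, file) {
  utils::write.table(coords, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Export a colored GO subgraph in DOT format
#'
#' Renders the subgraph induced by the union of grouped and enriched
#' terms plus all their ancestors. Terms found only by group extraction
#' are blue, terms found only by the enrichment test are orange, terms
#' found by both are red, and connecting ancestors are grey.
#'
#' @param ontology A `go_ontology`.
#' @param group_terms Character vector of term ids from group extraction.
#' @param enriched_terms Character vector of term ids from the
#'   hypergeometric test.
#' @param file Output path.
#' @param relations Relation subset used to pull in ancestors.
#' @export
write_dot <- function(ontology, group_terms, enriched_terms, file,
                      relations = DEFAULT_RELATIONS) {
  base <- union(group_terms, enriched_terms)
  base <- intersect(base, ontology$terms$id)
  anc <- ancestor_closure(ontology, relations)
  ids <- ontology$terms$id
  idx <- seq_along(ids); names(idx) <- ids
  keep <- unique(c(idx[base],
                   unlist(anc[idx[base]], use.names = FALSE)))
  keep_ids <- ids[sort(keep)]
  color_of <- function(t) {
    ing <- t %in% group_terms; ine <- t %in% enriched_terms
    if (ing && ine) "red" else if (ing) "blue"
    else if (ine) "orange" else "grey"
  }
  con <- file(file, "w"); on.exit(close(con))
  writeLines("digraph ontology {", con)
  writeLines("  rankdir=BT;", con)
  nm <- stats::setNames(ontology$terms$name, ontology$terms$id)
  for (t in keep_ids)
    writeLines(sprintf(
      "  \"%s\" [label=\"%s\\n%s\", style=filled, fillcolor=%s];",
      t, t, nm[[t]], color_of(t)), con)
  e <- ontology$edges[ontology$edges$relation %in% relations, , drop = FALSE]
  e <- e[e$child %in% keep_ids & e$parent %in% keep_ids, , drop = FALSE]
  for (i in seq_len(nrow(e)))
    writeLines(sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                       e$child[i], e$parent[i], e$relation[i]), con)
  writeLines("}", con)
  invisible(file)
}

#' Write enrichment results as TSV
#' @param results data.frame from [go_enrichment()].
#' @param file Output path.
#' @param ontology Optional `go_ontology` used to add term names.
#' @export
write_enrichment <- function(results, file, ontology = NULL) {
  if (!is.null(ontology)) {
    nm <- stats::setNames(ontology$terms$name, ontology$terms$id)
    results <- cbind(results[, "term", drop = FALSE],
                     name = unname(nm[results$term]),
                     results[, setdiff(names(results), "term"),
                             drop = FALSE])
  }
  utils::write.table(results, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
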