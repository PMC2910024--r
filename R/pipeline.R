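#' Full fraction analysis pipeline
#'
#' Runs the whole analysis on parsed inputs: assigns proteins to fractions
#' from abundance ratios, propagates annotation counts per dataset and for
#' the background corpus, computes representation scores, builds the
#' log2-transformed score matrix (choosing the absence placeholder by
#' group separation when `placeholder = "auto"`), fits the PCA, and
#' extracts labeled term groups plus the dataset-by-component contribution
#' table.
#'
#' @param ontology A `go_ontology`.
#' @param corpus An `annotation_corpus` (the background universe).
#' @param abundance Protein x fraction intensity matrix.
#' @param margins Pairwise fraction margins, see [assign_fractions()].
#' @param assignment_method `"ratio"` or `"share"`.
#' @param variant Score variant, see [rep_score()].
#' @param placeholder Numeric fixed placeholder, or `"auto"` to select one
#'   with [choose_placeholder()].
#' @param grid Candidate grid for the automatic placeholder.
#' @param cosine_threshold,magnitude_quantile,components Group-extraction
#'   tunables, see [extract_term_groups()].
#' @param relations Relation subset for true-path propagation.
#' @return A `go_fraction_analysis` list: `assignment`, `background_counts`,
#'   `dataset_counts`, `scores`, `placeholder`, `matrix`, `model`,
#'   `contribution`, `groups`.
#' @export
analyze_fractions <- function(ontology, corpus, abundance, margins = NULL,
                              assignment_method = "ratio",
                              variant = "bounded", placeholder = "auto",
                              grid = seq(-10, -30, by = -1),
                              cosine_threshold = 0.8,
                              magnitude_quantile = 0.5,
                              components = NULL,
                              relations = DEFAULT_RELATIONS) {
  assignment <- assign_fractions(abundance, margins = margins,
                                 method = assignment_method)
  background_counts <- propagate_counts(ontology, corpus,
                                        relations = relations)
  counts <- dataset_counts(ontology, corpus, assignment,
                           relations = relations)
  counts <- Filter(function(ci) ci$total >= 1L, counts)
  if (length(counts) < 2)
    stop("need at least 2 non-empty datasets for PCA")
  scores <- lapply(counts, function(ci)
    score_dataset(ontology, background_counts, ci, variant = variant))
  if (identical(placeholder, "auto")) {
    placeholder <- choose_placeholder(scores, grid = grid,
                                      cosine_threshold = cosine_threshold,
                                      magnitude_quantile = magnitude_quantile,
                                      components = components)
  }
  sm <- score_matrix(scores, placeholder = as.numeric(placeholder))
  model <- go_pca(sm)
  comps <- if (is.null(components)) seq(2, ncol(model$loadings)) else components
  groups <- extract_term_groups(model, sm,
                                cosine_threshold = cosine_threshold,
                                magnitude_quantile = magnitude_quantile,
                                components = comps)
  structure(list(assignment = assignment,
                 background_counts = background_counts,
                 dataset_counts = counts,
                 scores = scores,
                 placeholder = as.numeric(placeholder),
                 matrix = sm,
                 model = model,
                 contribution = contribution_table(model),
                 groups = groups),
            class = "go_fraction_analysis")
}

#' @export
print.go_fraction_analysis <- function(x, ...) {
  cat("go_fraction_analysis\n")
  cat("  datasets:", paste(names(x$dataset_counts), collapse = ", "), "\n")
  tot <- vapply(x$dataset_counts, function(ci) ci$total, 0L)
  cat("  annotated proteins per dataset:",
      paste(sprintf("%s=%d", names(tot), tot), collapse = ", "), "\n")
  cat("  background proteins:", x$background_counts$total, "\n")
  cat("  score matrix:", nrow(x$matrix$values), "terms x",
      ncol(x$matrix$values), "datasets, placeholder", x$placeholder, "\n")
  cat("  eigenvalues:",
      paste(signif(x$model$eigenvalues, 4), collapse = " "), "\n")
  cg <- count_term_groups(x$groups)
  cat("  groups:\n")
  for (i in seq_len(nrow(cg)))
    cat(sprintf("    %-28s %d\n", cg$label[i], cg$n[i]))
  invisible(x)
}

#' Enrichment comparison per clean fraction
#'
#' Mirrors the comparison protocol against p-value based enrichment
#' analysis: for every fraction label of the assignment (excluding
#' `"non-specific"`), tests the fraction's protein list against the full
#' detected protein background with the hypergeometric test, and reports
#' the Pearson correlation between `100 * R` and `-log10(p_raw)` over the
#' shared terms.
#'
#' @param ontology A `go_ontology`.
#' @param corpus An `annotation_corpus`.
#' @param analysis A `go_fraction_analysis` from [analyze_fractions()].
#' @param alpha Significance level.
#' @param terms Optional term subset (e.g. planted signature terms) to
#'   restrict each correlation to.
#' @return Named list per fraction: list with `enrichment` (data.frame)
#'   and `correlation` (numeric or `NA` when degenerate).
#' @export
compare_enrichment <- function(ontology, corpus, analysis, alpha = 0.05,
                               terms = NULL) {
  assignment <- analysis$assignment
  background <- names(assignment)
  fractions <- setdiff(sort(unique(assignment)), "non-specific")
  out <- lapply(fractions, function(f) {
    target <- names(assignment)[assignment == f]
    enr <- go_enrichment(ontology, corpus, target, background, alpha = alpha)
    corr <- tryCatch(
      score_pvalue_correlation(analysis$scores[[f]], enr, terms = terms),
      error = function(e) NA_real_)
    list(enrichment = enr, correlation = corr)
  })
  stats::setNames(out, fractions)
}
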