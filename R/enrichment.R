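#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`: the probability of
#' drawing at least `k` annotated proteins in a target list of size `n`
#' sampled without replacement from a background of `M` proteins of which
#' `K` carry the annotation. The convention includes `k` itself, matching
#' standard over-representation practice.
#'
#' @param k Observed hits in the target.
#' @param n Target size.
#' @param K Background hits.
#' @param M Background size.
#' @return Probability in `(0, 1]`; exactly 1 when `k = 0`.
#' @export
hyper_pvalue <- function(k, n, K, M) {
  if (any(k < 0) || any(k > n) || any(n > M) || any(K > M) || any(k > K))
    stop("hypergeometric bounds violated (need k <= n <= M, k <= K <= M)")
  stats::phyper(k - 1, m = K, n = M - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; monotone, capped at 1, with
#' the original order restored.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p <= 0) || any(p > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Hypergeometric over-representation test per GO term
#'
#' For every term reached by at least one background protein under
#' true-path propagation, tests whether the target protein list hits the
#' term more often than expected from the background.
#'
#' @param ontology A `go_ontology`.
#' @param corpus An `annotation_corpus`.
#' @param target Character vector of target protein ids; must be a subset
#'   of `background`.
#' @param background Character vector of background protein ids.
#' @param alpha Significance level applied to the adjusted values.
#' @param adjust Adjustment method, see [adjust_pvalues()].
#' @param relations Relation subset used for propagation.
#' @return data.frame with columns `term`, `k`, `n`, `K`, `M`, `p_raw`,
#'   `p_adj`, `significant`, sorted by `p_adj` then term id.
#' @export
go_enrichment <- function(ontology, corpus, target, background,
                          alpha = 0.05, adjust = "BH",
                          relations = DEFAULT_RELATIONS) {
  if (!length(target)) stop("target protein set is empty")
  extra <- setdiff(target, background)
  if (length(extra))
    stop("target must be a subset of the background (",
         length(extra), " protein(s) outside it)")
  cnt_t <- propagate_counts(ontology, corpus, proteins = target,
                            relations = relations)
  cnt_b <- propagate_counts(ontology, corpus, proteins = background,
                            relations = relations)
  keep <- cnt_b$counts >= 1L
  terms <- names(cnt_b$counts)[keep]
  K <- cnt_b$counts[keep]
  k <- cnt_t$counts[terms]
  n <- cnt_t$total
  M <- cnt_b$total
  p_raw <- hyper_pvalue(k, n, K, M)
  p_adj <- adjust_pvalues(p_raw, method = adjust)
  out <- data.frame(term = terms, k = as.integer(k), n = n,
                    K = as.integer(K), M = M,
                    p_raw = unname(p_raw), p_adj = unname(p_adj),
                    significant = unname(p_adj) <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_adj, out$term), , drop = FALSE]
}

#' Correlation between representation scores and enrichment p-values
#'
#' Pearson correlation between `scale * R` and `-log10(p)` over the terms
#' shared by a dataset's scores and an enrichment result. The scores are
#' pre-scaled (default factor 100) so both axes have comparable orders of
#' magnitude. Raw p-values are used by default.
#'
#' @param scores A `term_scores` data.frame.
#' @param results An enrichment data.frame from [go_enrichment()].
#' @param scale Pre-scaling factor applied to R.
#' @param use_adjusted Use `p_adj` instead of `p_raw`.
#' @param terms Optional term subset to restrict the comparison to.
#' @return Pearson correlation coefficient.
#' @export
score_pvalue_correlation <- function(scores, results, scale = 100,
                                     use_adjusted = FALSE, terms = NULL) {
  shared <- intersect(scores$term, results$term)
  if (!is.null(terms)) shared <- intersect(shared, terms)
  if (length(shared) < 3)
    stop("need at least 3 shared terms, got ", length(shared))
  r <- scale * scores$r[match(shared, scores$term)]
  p <- results[[if (use_adjusted) "p_adj" else "p_raw"]][
    match(shared, results$term)]
  lp <- -log10(p)
  if (stats::sd(r) == 0 || stats::sd(lp) == 0)
    stop("degenerate input: constant scores or p-values among shared terms")
  stats::cor(r, lp)
}
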