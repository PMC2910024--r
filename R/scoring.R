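#' Representation score for a GO term in one dataset
#'
#' Combines the experimental relative frequency of a term with a background
#' normalisation. With `x` experiment proteins out of `n_exp` reaching the
#' term and `y` background proteins out of `m_goa`:
#'
#' * variant `"bounded"` (default): `r = (x/n_exp)^2 * sqrt(y/m_goa)`,
#'   guaranteed in `[0, 1]`. The squared first factor expands the
#'   distribution of relative frequencies; the square-rooted second factor
#'   down-weights the background normalisation because the experiment is a
#'   small subset of the annotated universe. Under this variant the score
#'   is monotone non-increasing from the root toward the leaves, so more
#'   specific terms score lower.
#' * variant `"reciprocal"`: `r = (x/n_exp)^2 * sqrt(m_goa/y)`, the literal
#'   reciprocal background frequency; [score_dataset()] rescales it onto
#'   `[0, 1]` by dividing by the dataset maximum.
#'
#' @param x Experiment count(s), `0 <= x <= n_exp`.
#' @param n_exp Experiment total (distinct annotated proteins), `>= 1`.
#' @param y Background count(s), `1 <= y <= m_goa`.
#' @param m_goa Background total.
#' @param variant `"bounded"` or `"reciprocal"`.
#' @return Numeric vector of scores.
#' @examples
#' rep_score(2, 10, 4, 100)                        # 0.008
#' rep_score(2, 10, 4, 100, variant = "reciprocal") # 0.2
#' @export
rep_score <- function(x, n_exp, y, m_goa, variant = c("bounded", "reciprocal")) {
  variant <- match.arg(variant)
  if (any(y == 0)) stop("y = 0: term absent from background cannot be scored")
  if (any(x > n_exp)) stop("x exceeds n_exp")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (n_exp < 1) stop("n_exp must be >= 1")
  if (any(y > m_goa)) stop("y exceeds m_goa")
  f1 <- (x / n_exp)^2
  if (variant == "bounded") f1 * sqrt(y / m_goa) else f1 * sqrt(m_goa / y)
}

#' Score every background term for one dataset
#'
#' Computes one representation score per term with background count >= 1,
#' from propagated experiment and background count indices.
#'
#' @param ontology A `go_ontology`.
#' @param background `term_counts` for the annotation background (y, M).
#' @param experiment `term_counts` for the dataset (x, N).
#' @param variant Score variant, see [rep_score()]. The reciprocal variant
#'   is rescaled onto `[0, 1]` by its dataset maximum.
#' @return A `term_scores` data.frame with columns `term`, `x`, `y`,
#'   `n_exp`, `m_goa`, `r`, `log_r` (`log2(r)` where `x > 0`, `NA`
#'   otherwise), ordered by term id.
#' @export
score_dataset <- function(ontology, background, experiment,
                          variant = c("bounded", "reciprocal")) {
  variant <- match.arg(variant)
  if (background$total == 0L) stop("background total is 0")
  if (experiment$total < 1L) stop("experiment total must be >= 1")
  keep <- background$counts >= 1L
  terms <- names(background$counts)[keep]
  terms <- sort(terms)
  y <- background$counts[terms]
  x <- experiment$counts[terms]
  x[is.na(x)] <- 0L
  r <- rep_score(x, experiment$total, y, background$total, variant = variant)
  if (variant == "reciprocal" && max(r) > 0) r <- r / max(r)
  out <- data.frame(term = terms,
                    x = as.integer(x), y = as.integer(y),
                    n_exp = experiment$total, m_goa = background$total,
                    r = unname(r),
                    log_r = ifelse(x > 0, log2(unname(r)), NA_real_),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("term_scores", "data.frame")
  attr(out, "variant") <- variant
  out
}

#' Build the term-by-dataset score matrix for PCA
#'
#' Rows are the terms represented (`x > 0`) in at least one dataset; under
#' true-path propagation this row set is closed under taking ancestors.
#' Cells hold `log2(r)` where the term is present and a finite placeholder
#' where it is absent (`x = 0`), avoiding the log-zero problem; the absence
#' pattern is kept as a mask. Rows and columns are ordered lexically.
#'
#' @param scores Named list of `term_scores`, one per dataset.
#' @param placeholder Finite value for absent cells; must be strictly below
#'   every finite `log2(r)` in the matrix.
#' @return A `score_matrix`: list with `values` (numeric matrix), `mask`
#'   (logical matrix, `TRUE` where absent), `placeholder`, and later the
#'   standardisation parameters.
#' @export
score_matrix <- function(scores, placeholder = -10) {
  stopifnot(is.list(scores), length(scores) >= 1, !is.null(names(scores)))
  datasets <- sort(names(scores))
  present_terms <- sort(unique(unlist(
    lapply(scores, function(s) s$term[s$x > 0]), use.names = FALSE)))
  if (!length(present_terms)) stop("no term is present in any dataset")
  values <- matrix(placeholder, nrow = length(present_terms),
                   ncol = length(datasets),
                   dimnames = list(present_terms, datasets))
  mask <- matrix(TRUE, nrow = length(present_terms), ncol = length(datasets),
                 dimnames = list(present_terms, datasets))
  for (d in datasets) {
    s <- scores[[d]]
    pres <- s$x > 0 & s$term %in% present_terms
    values[s$term[pres], d] <- s$log_r[pres]
    mask[s$term[pres], d] <- FALSE
  }
  finite_min <- min(values[!mask])
  if (length(values[!mask]) && placeholder >= finite_min)
    stop("placeholder (", placeholder, ") must be below the minimum finite ",
         "log2 score (", signif(finite_min, 6), ")")
  structure(list(values = values, mask = mask, placeholder = placeholder,
                 standardized = FALSE, center = NULL, scale = NULL),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x$values), "terms x", ncol(x$values),
      "datasets; placeholder", x$placeholder,
      if (isTRUE(x$standardized)) "(standardized)" else "", "\n")
  invisible(x)
}

#' Select the absence placeholder by group separation
#'
#' Varies the placeholder over a descending grid starting at -10 and keeps
#' the candidate whose downstream group assignment separates best in the
#' PC2/PC3 plane, measured as the mean silhouette width over all terms
#' with the group labels (including the unassigned class) as the
#' clustering. Candidates that are not strictly below the minimum finite
#' `log2(r)` violate the matrix precondition and are skipped. Ties keep
#' the candidate closest to -10 (grid order).
#'
#' @param scores Named list of `term_scores`, one per dataset.
#' @param grid Strictly descending candidate values.
#' @param cosine_threshold,magnitude_quantile,components Passed to
#'   [extract_term_groups()].
#' @return The selected placeholder, with the per-candidate criterion in
#'   attribute `"criterion"`. If no candidate yields more than one group,
#'   returns -10 with a warning; if the whole grid is invalid, returns
#'   `floor(min finite) - 1` with a warning.
#' @export
choose_placeholder <- function(scores, grid = seq(-10, -30, by = -1),
                               cosine_threshold = 0.8,
                               magnitude_quantile = 0.5,
                               components = NULL) {
  stopifnot(length(grid) >= 1, all(diff(grid) < 0))
  finite_min <- min(unlist(lapply(scores, function(s) s$log_r),
                           use.names = FALSE), na.rm = TRUE)
  crit <- rep(NA_real_, length(grid))
  names(crit) <- as.character(grid)
  for (i in seq_along(grid)) {
    cand <- grid[i]
    if (cand >= finite_min) next
    sm <- score_matrix(scores, placeholder = cand)
    if (nrow(sm$values) < 3 || ncol(sm$values) < 3) next
    model <- try(go_pca(sm), silent = TRUE)
    if (inherits(model, "try-error")) next
    comps <- if (is.null(components)) seq(2, ncol(model$loadings)) else components
    groups <- extract_term_groups(model, sm,
                                  cosine_threshold = cosine_threshold,
                                  magnitude_quantile = magnitude_quantile,
                                  components = comps)
    if (length(unique(groups$label)) < 2 ||
        sum(groups$label != "unassigned") < 3) next
    coords <- model$scores[groups$term, c(2, 3), drop = FALSE]
    sil <- cluster::silhouette(as.integer(factor(groups$label)),
                               stats::dist(coords))
    crit[i] <- mean(sil[, "sil_width"])
  }
  if (all(is.na(crit))) {
    if (all(grid >= finite_min)) {
      fallback <- floor(finite_min) - 1
      warning("no grid candidate lies below the minimum finite log2 score; ",
              "using ", fallback)
      return(structure(fallback, criterion = crit))
    }
    warning("no candidate yields more than one group; using -10")
    best <- if (-10 < finite_min) -10 else floor(finite_min) - 1
    return(structure(best, criterion = crit))
  }
  best <- grid[which.max(crit)]   # which.max takes the first (closest to -10)
  structure(best, criterion = crit)
}
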