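#' Standardize a score matrix
#'
#' Centers and scales every dataset column to mean 0 and sample variance 1
#' (divisor N-1), keeping the per-column means and standard deviations for
#' the PCA model.
#'
#' @param sm A `score_matrix`.
#' @return The standardized `score_matrix` with `center` and `scale` set.
#' @export
standardize_matrix <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"))
  if (isTRUE(sm$standardized)) return(sm)
  v <- sm$values
  ctr <- colMeans(v)
  sds <- apply(v, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance dataset column(s): ",
         paste(colnames(v)[zero], collapse = ", "))
  sm$values <- sweep(sweep(v, 2, ctr, "-"), 2, sds, "/")
  sm$center <- ctr
  sm$scale <- sds
  sm$standardized <- TRUE
  sm
}

#' Principal component analysis of the score matrix via SVD
#'
#' Runs PCA on the standardized term-by-dataset matrix: terms are the
#' observations (rows), datasets the variables (columns). The singular
#' value decomposition `X = U D V'` yields the loadings (columns of `V`,
#' unit-length eigenvectors of the sample covariance `S = X'X/(N-1)`),
#' eigenvalues `d^2/(N-1)` in descending order, and PC scores `X V`. The
#' eigenvector sign is fixed so each loading's largest-magnitude
#' coefficient is positive, making output reproducible across linear
#' algebra backends.
#'
#' @param sm A `score_matrix`; standardized automatically if it is not.
#' @return A `go_pca` model: `loadings` (dataset x component),
#'   `eigenvalues`, `scores` (term x component), `center`, `scale`,
#'   `n_rows`.
#' @export
go_pca <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"))
  if (nrow(sm$values) < 2) stop("need at least 2 rows for PCA")
  if (ncol(sm$values) < 2) stop("need at least 2 dataset columns for PCA")
  sm <- standardize_matrix(sm)
  x <- sm$values
  n <- nrow(x); p <- ncol(x)
  sv <- svd(x, nu = 0, nv = p)
  eig <- sv$d^2 / (n - 1)
  if (length(eig) < p) eig <- c(eig, rep(0, p - length(eig)))
  load <- sv$v
  for (j in seq_len(p)) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  comp <- paste0("PC", seq_len(p))
  dimnames(load) <- list(colnames(x), comp)
  scores <- x %*% load
  dimnames(scores) <- list(rownames(x), comp)
  structure(list(loadings = load, eigenvalues = stats::setNames(eig, comp),
                 scores = scores, center = sm$center, scale = sm$scale,
                 n_rows = n),
            class = "go_pca")
}

#' @export
print.go_pca <- function(x, ...) {
  cat("go_pca:", x$n_rows, "terms,", ncol(x$loadings), "components\n")
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' Share of each dataset's variance carried by each component
#'
#' Entry (f, k) is `100 * a_fk^2 * lambda_k / sum_j a_fj^2 * lambda_j`: the
#' percentage of variable f's variance explained by component k, i.e. the
#' squared correlation between the (standardized) dataset variable and the
#' PC. Every row sums to 100 up to rank deficiency.
#'
#' @param model A `go_pca` model.
#' @return Numeric matrix (dataset x component) of percentages.
#' @export
contribution_table <- function(model) {
  stopifnot(inherits(model, "go_pca"))
  a2l <- sweep(model$loadings^2, 2, model$eigenvalues, "*")
  100 * a2l / rowSums(a2l)
}

#' Extract labeled groups of terms from PC coordinates
#'
#' Associates each term with the dataset(s) whose loading direction its PC
#' score vector follows. Both vectors are restricted to the selected
#' components (PC1 is excluded by default because it encodes term
#' specificity, not dataset identity). Terms whose restricted score
#' magnitude falls below the `magnitude_quantile` of all magnitudes are
#' `"unassigned"`; otherwise a term receives every dataset label whose
#' restricted loading has cosine similarity at or above
#' `cosine_threshold` with the term's vector. One label gives a clean
#' group; two or more give a mixed group labeled by the sorted label set
#' joined with `"+"`; none gives `"unassigned"`.
#'
#' @param model A `go_pca` model.
#' @param sm The (standardized or raw) `score_matrix` the model was fitted
#'   on; used to order group members by decreasing score in the label's
#'   first dataset.
#' @param cosine_threshold Cosine similarity threshold in `(0, 1]`.
#' @param magnitude_quantile Quantile in `(0, 1]` below which terms are
#'   unassigned.
#' @param components Integer components to use; default `2:p`.
#' @param method `"cosine"` (default) as described above; `"kmeans"` runs
#'   k-means on the restricted scores with one center per dataset and
#'   labels each cluster by the loading nearest its centroid.
#' @return A `term_groups` data.frame with columns `label`, `term`,
#'   `rank`, `score`; rows ordered by label (clean, mixed, unassigned)
#'   and within a label by decreasing score.
#' @export
extract_term_groups <- function(model, sm, cosine_threshold = 0.8,
                                magnitude_quantile = 0.5, components = NULL,
                                method = c("cosine", "kmeans")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "go_pca"))
  p <- ncol(model$loadings)
  if (is.null(components)) components <- seq(2, p)
  if (any(components < 1) || any(components > p))
    stop("components outside model rank 1..", p)
  if (cosine_threshold <= 0 || cosine_threshold > 1)
    stop("cosine_threshold must be in (0, 1]")
  if (magnitude_quantile <= 0 || magnitude_quantile > 1)
    stop("magnitude_quantile must be in (0, 1]")

  s <- model$scores[, components, drop = FALSE]
  l <- model$loadings[, components, drop = FALSE]
  mags <- sqrt(rowSums(s^2))
  thr <- stats::quantile(mags, magnitude_quantile, names = FALSE)
  lnorm <- sqrt(rowSums(l^2))
  lu <- l / pmax(lnorm, .Machine$double.eps)

  labels <- character(nrow(s))
  if (method == "cosine") {
    su <- s / pmax(mags, .Machine$double.eps)
    cosim <- su %*% t(lu)                       # term x dataset cosines
    cosim[, lnorm == 0] <- -Inf   # dataset absent from these components
    cosim[is.na(cosim)] <- -Inf
    for (i in seq_len(nrow(s))) {
      if (mags[i] < thr) { labels[i] <- "unassigned"; next }
      hits <- colnames(cosim)[cosim[i, ] >= cosine_threshold]
      labels[i] <- if (length(hits)) paste(sort(hits), collapse = "+")
                   else "unassigned"
    }
  } else {
    keep <- mags >= thr
    labels[!keep] <- "unassigned"
    if (sum(keep) >= nrow(l)) {
      km <- stats::kmeans(s[keep, , drop = FALSE], centers = nrow(l),
                          nstart = 5)
      cen <- km$centers / sqrt(rowSums(km$centers^2))
      nearest <- apply(cen %*% t(lu), 1, which.max)
      labels[keep] <- rownames(l)[nearest[km$cluster]]
    } else labels[keep] <- "unassigned"
  }
  names(labels) <- rownames(s)

  first_dataset <- function(lab) strsplit(lab, "+", fixed = TRUE)[[1]][1]
  mat <- if (inherits(sm, "score_matrix")) sm$values else as.matrix(sm)

  ulabs <- unique(labels)
  clean <- sort(ulabs[!grepl("+", ulabs, fixed = TRUE) & ulabs != "unassigned"])
  mixed <- sort(ulabs[grepl("+", ulabs, fixed = TRUE)])
  ordered_labels <- c(clean, mixed, intersect("unassigned", ulabs))

  rows <- lapply(ordered_labels, function(lab) {
    members <- names(labels)[labels == lab]
    if (lab == "unassigned") {
      members <- sort(members)
      sc <- rep(NA_real_, length(members))
    } else {
      d <- first_dataset(lab)
      sc <- mat[members, d]
      o <- order(-sc, members)
      members <- members[o]; sc <- unname(sc[o])
    }
    data.frame(label = lab, term = members, rank = seq_along(members),
               score = sc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("term_groups", "data.frame")
  attr(out, "components") <- components
  out
}

#' Tally group sizes
#'
#' @param groups A `term_groups` data.frame.
#' @return data.frame with columns `label`, `n`; clean labels first, then
#'   mixed, then `"unassigned"`.
#' @export
count_term_groups <- function(groups) {
  if (!nrow(groups))
    return(data.frame(label = character(), n = integer(),
                      stringsAsFactors = FALSE))
  labs <- unique(groups$label)   # already ordered clean, mixed, unassigned
  data.frame(label = labs,
             n = vapply(labs, function(l) sum(groups$label == l), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Upper bound on the number of group categories
#'
#' For `k` datasets and groups that are either clean (one dataset) or
#' mixed pairs: the `"ordered"` convention counts ordered pairs,
#' `k * (k - 1)` (for four fractions, 12); the `"unordered"` convention
#' counts the labels the extraction rule can actually emit for
#' pair-limited mixing, `k + k * (k - 1) / 2` clean-plus-unordered-pair
#' labels (for four fractions, 10).
#'
#' @param k Number of datasets, `>= 2`.
#' @param convention `"ordered"` or `"unordered"`.
#' @return Integer count.
#' @examples
#' group_label_bound(4, "ordered")    # 12
#' group_label_bound(4, "unordered")  # 10
#' @export
group_label_bound <- function(k, convention = c("ordered", "unordered")) {
  convention <- match.arg(convention)
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k))
    stop("k must be an integer >= 2")
  k <- as.integer(k)
  if (convention == "ordered") k * (k - 1L) else k + (k * (k - 1L)) %/% 2L
}

#' Bi-plot coordinates for a component pair
#'
#' Term PC scores together with dataset loadings for components `i` and
#' `j`; loadings are scaled by `sqrt(lambda)` for display (flagged by the
#' `display_scaled` column).
#'
#' @param model A `go_pca` model.
#' @param i,j Distinct component indices within the model rank.
#' @return data.frame with columns `id`, `kind` (`"score"`/`"loading"`),
#'   `coord_i`, `coord_j`, `display_scaled`.
#' @export
biplot_coords <- function(model, i = 1, j = 2) {
  stopifnot(inherits(model, "go_pca"))
  p <- ncol(model$loadings)
  if (i == j) stop("components i and j must differ")
  if (any(c(i, j) < 1) || any(c(i, j) > p))
    stop("component out of range 1..", p)
  sc <- data.frame(id = rownames(model$scores), kind = "score",
                   coord_i = unname(model$scores[, i]),
                   coord_j = unname(model$scores[, j]),
                   display_scaled = FALSE, stringsAsFactors = FALSE)
  sc <- sc[order(sc$id), ]
  ld <- data.frame(id = rownames(model$loadings), kind = "loading",
                   coord_i = unname(model$loadings[, i]) *
                     sqrt(model$eigenvalues[i]),
                   coord_j = unname(model$loadings[, j]) *
                     sqrt(model$eigenvalues[j]),
                   display_scaled = TRUE, stringsAsFactors = FALSE)
  ld <- ld[order(ld$id), ]
  out <- rbind(sc, ld)
  rownames(out) <- NULL
  out
}
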