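make_sm <- function(values) {
  structure(list(values = values,
                 mask = matrix(FALSE, nrow(values), ncol(values),
                               dimnames = dimnames(values)),
                 placeholder = -10, standardized = FALSE,
                 center = NULL, scale = NULL),
            class = "score_matrix")
}

random_sm <- function(n, p, seed) {
  set.seed(seed)
  make_sm(matrix(rnorm(n * p), n, p,
                 dimnames = list(sprintf("GO:%07d", seq_len(n)),
                                 sprintf("d%d", seq_len(p)))))
}

test_that("standardization centres and scales with divisor N-1", {
  sm <- make_sm(cbind(d1 = c(1, 2, 3), d2 = c(5, 1, 0)))
  rownames(sm$values) <- c("t1", "t2", "t3")
  sm$mask <- matrix(FALSE, 3, 2, dimnames = dimnames(sm$values))
  std <- standardize_matrix(sm)
  expect_equal(unname(std$values[, "d1"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(std$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(std$values, 2, var)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(std$center), c(2, 2))

  smz <- make_sm(cbind(d1 = c(1, 2, 3), flatset = c(1, 1, 1)))
  expect_error(standardize_matrix(smz), "flatset")
})

test_that("PCA recovers exact structure of constructed matrices", {
  # two identical columns: lambda = {2, 0}, first loading (1,1)/sqrt(2)
  x <- rnorm(20)
  sm <- make_sm(cbind(d1 = x, d2 = x))
  rownames(sm$values) <- sprintf("t%02d", 1:20)
  model <- go_pca(sm)
  expect_equal(unname(model$eigenvalues), c(2, 0), tolerance = 1e-10)
  expect_equal(unname(model$loadings[, 1]), c(1, 1) / sqrt(2),
               tolerance = 1e-10)

  # two orthogonally constructed columns: lambda = {1, 1}
  a <- scale(rnorm(21))[, 1]
  b <- scale(residuals(lm(rnorm(21) ~ a)))[, 1]
  sm2 <- make_sm(cbind(d1 = a, d2 = b))
  rownames(sm2$values) <- sprintf("t%02d", 1:21)
  expect_equal(unname(go_pca(sm2)$eigenvalues), c(1, 1), tolerance = 1e-10)

  expect_error(go_pca(make_sm(matrix(1:2, 1, 2))), "at least 2 rows")
})

test_that("PCA matches an independent covariance eigendecomposition", {
  for (seed in 1:5) {
    sm <- random_sm(20, 4, seed)
    model <- go_pca(sm)
    z <- scale(sm$values)
    eig <- eigen(cov(z), symmetric = TRUE)
    expect_equal(unname(model$eigenvalues), eig$values, tolerance = 1e-8)
    for (j in 1:4) {
      v <- eig$vectors[, j]
      if (v[which.max(abs(v))] < 0) v <- -v
      expect_equal(unname(model$loadings[, j]), v, tolerance = 1e-8)
    }
    # reconstruction at full rank
    expect_equal(model$scores %*% t(model$loadings), z,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("contribution table is the squared-correlation share", {
  # rank-1 matrix: every variable fully explained by PC1
  x <- rnorm(15)
  sm <- make_sm(cbind(d1 = x, d2 = 2 * x, d3 = -x))
  rownames(sm$values) <- sprintf("t%02d", 1:15)
  ct <- contribution_table(go_pca(sm))
  expect_equal(unname(ct[, 1]), rep(100, 3), tolerance = 1e-8)

  for (seed in 6:8) {
    sm <- random_sm(20, 4, seed)
    model <- go_pca(sm)
    ct <- contribution_table(model)
    expect_equal(unname(rowSums(ct)), rep(100, 4), tolerance = 0.1)
    # oracle: squared Pearson correlation between variable and PC score
    z <- scale(sm$values)
    for (f in 1:4) for (k in 1:4)
      expect_equal(ct[f, k], 100 * cor(z[, f], model$scores[, k])^2,
                   tolerance = 1e-6)
  }
})

test_that("cosine rule labels terms by loading alignment", {
  # constructed 3-component model with axis-aligned loadings
  loadings <- diag(3)
  dimnames(loadings) <- list(c("A", "B", "C"), paste0("PC", 1:3))
  scores <- rbind(
    t1 = c(0, 5, 0),            # exactly along B in PC2/PC3 space
    t2 = c(0, 0, 4),            # exactly along C
    t3 = c(0, 3, 3),            # bisecting B and C (cosine ~0.707 < 0.8)
    t4 = c(0, 0.01, 0.01),      # tiny magnitude
    t5 = c(0, 4, 0.5))
  colnames(scores) <- paste0("PC", 1:3)
  model <- structure(list(loadings = loadings,
                          eigenvalues = c(PC1 = 2, PC2 = 1, PC3 = 0.5),
                          scores = scores, center = c(A = 0, B = 0, C = 0),
                          scale = c(A = 1, B = 1, C = 1), n_rows = 5),
                     class = "go_pca")
  vals <- matrix(-seq_len(15), 5, 3,
                 dimnames = list(rownames(scores), c("A", "B", "C")))
  groups <- extract_term_groups(model, make_sm(vals),
                                magnitude_quantile = 0.2)
  lab <- stats::setNames(groups$label, groups$term)
  expect_equal(unname(lab["t1"]), "B")
  expect_equal(unname(lab["t2"]), "C")
  expect_equal(unname(lab["t4"]), "unassigned")
  expect_equal(unname(lab["t5"]), "B")
  # the bisecting term joins both groups once the cone is wide enough
  groups2 <- extract_term_groups(model, make_sm(vals),
                                 cosine_threshold = 0.7,
                                 magnitude_quantile = 0.2)
  lab2 <- stats::setNames(groups2$label, groups2$term)
  expect_equal(unname(lab2["t3"]), "B+C")

  expect_error(extract_term_groups(model, make_sm(vals), components = 4),
               "components outside")
})

test_that("group extraction is invariant to row permutation and sorts
           members by decreasing score", {
  study <- synthetic_study(1)
  model <- study$analysis$model
  sm <- study$analysis$matrix
  g1 <- extract_term_groups(model, sm)
  perm <- sample(nrow(model$scores))
  model2 <- model
  model2$scores <- model$scores[perm, , drop = FALSE]
  g2 <- extract_term_groups(model2, sm)
  expect_equal(g1, g2, ignore_attr = TRUE)
  # rank order within each labeled group follows the matrix values
  for (lab in setdiff(unique(g1$label), "unassigned")) {
    sub <- g1[g1$label == lab, ]
    expect_false(is.unsorted(rev(sub$score)))
    expect_equal(sub$rank, seq_len(nrow(sub)))
  }
})

test_that("group tallies and label bounds are correct", {
  g <- data.frame(label = rep(c("a", "b", "c"), times = c(2, 3, 4)),
                  term = sprintf("t%d", 1:9), rank = 1, score = 1)
  class(g) <- c("term_groups", "data.frame")
  expect_equal(count_term_groups(g)$n, c(2L, 3L, 4L))
  expect_equal(nrow(count_term_groups(g[0, ])), 0L)

  expect_equal(group_label_bound(4, "ordered"), 12L)
  expect_equal(group_label_bound(4, "unordered"), 10L)
  expect_equal(group_label_bound(2, "ordered"), 2L)
  expect_error(group_label_bound(1), "k must be")
})

test_that("biplot coordinates expose scores and sqrt-eigenvalue loadings", {
  sm <- random_sm(20, 4, 42)
  model <- go_pca(sm)
  bp <- biplot_coords(model, 1, 2)
  expect_equal(sum(bp$kind == "loading"), 4L)
  sc <- bp[bp$kind == "score", ]
  expect_equal(sc$coord_i[match(rownames(model$scores), sc$id)],
               unname(model$scores[, 1]))
  ld <- bp[bp$kind == "loading", ]
  expect_equal(abs(ld$coord_i[match(rownames(model$loadings), ld$id)]),
               unname(sqrt(model$eigenvalues[1]) * abs(model$loadings[, 1])),
               tolerance = 1e-10)
  expect_true(all(ld$display_scaled))
  expect_error(biplot_coords(model, 2, 2), "must differ")
  expect_error(biplot_coords(model, 1, 9), "out of range")
})
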