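test_that("representation score matches hand-computed values", {
  expect_equal(rep_score(0, 10, 4, 100), 0)
  expect_equal(rep_score(0, 10, 4, 100, variant = "reciprocal"), 0)
  expect_equal(rep_score(10, 10, 100, 100), 1)      # x = n, y = M
  expect_equal(rep_score(2, 10, 4, 100), 0.008)
  expect_equal(rep_score(2, 10, 4, 100, variant = "reciprocal"), 0.2)
  expect_error(rep_score(1, 10, 0, 100), "y = 0")
  expect_error(rep_score(11, 10, 4, 100), "exceeds n_exp")
})

test_that("dataset scores agree with per-term single calls", {
  ont <- chain_ontology(3)
  background <- propagate_counts(ont, as_corpus(list(
    B1 = "GO:0000003", B2 = "GO:0000002", B3 = "GO:0000002",
    B4 = "GO:0000001", B5 = "GO:0000001")))
  experiment <- propagate_counts(ont, as_corpus(list(
    E1 = "GO:0000003", E2 = "GO:0000003")))
  sc <- score_dataset(ont, background, experiment)
  for (i in seq_len(nrow(sc))) {
    expect_equal(sc$r[i],
                 rep_score(sc$x[i], experiment$total, sc$y[i],
                           background$total))
  }
  # both factors maximal at the root when experiment equals background
  sc_bg <- score_dataset(ont, background, background)
  expect_equal(sc_bg$term[which.max(sc_bg$r)], "GO:0000001")
  # decreasing sort puts the most specific chain term last
  expect_equal(sc$term[order(-sc$r)][nrow(sc)], "GO:0000003")
})

test_that("bounded scores lie in [0,1], vanish iff absent, and are
           monotone along edges", {
  for (seed in 1:3) {
    dag <- random_test_dag(35, seed + 20)
    ont <- dag_to_ontology(dag)
    direct <- random_direct(dag, 25, seed + 30)
    background <- propagate_counts(ont, as_corpus(direct))
    experiment <- propagate_counts(ont, as_corpus(direct),
                                   proteins = names(direct)[1:8])
    sc <- score_dataset(ont, background, experiment)
    expect_true(all(sc$r >= 0 & sc$r <= 1))
    expect_equal(sc$r == 0, sc$x == 0)
    expect_equal(is.na(sc$log_r), sc$x == 0)
    r_of <- stats::setNames(sc$r, sc$term)
    scored_edges <- ont$edges[ont$edges$child %in% sc$term &
                                ont$edges$parent %in% sc$term, , drop = FALSE]
    for (i in seq_len(nrow(scored_edges)))
      expect_lte(r_of[[scored_edges$child[i]]], r_of[[scored_edges$parent[i]]])
  }
})

test_that("scores are invariant to duplicating the experiment and depend on
           the background only through its ratios", {
  ont <- chain_ontology(4)
  direct <- list(E1 = "GO:0000004", E2 = "GO:0000002", E3 = "GO:0000003")
  bg_direct <- c(direct, list(B1 = "GO:0000001", B2 = "GO:0000004"))
  background <- propagate_counts(ont, as_corpus(bg_direct))
  experiment <- propagate_counts(ont, as_corpus(direct))
  sc <- score_dataset(ont, background, experiment)

  doubled <- c(direct, stats::setNames(direct, paste0(names(direct), "x")))
  sc2 <- score_dataset(ont, background,
                       propagate_counts(ont, as_corpus(doubled)))
  expect_equal(sc$r, sc2$r)

  bg2 <- c(bg_direct, stats::setNames(bg_direct, paste0(names(bg_direct), "y")))
  sc3 <- score_dataset(ont, propagate_counts(ont, as_corpus(bg2)), experiment)
  expect_equal(sc$r, sc3$r)
})

test_that("reciprocal variant is rescaled onto [0,1]", {
  ont <- chain_ontology(4)
  background <- propagate_counts(ont, as_corpus(list(
    B1 = "GO:0000004", B2 = "GO:0000003", B3 = "GO:0000002",
    B4 = "GO:0000001")))
  experiment <- propagate_counts(ont, as_corpus(list(E1 = "GO:0000004")))
  sc <- score_dataset(ont, background, experiment, variant = "reciprocal")
  expect_true(all(sc$r >= 0 & sc$r <= 1))
  expect_equal(max(sc$r), 1)
  expect_equal(sc$r == 0, sc$x == 0)
})

test_that("score matrix holds log2 scores with a masked placeholder", {
  ont <- chain_ontology(4)
  bg <- propagate_counts(ont, as_corpus(list(
    B1 = "GO:0000004", B2 = "GO:0000003", B3 = "GO:0000002",
    B4 = "GO:0000001")))
  e1 <- propagate_counts(ont, as_corpus(list(P1 = "GO:0000004")))
  e2 <- propagate_counts(ont, as_corpus(list(P2 = "GO:0000003")))
  scores <- list(d1 = score_dataset(ont, bg, e1),
                 d2 = score_dataset(ont, bg, e2))
  sm <- score_matrix(scores, placeholder = -20)
  # d2 misses the deepest term only
  expect_equal(sum(sm$mask), 1L)
  expect_true(sm$mask["GO:0000004", "d2"])
  expect_equal(sm$values["GO:0000004", "d2"], -20)
  # cells are log2 of the score
  expect_equal(sm$values["GO:0000004", "d1"],
               log2(scores$d1$r[scores$d1$term == "GO:0000004"]))
  # r = 0.25 maps to cell -2
  expect_equal(unname(log2(0.25)), -2)
  # a placeholder at or above a finite score is rejected
  expect_error(score_matrix(scores, placeholder = -0.1), "placeholder")
})

test_that("rows of the matrix are closed under taking ancestors", {
  study <- synthetic_study(1)
  sm <- study$analysis$matrix
  ont <- study$ontology
  for (t in sample(rownames(sm$values), 20))
    expect_true(all(go_ancestors(ont, t) %in% rownames(sm$values)))
})

test_that("placeholder selection is deterministic and honours the grid", {
  ont <- chain_ontology(4)
  bg <- propagate_counts(ont, as_corpus(list(
    B1 = "GO:0000004", B2 = "GO:0000003", B3 = "GO:0000002",
    B4 = "GO:0000001")))
  e <- propagate_counts(ont, as_corpus(list(P1 = "GO:0000004")))
  scores3 <- list(d1 = score_dataset(ont, bg, e),
                  d2 = score_dataset(ont, bg, e),
                  d3 = score_dataset(ont, bg, e))
  # no masked cells anywhere: criterion is placeholder-free, keep -10
  expect_warning(ph <- choose_placeholder(scores3), "single group|using")
  expect_equal(as.numeric(ph), -10)
})

test_that("a one-candidate grid returns that candidate", {
  study <- synthetic_study(1)
  ph <- suppressWarnings(choose_placeholder(study$analysis$scores,
                                            grid = -28))
  expect_equal(as.numeric(ph), -28)
})

test_that("selected placeholder maximises the separation criterion", {
  study <- synthetic_study(1)
  scores <- study$analysis$scores
  ph <- choose_placeholder(scores)
  crit <- attr(ph, "criterion")
  expect_false(all(is.na(crit)))
  expect_equal(as.numeric(ph),
               as.numeric(names(crit)[which.max(crit)]))
  # identical on repeat evaluation
  expect_equal(as.numeric(choose_placeholder(scores)), as.numeric(ph))
})
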