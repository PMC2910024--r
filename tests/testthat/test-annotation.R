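test_that("read_gaf filters NOT qualifiers, deduplicates and selects aspect", {
  path <- write_gaf_rows(c(
    gaf_row("P1", "GO:0000001"),
    gaf_row("P1", "GO:0000001"),                      # duplicate
    gaf_row("P2", "GO:0000002", qualifier = "NOT|located_in"),
    gaf_row("P3", "GO:0000001")))
  corpus <- read_gaf(path)
  expect_equal(sort(names(corpus$direct)), c("P1", "P3"))
  expect_equal(corpus$direct$P1, "GO:0000001")

  # aspect filter keeps exactly the C rows of a mixed fixture
  rows <- c(gaf_row("P1", "GO:0000001", aspect = "C"),
            gaf_row("P2", "GO:0000002", aspect = "P"),
            gaf_row("P3", "GO:0000003", aspect = "F"),
            gaf_row("P4", "GO:0000004", aspect = "C"),
            gaf_row("P5", "GO:0000005", aspect = "P"))
  corpus <- read_gaf(write_gaf_rows(rows), namespace = "cellular_component")
  expect_equal(sort(names(corpus$direct)), c("P1", "P4"))
})

test_that("read_gaf warns on malformed rows and errors on empty input", {
  path <- write_gaf_rows(c(gaf_row("P1", "GO:0000001"), "too\tfew\tcolumns"))
  expect_warning(corpus <- read_gaf(path), "malformed")
  expect_equal(names(corpus$direct), "P1")
  expect_error(
    suppressWarnings(read_gaf(write_gaf_rows("too\tfew"))), "no usable rows")
})

test_that("propagated counts follow the true-path rule", {
  ont <- chain_ontology(3)
  corpus <- as_corpus(list(P1 = "GO:0000003"))
  idx <- propagate_counts(ont, corpus)
  expect_equal(unname(idx$counts[c("GO:0000001", "GO:0000002", "GO:0000003")]),
               c(1L, 1L, 1L))
  expect_equal(idx$total, 1L)

  # a protein annotated to both children of one parent counts once
  ont <- diamond_ontology()
  corpus <- as_corpus(list(P1 = c("GO:0000002", "GO:0000003")))
  idx <- propagate_counts(ont, corpus)
  expect_equal(unname(idx$counts["GO:0000001"]), 1L)
})

test_that("propagated counts equal the per-protein ancestor-union oracle", {
  for (seed in 1:3) {
    dag <- random_test_dag(40, seed)
    ont <- dag_to_ontology(dag)
    direct <- random_direct(dag, 30, seed + 100)
    idx <- propagate_counts(ont, as_corpus(direct))
    orc <- oracle_counts(dag, direct)
    expect_equal(idx$counts[dag$ids], orc$counts[dag$ids])
    expect_equal(idx$total, orc$total)
    # subsetting: experiment counts never exceed background counts
    sub <- names(direct)[1:10]
    idx_sub <- propagate_counts(ont, as_corpus(direct), proteins = sub)
    expect_true(all(idx_sub$counts <= idx$counts))
    expect_equal(idx_sub$counts[dag$ids],
                 oracle_counts(dag, direct, proteins = sub)$counts[dag$ids])
  }
})

test_that("count indices are monotone along edges and root equals total", {
  dag <- random_test_dag(30, 7)
  ont <- dag_to_ontology(dag)
  idx <- propagate_counts(ont, as_corpus(random_direct(dag, 20, 8)))
  for (i in seq_len(nrow(ont$edges)))
    expect_lte(idx$counts[[ont$edges$child[i]]],
               idx$counts[[ont$edges$parent[i]]])
  expect_equal(unname(idx$counts[["GO:2000001"]]), idx$total)
})

test_that("disjoint protein subset yields a zero-total index with warning", {
  ont <- chain_ontology(2)
  corpus <- as_corpus(list(P1 = "GO:0000002"))
  expect_warning(idx <- propagate_counts(ont, corpus, proteins = "PX"),
                 "no protein")
  expect_equal(idx$total, 0L)
})

test_that("fraction assignment follows the pairwise margin rule", {
  ab <- rbind(a = c(nucleus = 1.4, cytosolic = 1.0, membrane = 1.0),
              b = c(nucleus = 1.0, cytosolic = 1.0, membrane = 1.0),
              c = c(nucleus = 1.0, cytosolic = 1.0, membrane = 1.45))
  out <- assign_fractions(ab)
  # 40% over both other fractions beats the 30% margins
  expect_equal(unname(out["a"]), "nucleus")
  # no enrichment anywhere
  expect_equal(unname(out["b"]), "non-specific")
  # membrane over cytosolic at 45% misses the 50% margin
  expect_equal(unname(out["c"]), "non-specific")
})

test_that("fraction assignment is invariant to per-protein rescaling", {
  set.seed(1)
  ab <- matrix(runif(30, 0.5, 2), nrow = 10,
               dimnames = list(sprintf("p%02d", 1:10),
                               c("cytosolic", "membrane", "nucleus")))
  scaled <- ab * runif(10, 0.1, 10)
  expect_equal(assign_fractions(ab), assign_fractions(scaled))
})

test_that("fraction assignment validates inputs", {
  ab <- rbind(a = c(cytosolic = 1, membrane = -1, nucleus = 1))
  expect_error(assign_fractions(ab), "negative")
  ab2 <- rbind(a = c(x = 1, y = 2))
  expect_error(assign_fractions(ab2), "margins must be given")
  expect_error(assign_fractions(ab2, margins = c("x:z" = 0.3)),
               "unknown fraction")
  # a single unnamed margin applies to all pairs
  expect_equal(unname(assign_fractions(ab2, margins = 0.5)["a"]), "y")
})

test_that("zero intensities are treated as infinite or null enrichment", {
  ab <- rbind(a = c(cytosolic = 1, membrane = 0, nucleus = 0),
              b = c(cytosolic = 0, membrane = 0, nucleus = 0))
  out <- assign_fractions(ab)
  expect_equal(unname(out["a"]), "cytosolic")
  expect_equal(unname(out["b"]), "non-specific")
})

test_that("dataset counts partition the annotated proteins", {
  dag <- random_test_dag(25, 11)
  ont <- dag_to_ontology(dag)
  direct <- random_direct(dag, 12, 12)
  assignment <- stats::setNames(
    rep(c("cytosolic", "nucleus"), each = 6), names(direct))
  out <- dataset_counts(ont, as_corpus(direct), assignment)
  expect_equal(sum(vapply(out, function(x) x$total, 0L)), 12L)
  for (lab in names(out)) {
    orc <- oracle_counts(dag, direct,
                         proteins = names(assignment)[assignment == lab])
    expect_equal(out[[lab]]$counts[dag$ids], orc$counts[dag$ids])
  }
  # a label with no annotated proteins warns and totals zero
  assignment2 <- c(assignment, PXX = "membrane")
  expect_warning(out2 <- dataset_counts(ont, as_corpus(direct), assignment2),
                 "membrane")
  expect_equal(out2$membrane$total, 0L)
})
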