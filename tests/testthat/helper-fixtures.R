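# Fixture builders and independent oracles, kept deliberately separate from
# the package's own graph machinery: oracles enumerate paths explicitly.

obo_header <- "format-version: 1.2"

write_obo_text <- function(stanzas) {
  path <- tempfile(fileext = ".obo")
  writeLines(c(obo_header, "", stanzas), path)
  path
}

term_stanza <- function(id, name = id, namespace = "cellular_component",
                        is_a = character(), part_of = character(),
                        alt_id = character(), obsolete = FALSE) {
  c("[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    paste0("namespace: ", namespace),
    if (length(alt_id)) paste0("alt_id: ", alt_id),
    if (length(is_a)) paste0("is_a: ", is_a),
    if (length(part_of)) paste0("relationship: part_of ", part_of),
    if (obsolete) "is_obsolete: true",
    "")
}

# linear chain root <- t2 <- ... <- tn via is_a
chain_ontology <- function(n) {
  ids <- sprintf("GO:0%06d", seq_len(n))
  stanzas <- unlist(lapply(seq_len(n), function(i) {
    term_stanza(ids[i], is_a = if (i > 1) ids[i - 1] else character())
  }))
  read_obo(write_obo_text(stanzas))
}

# diamond: d is_a b, d is_a c, b is_a a, c is_a a
diamond_ontology <- function() {
  stanzas <- c(term_stanza("GO:0000001"),
               term_stanza("GO:0000002", is_a = "GO:0000001"),
               term_stanza("GO:0000003", is_a = "GO:0000001"),
               term_stanza("GO:0000004", is_a = c("GO:0000002", "GO:0000003")))
  read_obo(write_obo_text(stanzas))
}

# random DAG constructed independently of the package generator: node i
# (i >= 2) picks 1-2 parents among nodes 1..i-1, mixed relations
random_test_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("GO:2%06d", seq_len(n))
  child <- character(); parent <- character(); rel <- character()
  for (i in seq_len(n)[-1]) {
    k <- sample(1:2, 1)
    ps <- sample(seq_len(i - 1), min(k, i - 1))
    for (p in ps) {
      child <- c(child, ids[i]); parent <- c(parent, ids[p])
      rel <- c(rel, sample(c("is_a", "is_a", "part_of"), 1))
    }
  }
  list(ids = ids,
       edges = data.frame(child = child, parent = parent, relation = rel,
                          stringsAsFactors = FALSE))
}

dag_to_ontology <- function(dag) {
  stanzas <- unlist(lapply(dag$ids, function(id) {
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    term_stanza(id,
                is_a = e$parent[e$relation == "is_a"],
                part_of = e$parent[e$relation == "part_of"])
  }))
  read_obo(write_obo_text(stanzas))
}

# brute-force ancestor oracle: enumerate every parent path, deduplicate
oracle_ancestors <- function(edges, term,
                             relations = c("is_a", "part_of")) {
  e <- edges[edges$relation %in% relations, , drop = FALSE]
  res <- character(0)
  recurse <- function(t) {
    for (p in e$parent[e$child == t]) {
      res <<- c(res, p)
      recurse(p)
    }
  }
  recurse(term)
  unique(res)
}

# per-protein ancestor-union counting oracle
oracle_counts <- function(dag, direct, proteins = NULL,
                          relations = c("is_a", "part_of")) {
  prots <- names(direct)
  if (!is.null(proteins)) prots <- intersect(proteins, prots)
  counts <- stats::setNames(integer(length(dag$ids)), dag$ids)
  total <- 0L
  for (p in prots) {
    d <- direct[[p]]
    if (!length(d)) next
    u <- unique(c(d, unlist(lapply(d, function(t)
      oracle_ancestors(dag$edges, t, relations)))))
    counts[u] <- counts[u] + 1L
    total <- total + 1L
  }
  list(counts = counts, total = total)
}

# random annotation corpus over a DAG (direct map form)
random_direct <- function(dag, n_proteins, seed, max_terms = 3) {
  set.seed(seed)
  prots <- sprintf("P%03d", seq_len(n_proteins))
  direct <- lapply(prots, function(p)
    sample(dag$ids, sample(seq_len(max_terms), 1)))
  stats::setNames(direct, prots)
}

as_corpus <- function(direct, namespace = "cellular_component") {
  gopca:::new_annotation_corpus(direct, namespace)
}

# exhaustive hypergeometric upper-tail oracle from binomial coefficients
oracle_hyper <- function(k, n, K, M) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(M - K, n - j)) / choose(M, n)
}

# GAF writer for corpus-style fixtures
write_gaf_rows <- function(rows) {
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2", rows), path)
  path
}

gaf_row <- function(protein, term, aspect = "C", qualifier = "located_in") {
  paste(c("DB", protein, protein, qualifier, term, "REF", "IEA", "",
          aspect, "", "", "protein", "taxon:10090", "20260101", "DB"),
        collapse = "\t")
}

# one full synthetic study for the default conditions, memoised per seed
synthetic_study <- local({
  cache <- list()
  function(seed) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- synthetic_config(seed = seed)
    ont <- simulate_ontology(cfg)
    bg <- simulate_background(cfg, ont)
    ex <- simulate_experiment(cfg, ont, bg)
    res <- suppressWarnings(analyze_fractions(ont, bg, ex$abundance))
    out <- list(config = cfg, ontology = ont, background = bg,
                experiment = ex, analysis = res)
    cache[[key]] <<- out
    out
  }
})
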