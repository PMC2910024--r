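#' Configuration for the synthetic benchmark generator
#'
#' Bundles every tunable of the simulated study: a random single-root
#' ontology DAG, a background annotation corpus over it, and a fractionated
#' "experiment" whose proteins are enriched in planted, fraction-specific
#' GO branches with abundance ratios exceeding the fraction-assignment
#' thresholds.
#'
#' All sampling is driven by `seed` through documented per-stage offsets
#' (`seed` for the DAG, `seed + 1` for the background, `seed + 2` for the
#' experiment), so adding a later stage never perturbs earlier draws.
#'
#' @param seed Integer seed.
#' @param n_terms Number of ontology terms (default 200).
#' @param depth Number of layers below the root (default 6).
#' @param extra_parent_prob Probability that a term gains one extra parent
#'   (a `part_of` edge to a shallower layer; default 0.15).
#' @param m_goa Background proteins (default 2000).
#' @param noise_annotations Poisson mean for extra direct annotations per
#'   protein; each protein gets `1 + Poisson(noise_annotations)` direct
#'   terms (default 3).
#' @param dedicated_fraction Share of background proteins that are
#'   "dedicated" complex members with all annotations cliqued in one
#'   compartment branch; the rest are broadly localised bulk proteins
#'   annotated across the whole graph (default 0.35).
#' @param bulk_depth_decay Per-layer decay of the bulk proteins' direct
#'   annotation probability; values below 1 concentrate direct bulk
#'   annotation on shallow terms as in real corpora (default 0.5).
#' @param fractions Named list, one entry per planted fraction, each a
#'   list with `n_proteins`, `signature_terms`, `signal_prob`,
#'   `ratio_margin`. The defaults emulate a three-way subcellular
#'   fractionation with fraction sizes in realistic proportion.
#' @param nonspecific_proteins Size of the near-equal-intensity protein
#'   pool that lands in the `"non-specific"` dataset (default 600).
#' @param resident_min_share Minimum share of a protein's direct
#'   annotations that must lie inside a fraction's signature branch for
#'   the protein to count as a compartment resident during fraction
#'   sampling (default 1: residents are fully cliqued complex members,
#'   modelling lists that passed stringent enrichment thresholds).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_terms = 200L, depth = 6L,
                             extra_parent_prob = 0.15, m_goa = 2000L,
                             noise_annotations = 3,
                             dedicated_fraction = 0.35,
                             bulk_depth_decay = 0.5,
                             fractions = list(
                               cytosolic = list(n_proteins = 110L,
                                                signature_terms = 8L,
                                                signal_prob = 0.98,
                                                ratio_margin = 0.8),
                               membrane = list(n_proteins = 60L,
                                               signature_terms = 8L,
                                               signal_prob = 0.98,
                                               ratio_margin = 0.8),
                               nucleus = list(n_proteins = 35L,
                                              signature_terms = 8L,
                                              signal_prob = 0.98,
                                              ratio_margin = 0.8)),
                             nonspecific_proteins = 600L,
                             resident_min_share = 1) {
  stopifnot(depth >= 2, n_terms >= 1, m_goa >= 1,
            extra_parent_prob >= 0, extra_parent_prob <= 1,
            length(fractions) >= 1, !is.null(names(fractions)))
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 depth = as.integer(depth),
                 extra_parent_prob = extra_parent_prob,
                 m_goa = as.integer(m_goa),
                 noise_annotations = noise_annotations,
                 dedicated_fraction = dedicated_fraction,
                 bulk_depth_decay = bulk_depth_decay,
                 fractions = fractions,
                 nonspecific_proteins = as.integer(nonspecific_proteins),
                 resident_min_share = resident_min_share),
            class = "synthetic_config")
}

synthetic_term_id <- function(i) sprintf("GO:1%06d", i)

#' Simulate a single-root layered ontology DAG
#'
#' Terms are placed in `depth` layers below a single root; every non-root
#' term receives one `is_a` parent from the previous layer and, with
#' probability `extra_parent_prob`, one extra `part_of` parent from a
#' shallower layer. Extra parents are drawn from the term's own
#' compartment branch (the subtree below its layer-2 ancestor on the
#' primary `is_a` chain) when possible, falling back to the top layers:
#' multiple parentage in the real cellular-component graph is
#' predominantly intra-compartment. The construction is acyclic by
#' layering. Namespace is `"cellular_component"`.
#'
#' @param config A `synthetic_config`.
#' @return A `go_ontology`; the layer of each term is kept in attribute
#'   `"layers"` (root = 0).
#' @export
simulate_ontology <- function(config) {
  set.seed(config$seed)
  n <- config$n_terms
  ids <- synthetic_term_id(seq_len(n))
  layers <- integer(n)            # root at layer 0
  if (n > 1) {
    # geometric layer widths: few broad compartment branches fanning out
    # into many specific terms, echoing the width profile of GO
    w <- 1.7^seq_len(config$depth)
    sizes <- pmax(1L, round((n - 1L) * w / sum(w)))
    while (sum(sizes) > n - 1L) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    while (sum(sizes) < n - 1L) sizes[which.max(w)] <- sizes[which.max(w)] + 1L
    layers[-1] <- rep(seq_len(config$depth), times = sizes)
  }
  e_child <- character(); e_parent <- character(); e_rel <- character()
  branch <- rep(NA_integer_, n)   # layer-2 ancestor on the primary chain
  n_branch <- sum(layers == 2L)
  branch_count <- stats::setNames(integer(n_branch),
                                  which(layers == 2L))
  for (i in seq_len(n)[-1]) {
    if (layers[i] <= 2L) {
      prev <- which(layers == layers[i] - 1L)
      par <- if (length(prev) == 1) prev else sample(prev, 1)
      if (layers[i] == 2L) branch[i] <- i
    } else {
      # keep compartment branches comparable in size: attach to the
      # least-filled branch that has a parent available one layer up
      o <- sample(seq_len(n_branch))           # random tie-break
      o <- o[order(branch_count[o])]
      par <- NA_integer_
      for (b in as.integer(names(branch_count)[o])) {
        cand <- which(layers == layers[i] - 1L & branch == b)
        if (length(cand)) {
          par <- if (length(cand) == 1) cand else sample(cand, 1)
          branch[i] <- b
          branch_count[as.character(b)] <- branch_count[as.character(b)] + 1L
          break
        }
      }
      if (is.na(par)) {   # tiny graphs: fall back to any parent one layer up
        prev <- which(layers == layers[i] - 1L)
        par <- if (length(prev) == 1) prev else sample(prev, 1)
        branch[i] <- branch[par]
      }
    }
    e_child <- c(e_child, ids[i]); e_parent <- c(e_parent, ids[par])
    e_rel <- c(e_rel, "is_a")
    if (layers[i] >= 2L && stats::runif(1) < config$extra_parent_prob) {
      same_branch <- which(layers < layers[i] & layers >= 2L &
                             branch == branch[i] & seq_len(n) != par)
      cand <- if (length(same_branch)) same_branch
              else which(layers <= 1L & seq_len(n) != par)
      ep <- if (length(cand) == 1) cand else sample(cand, 1)
      e_child <- c(e_child, ids[i]); e_parent <- c(e_parent, ids[ep])
      e_rel <- c(e_rel, "part_of")
    }
  }
  terms <- data.frame(id = ids,
                      name = c("cellular_component",
                               paste("synthetic term", seq_len(n))[-1]),
                      namespace = "cellular_component",
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = e_child, parent = e_parent, relation = e_rel,
                      stringsAsFactors = FALSE)
  g <- new_go_ontology(terms, edges,
                       roots = c(cellular_component = ids[1]))
  attr(g, "layers") <- stats::setNames(layers, ids)
  g
}

#' Simulate a background annotation corpus
#'
#' The corpus mixes two protein populations that together reproduce the
#' two salient features of real cellular-component annotation:
#'
#' * a `dedicated_fraction` of "dedicated" proteins (stable complex
#'   members) whose direct annotations are cliqued inside one home
#'   compartment branch (the subtree of one layer-2 term, chosen with
#'   probability proportional to subtree size), weighted toward deeper
#'   layers within the branch;
#' * the remaining "bulk" proteins (broadly localised machinery) whose
#'   direct annotations are drawn over the whole graph with a per-layer
#'   decay (`bulk_depth_decay`), giving every term a depth-decaying
#'   baseline of annotation mass.
#'
#' Each protein gets `1 + Poisson(noise_annotations)` direct terms. Terms
#' left with a propagated count of zero are covered by adding one direct
#' annotation to a randomly chosen protein, so every term keeps `y >= 1`.
#'
#' @param config A `synthetic_config`.
#' @param ontology The graph from [simulate_ontology()].
#' @return An `annotation_corpus` over proteins `P000001 ...`.
#' @export
simulate_background <- function(config, ontology) {
  set.seed(config$seed + 1L)
  layers <- attr(ontology, "layers")
  ids <- ontology$terms$id
  desc <- descendant_closure(ontology)
  branch_roots <- ids[layers[ids] == 2L]
  if (!length(branch_roots)) branch_roots <- ids[layers[ids] == 1L]
  branch_terms <- lapply(branch_roots, function(b) ids[desc[[b]]])
  bsize <- lengths(branch_terms)
  prots <- sprintf("P%06d", seq_len(config$m_goa))
  n_annot <- 1L + stats::rpois(config$m_goa, config$noise_annotations)
  n_ded <- round(config$dedicated_fraction * config$m_goa)
  is_ded <- seq_len(config$m_goa) <= n_ded
  home <- sample.int(length(branch_roots), config$m_goa, replace = TRUE,
                     prob = bsize)
  nonroot <- ids[layers[ids] > 0L]
  w_bulk <- config$bulk_depth_decay^(layers[nonroot] - 1L)
  direct <- lapply(seq_len(config$m_goa), function(i) {
    if (is_ded[i]) {
      pool <- branch_terms[[home[i]]]
      k <- min(n_annot[i], length(pool))
      if (length(pool) == 1) pool
      else sample(pool, k, prob = layers[pool])
    } else {
      k <- min(n_annot[i], length(nonroot))
      sample(nonroot, k, prob = w_bulk)
    }
  })
  names(direct) <- prots
  corpus <- new_annotation_corpus(direct, "cellular_component")
  # coverage repair: every term must retain y >= 1 after propagation.
  # Repairs go to bulk proteins so dedicated proteins stay cliqued.
  cnt <- propagate_counts(ontology, corpus)
  uncovered <- names(cnt$counts)[cnt$counts == 0L]
  repair_pool <- if (any(!is_ded)) prots[!is_ded] else prots
  for (t in uncovered) {
    p <- if (length(repair_pool) == 1) repair_pool
         else sample(repair_pool, 1)
    corpus$direct[[p]] <- unique(c(corpus$direct[[p]], t))
  }
  corpus
}

# Pick disjoint signature subtrees, one per fraction: a subtree root one
# layer below the compartment (layer-2) level, in a distinct compartment
# branch per fraction, whose inclusive descendant set has at least `size`
# members; the signature is the first `size` subtree terms in layer
# order. Planting below the compartment roots keeps the generic shallow
# layers shared between all datasets while the planted complexes stay
# fraction-exclusive.
pick_signatures <- function(ontology, sizes, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(sizes))
  layers <- attr(ontology, "layers")
  ids <- ontology$terms$id
  desc <- descendant_closure(ontology)
  anc <- ancestor_closure(ontology)
  # compartment (layer-2) ancestor of each term, first chain if several
  compartment_of <- function(t) {
    if (layers[t] == 2L) return(t)
    a <- ids[anc[[t]]]
    a <- a[layers[a] == 2L]
    if (length(a)) a[1] else NA_character_
  }
  top_of <- function(t) {      # layer-1 (top-level) ancestor, first chain
    if (layers[t] == 1L) return(t)
    a <- ids[anc[[t]]]
    a <- a[layers[a] == 1L]
    if (length(a)) a[1] else NA_character_
  }
  cand3 <- ids[layers[ids] == 3L]
  cand2 <- ids[layers[ids] == 2L]
  mkcand <- function(cc) cc[order(lengths(desc[cc]), cc)]
  place <- function(require_distinct_tops) {
    used_branches <- character(); used_tops <- character()
    out <- vector("list", length(sizes))
    for (f in seq_along(sizes)) {
      found <- FALSE
      for (r in cand) {
        comp <- compartment_of(r)
        if (is.na(comp) || comp %in% used_branches) next
        if (require_distinct_tops) {
          top <- top_of(comp)
          if (!is.na(top) && top %in% used_tops) next
        }
        members <- ids[desc[[r]]]
        if (length(members) >= sizes[f]) {
          o <- order(layers[members], members)  # root of subtree first
          out[[f]] <- members[o][seq_len(sizes[f])]
          used_branches <- c(used_branches, comp)
          used_tops <- c(used_tops, top_of(comp))
          found <- TRUE
          break
        }
      }
      if (!found) return(NULL)
    }
    attr(out, "branches") <- used_branches
    out
  }
  # fractions model distinct top-level compartments where the graph
  # allows; small graphs fall back to compartment-level subtree roots
  out <- NULL
  for (cand in list(mkcand(cand3), mkcand(cand2),
                    mkcand(c(cand3, cand2)))) {
    if (!length(cand)) next
    out <- place(TRUE)
    if (is.null(out)) out <- place(FALSE)
    if (!is.null(out)) break
  }
  if (is.null(out))
    stop("cannot place ", length(sizes), " disjoint signature subtrees ",
         "in distinct compartment branches; increase n_terms or reduce ",
         "signature_terms")
  out
}

#' Simulate a fractionated experiment with planted GO signatures
#'
#' Selects disjoint signature subtrees (one per configured fraction), then
#' samples each fraction's proteins from the background: with probability
#' `signal_prob` a compartment-resident protein whose propagated
#' annotations hit a signature term (cycled round-robin so every
#' signature term is covered; residents -- proteins with at least
#' `resident_min_share` of their direct annotations inside the signature
#' branch, as biochemical enrichment selects proteins physically located
#' in the compartment -- are preferred, other hitters are the fallback),
#' otherwise a random background protein. Intensities are constructed so every
#' fraction protein exceeds its configured `ratio_margin` over every other
#' fraction while the non-specific pool stays within +/-5% of flat.
#'
#' @param config A `synthetic_config`.
#' @param ontology The graph from [simulate_ontology()].
#' @param background The corpus from [simulate_background()].
#' @return List with `abundance` (protein x fraction intensity matrix),
#'   `truth` (named list: fraction -> planted signature term ids), and
#'   `fraction_proteins` (named list: fraction -> sampled protein ids).
#' @export
simulate_experiment <- function(config, ontology, background) {
  set.seed(config$seed + 2L)
  fr_names <- names(config$fractions)
  sizes <- vapply(config$fractions, function(f) f$signature_terms, 0L)
  sigs <- pick_signatures(
    ontology, sizes,
    weights = vapply(config$fractions, function(f) f$n_proteins, 0L))
  branches <- attr(sigs, "branches")
  names(sigs) <- fr_names
  names(branches) <- fr_names

  # propagated protein -> term-index sets
  ids <- ontology$terms$id
  idx <- seq_along(ids); names(idx) <- ids
  anc <- ancestor_closure(ontology)
  prot_terms <- lapply(background$direct, function(d) {
    di <- idx[d[d %in% ids]]
    unique(c(di, unlist(anc[di], use.names = FALSE)))
  })
  prots <- names(prot_terms)
  # term index -> proteins reaching it
  hit_map <- vector("list", length(ids))
  for (p in seq_along(prot_terms))
    for (t in prot_terms[[p]]) hit_map[[t]] <- c(hit_map[[t]], p)

  used <- logical(length(prots))
  fraction_proteins <- stats::setNames(vector("list", length(fr_names)),
                                       fr_names)
  for (f in fr_names) {
    cfg <- config$fractions[[f]]
    sig_idx <- idx[sigs[[f]]]
    # residency is judged against the full compartment branch that
    # contains the signature subtree
    branch_full <- desc_ids(ontology, branches[[f]])
    resident <- vapply(background$direct, function(d)
      mean(d %in% branch_full) >= config$resident_min_share, logical(1))
    chosen <- integer(0)
    rr <- 0L
    for (s in seq_len(cfg$n_proteins)) {
      pick <- NA_integer_
      if (stats::runif(1) < cfg$signal_prob) {
        # round-robin over signature terms guarantees per-term coverage
        for (tries in seq_along(sig_idx)) {
          rr <- rr %% length(sig_idx) + 1L
          pool <- hit_map[[sig_idx[rr]]]
          pool <- pool[!used[pool]]
          if (length(pool)) {
            res_pool <- pool[resident[pool]]
            if (length(res_pool)) pool <- res_pool
            pick <- if (length(pool) == 1) pool else sample(pool, 1)
            break
          }
        }
      }
      if (is.na(pick)) {
        pool <- which(!used)
        if (!length(pool)) break
        pick <- if (length(pool) == 1) pool else sample(pool, 1)
      }
      used[pick] <- TRUE
      chosen <- c(chosen, pick)
    }
    fraction_proteins[[f]] <- prots[chosen]
  }
  # the non-specific internal standard holds genuinely multi-localised
  # proteins: no single compartment branch carries more than half of a
  # pool protein's direct annotations
  comp_root <- branch_of_terms(ontology)
  max_share <- vapply(background$direct, function(d) {
    b <- comp_root[d]
    b <- b[!is.na(b)]
    if (!length(b)) return(0)
    max(table(b)) / length(d)
  }, numeric(1))
  pool <- which(!used & max_share <= 0.5)
  if (length(pool) < config$nonspecific_proteins)
    pool <- which(!used)
  ns_n <- min(config$nonspecific_proteins, length(pool))
  ns_pick <- if (ns_n) sort(sample(pool, ns_n)) else integer(0)
  nonspecific <- prots[ns_pick]

  all_prots <- c(unlist(fraction_proteins, use.names = FALSE), nonspecific)
  ab <- matrix(0, nrow = length(all_prots), ncol = length(fr_names),
               dimnames = list(all_prots, fr_names))
  for (f in fr_names) {
    cfg <- config$fractions[[f]]
    for (p in fraction_proteins[[f]]) {
      base <- stats::rlnorm(1, meanlog = 0, sdlog = 0.5)
      others <- base * stats::runif(length(fr_names) - 1, 0.95, 1.05)
      ab[p, setdiff(fr_names, f)] <- others
      ab[p, f] <- max(others) * (1 + cfg$ratio_margin +
                                   stats::runif(1, 0.05, 0.3))
    }
  }
  for (p in nonspecific) {
    base <- stats::rlnorm(1, meanlog = 0, sdlog = 0.5)
    ab[p, ] <- base * stats::runif(length(fr_names), 0.95, 1.05)
  }
  list(abundance = ab, truth = sigs, fraction_proteins = fraction_proteins)
}

#' Write an ontology as OBO 1.2
#' @param ontology A `go_ontology`.
#' @param file Output path.
#' @export
write_obo <- function(ontology, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(seq_len(nrow(ontology$edges)), ontology$edges$child)
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", ontology$terms$name[i]),
                 paste0("namespace: ", ontology$terms$namespace[i])), con)
    for (e in by_child[[id]]) {
      rel <- ontology$edges$relation[e]
      par <- ontology$edges$parent[e]
      writeLines(if (rel == "is_a") paste0("is_a: ", par)
                 else paste0("relationship: ", rel, " ", par), con)
    }
    writeLines("", con)
  }
  invisible(file)
}

#' Write an annotation corpus as GAF 2.2
#' @param corpus An `annotation_corpus`.
#' @param file Output path.
#' @export
write_gaf <- function(corpus, file) {
  aspect <- switch(corpus$namespace, cellular_component = "C",
                   biological_process = "P", molecular_function = "F")
  qualifier <- switch(aspect, C = "located_in", P = "involved_in",
                      F = "enables")
  con <- file(file, "w"); on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (p in names(corpus$direct)) {
    for (t in corpus$direct[[p]]) {
      writeLines(paste(c("SYN", p, p, qualifier, t, "SYN:0000001", "IEA",
                         "", aspect, "", "", "protein", "taxon:10090",
                         "20260101", "SYN", "", ""), collapse = "\t"), con)
    }
  }
  invisible(file)
}

#' Write an abundance matrix as TSV
#' @param abundance Protein x fraction numeric matrix.
#' @param file Output path.
#' @export
write_abundance <- function(abundance, file) {
  df <- data.frame(protein = rownames(abundance), abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write / read a planted-signature truth table as TSV
#'
#' Two columns, `fraction` and `term`; the round-trip is lossless.
#' @param truth Named list fraction -> character vector of term ids.
#' @param file Path.
#' @export
write_truth <- function(truth, file) {
  df <- data.frame(
    fraction = rep(names(truth), lengths(truth)),
    term = unlist(truth, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  lapply(split(df$term, df$fraction), as.character)
}

# ids of the inclusive descendant set of one term
desc_ids <- function(ontology, term) {
  ids <- ontology$terms$id
  ids[descendant_closure(ontology)[[term]]]
}

# compartment (layer-2 subtree root) of every term; NA above layer 2
branch_of_terms <- function(ontology) {
  layers <- attr(ontology, "layers")
  ids <- ontology$terms$id
  desc <- descendant_closure(ontology)
  out <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (b in ids[layers[ids] == 2L]) {
    members <- ids[desc[[b]]]
    fill <- is.na(out[members])
    out[members[fill]] <- b
  }
  out
}
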