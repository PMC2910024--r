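#' Ontology graph objects
#'
#' A `go_ontology` holds one or more namespaces of the Gene Ontology as a
#' directed acyclic graph: a term table, typed child-to-parent edges
#' (`is_a`, `part_of`, `regulates`), the namespace root(s), obsolete term
#' ids and an alt-id lookup mapping secondary ids onto canonical ones.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param roots named character vector, names are namespaces.
#' @param obsolete character vector of obsolete term ids.
#' @param alt_ids named character vector mapping alt id -> canonical id.
#' @return An object of class `go_ontology`.
#' @keywords internal
new_go_ontology <- function(terms, edges, roots, obsolete = character(),
                            alt_ids = character()) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  structure(
    list(terms = terms, edges = edges, roots = roots,
         obsolete = obsolete, alt_ids = alt_ids),
    class = "go_ontology"
  )
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("go_ontology:", nrow(x$terms), "terms,", nrow(x$edges), "edges\n")
  ns <- table(x$terms$namespace)
  for (n in names(ns)) {
    cat("  ", n, ": ", ns[[n]], " terms, root ",
        paste(x$roots[names(x$roots) == n], collapse = ", "), "\n", sep = "")
  }
  if (length(x$obsolete)) cat("  obsolete terms:", length(x$obsolete), "\n")
  invisible(x)
}

KNOWN_RELATIONS <- c("is_a", "part_of", "regulates")
DEFAULT_RELATIONS <- c("is_a", "part_of")

#' Read an ontology in OBO format
#'
#' Parses OBO 1.2/1.4 `[Term]` stanzas into a [new_go_ontology()] object.
#' `is_a` and `relationship:` lines become typed child-to-parent edges;
#' `negatively_regulates`/`positively_regulates` collapse onto `regulates`.
#' Obsolete terms are recorded but excluded from the graph and from
#' traversal; `alt_id` entries are kept as a lookup onto the canonical id.
#'
#' @param file Path to an OBO file (or a connection readable by `readLines`).
#' @param namespace Optional namespace filter; one or more of
#'   `"cellular_component"`, `"biological_process"`, `"molecular_function"`.
#'   Edges leading out of the selected namespace(s) are dropped.
#' @return A `go_ontology`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
#'              "name: root", "namespace: cellular_component"), obo)
#' read_obo(obo)
#' @export
read_obo <- function(file, namespace = NULL) {
  lines <- readLines(file, warn = FALSE)
  # stanza boundaries: lines like [Term], [Typedef], ...
  stanza_at <- grep("^\\[", lines)
  if (!length(stanza_at)) stop("no stanzas found in OBO input")
  bounds <- c(stanza_at, length(lines) + 1L)

  ids <- character(); names_ <- character(); namespaces <- character()
  obsolete <- character()
  alt_from <- character(); alt_to <- character()
  e_child <- character(); e_parent <- character(); e_rel <- character()

  for (s in seq_along(stanza_at)) {
    if (lines[stanza_at[s]] != "[Term]") next
    body <- lines[seq(stanza_at[s] + 1L, bounds[s + 1L] - 1L)]
    body <- body[nzchar(body)]
    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else "", "")
    vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else "", "")
    # strip trailing OBO comments ("GO:x ! name") and modifiers
    vals <- sub("\\s*!.*$", "", vals)

    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id)) next
    nm <- vals[keys == "name"][1]
    ns <- vals[keys == "namespace"][1]
    if (any(keys == "is_obsolete" & grepl("^true", vals))) {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    names_ <- c(names_, if (is.na(nm)) "" else nm)
    namespaces <- c(namespaces, if (is.na(ns)) "" else ns)
    for (a in vals[keys == "alt_id"]) {
      alt_from <- c(alt_from, a); alt_to <- c(alt_to, id)
    }
    for (p in vals[keys == "is_a"]) {
      e_child <- c(e_child, id); e_parent <- c(e_parent, trimws(p))
      e_rel <- c(e_rel, "is_a")
    }
    for (r in vals[keys == "relationship"]) {
      parts <- strsplit(trimws(r), "\\s+")[[1]]
      if (length(parts) < 2) next
      rel <- parts[1]
      if (rel %in% c("negatively_regulates", "positively_regulates"))
        rel <- "regulates"
      if (!rel %in% KNOWN_RELATIONS) next
      e_child <- c(e_child, id); e_parent <- c(e_parent, parts[2])
      e_rel <- c(e_rel, rel)
    }
  }

  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    names_ <- names_[keep]; namespaces <- namespaces[keep]; ids <- ids[keep]
  }
  all_known <- c(ids, obsolete)

  if (!is.null(namespace)) {
    sel <- namespaces %in% namespace
    if (!any(sel)) stop("no terms in namespace(s): ",
                        paste(namespace, collapse = ", "))
    dropped <- ids[!sel]
    ids <- ids[sel]; names_ <- names_[sel]; namespaces <- namespaces[sel]
    # cross-namespace edges are out of scope: drop edges touching dropped terms
    keep_e <- !(e_child %in% dropped) & !(e_parent %in% dropped)
    e_child <- e_child[keep_e]; e_parent <- e_parent[keep_e]
    e_rel <- e_rel[keep_e]
  }
  # edges from/to obsolete terms are excluded from traversal
  keep_e <- e_child %in% ids & !(e_parent %in% obsolete)
  e_child <- e_child[keep_e]; e_parent <- e_parent[keep_e]; e_rel <- e_rel[keep_e]

  dangling <- setdiff(e_parent, all_known)
  if (length(dangling))
    stop("dangling parent id(s) in OBO input: ",
         paste(utils::head(dangling, 5), collapse = ", "))

  edges <- unique(data.frame(child = e_child, parent = e_parent,
                             relation = e_rel, stringsAsFactors = FALSE))
  terms <- data.frame(id = ids, name = names_, namespace = namespaces,
                      stringsAsFactors = FALSE)

  assert_acyclic(terms$id, edges)

  has_out <- terms$id %in% edges$child
  roots <- terms$id[!has_out]
  names(roots) <- terms$namespace[!has_out]

  alt <- alt_to
  names(alt) <- alt_from
  new_go_ontology(terms, edges, roots, obsolete = obsolete, alt_ids = alt)
}

# Kahn's algorithm on child->parent edges; errors naming a cycle member.
assert_acyclic <- function(ids, edges) {
  idx <- seq_along(ids); names(idx) <- ids
  out_deg <- tabulate(idx[edges$child], nbins = length(ids))
  parents_of <- split(idx[edges$parent], idx[edges$child])
  # reverse adjacency: parent -> children indices
  children_of <- split(idx[edges$child], idx[edges$parent])
  queue <- which(out_deg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (c in children_of[[as.character(v)]]) {
      out_deg[c] <- out_deg[c] - 1L
      if (out_deg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(ids)) {
    member <- ids[which(out_deg > 0L)[1]]
    stop("cycle detected in ontology graph involving term ", member)
  }
  invisible(TRUE)
}

# Resolve alt ids, validate existence / non-obsolete status.
resolve_term <- function(ontology, term) {
  if (term %in% ontology$terms$id) return(term)
  if (term %in% names(ontology$alt_ids)) return(unname(ontology$alt_ids[[term]]))
  if (term %in% ontology$obsolete)
    stop("term ", term, " is obsolete and excluded from traversal")
  stop("unknown term id: ", term)
}

# parent adjacency restricted to a relation subset, as a named list of
# character vectors (child id -> parent ids)
parent_adjacency <- function(ontology, relations = DEFAULT_RELATIONS) {
  e <- ontology$edges[ontology$edges$relation %in% relations, , drop = FALSE]
  split(e$parent, factor(e$child, levels = unique(e$child)))
}

#' Ancestors of a term under the true-path rule
#'
#' Returns every term reachable from `term` by repeatedly following
#' child-to-parent edges whose relation is in `relations`. The term itself
#' is excluded; each ancestor appears once regardless of path multiplicity.
#' The default relation set `{is_a, part_of}` is the conventional true-path
#' propagation set; `regulates` can be added explicitly.
#'
#' @param ontology A `go_ontology`.
#' @param term A term id (alt ids are resolved to their canonical id).
#' @param relations Character subset of `c("is_a", "part_of", "regulates")`.
#' @return Character vector of ancestor term ids (unordered set).
#' @export
go_ancestors <- function(ontology, term, relations = DEFAULT_RELATIONS) {
  term <- resolve_term(ontology, term)
  adj <- parent_adjacency(ontology, relations)
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    parents <- unique(unlist(adj[frontier], use.names = FALSE))
    parents <- setdiff(parents, seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  setdiff(seen, term)
}

#' Specificity level of a term
#'
#' The number of distinct predecessor (ancestor) terms of a GO term in the
#' DAG, used here as the measure of how specific a term is: the root has
#' level 0 and deeper terms have more ancestors.
#'
#' @inheritParams go_ancestors
#' @return Non-negative integer count of ancestors.
#' @export
term_specificity <- function(ontology, term, relations = DEFAULT_RELATIONS) {
  length(go_ancestors(ontology, term, relations))
}

# Full ancestor closure for every non-obsolete term, computed in one pass in
# topological order. Returns a named list: term id -> integer indices into
# ontology$terms$id of its ancestors. Used by propagation and scoring where
# per-term BFS would be wasteful.
ancestor_closure <- function(ontology, relations = DEFAULT_RELATIONS) {
  ids <- ontology$terms$id
  n <- length(ids)
  idx <- seq_len(n); names(idx) <- ids
  e <- ontology$edges[ontology$edges$relation %in% relations, , drop = FALSE]
  ci <- idx[e$child]; pi <- idx[e$parent]
  parents_of <- split(pi, factor(ci, levels = seq_len(n)))
  children_of <- split(ci, factor(pi, levels = seq_len(n)))
  out_deg <- tabulate(ci, nbins = n)
  anc <- vector("list", n)
  queue <- which(out_deg == 0L)
  order_ <- integer(0)
  deg <- out_deg
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    order_ <- c(order_, v)
    for (c in children_of[[v]]) {
      deg[c] <- deg[c] - 1L
      if (deg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order_) < n)
    stop("cycle detected in ontology graph involving term ",
         ids[setdiff(seq_len(n), order_)[1]])
  for (v in order_) {
    ps <- parents_of[[v]]
    if (!length(ps)) { anc[[v]] <- integer(0); next }
    anc[[v]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  names(anc) <- ids
  anc
}

# Descendant sets (inclusive of the term itself) for every term.
descendant_closure <- function(ontology, relations = DEFAULT_RELATIONS) {
  anc <- ancestor_closure(ontology, relations)
  ids <- ontology$terms$id
  n <- length(ids)
  desc <- vector("list", n)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in seq_len(n)) for (a in anc[[v]]) desc[[a]] <- c(desc[[a]], v)
  names(desc) <- ids
  lapply(desc, unique)
}
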