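#' Read a GAF 2.x gene association file
#'
#' Keeps rows of the requested aspect (`C`/`P`/`F` mapped onto the GO
#' namespaces), drops rows whose qualifier contains `NOT`, and collapses
#' duplicate (protein, term) pairs. Malformed rows (< 15 columns) are
#' skipped with a warning reporting their count.
#'
#' @param file Path to a GAF 2.x file; comment lines start with `!`.
#' @param namespace One of `"cellular_component"`, `"biological_process"`,
#'   `"molecular_function"`.
#' @param ontology Optional `go_ontology`; when given, alt ids are
#'   canonicalised and annotations to terms absent from the graph are
#'   dropped with a warning.
#' @return An `annotation_corpus`: list with `direct` (named list mapping
#'   protein id -> character vector of directly annotated term ids) and
#'   `namespace`.
#' @export
read_gaf <- function(file, namespace = "cellular_component", ontology = NULL) {
  aspect <- switch(namespace,
                   cellular_component = "C",
                   biological_process = "P",
                   molecular_function = "F",
                   stop("unknown namespace: ", namespace))
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 15L
  if (any(!ok))
    warning(sum(!ok), " malformed GAF row(s) skipped")
  fields <- fields[ok]
  if (!length(fields)) stop("no usable rows in GAF input")

  protein <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  asp <- vapply(fields, `[[`, "", 9L)

  keep <- asp == aspect & !grepl("(^|\\|)NOT(\\||$)", qualifier)
  protein <- protein[keep]; term <- term[keep]
  if (!length(protein))
    stop("no usable rows in GAF input for aspect ", aspect)

  if (!is.null(ontology)) {
    is_alt <- term %in% names(ontology$alt_ids)
    term[is_alt] <- unname(ontology$alt_ids[term[is_alt]])
    known <- term %in% ontology$terms$id
    if (any(!known))
      warning(sum(!known), " annotation(s) to terms absent from the ",
              "ontology dropped")
    protein <- protein[known]; term <- term[known]
    if (!length(protein)) stop("no usable rows after ontology filtering")
  }

  direct <- lapply(split(term, protein), unique)
  new_annotation_corpus(direct, namespace)
}

new_annotation_corpus <- function(direct, namespace) {
  structure(list(direct = direct, namespace = namespace),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("annotation_corpus:", length(x$direct), "proteins,",
      sum(lengths(x$direct)), "direct annotations,",
      "namespace", x$namespace, "\n")
  invisible(x)
}

#' Propagate annotation counts under the true-path rule
#'
#' Computes, for every non-obsolete term, the number of distinct proteins
#' annotated to the term or to any of its descendants: each protein
#' contributes once to every term in the union of its direct terms and
#' their ancestors (multiply assigned proteins are counted only once).
#'
#' @param ontology A `go_ontology`.
#' @param corpus An `annotation_corpus`.
#' @param proteins Optional protein id subset; counts are restricted to it.
#' @param relations Relation subset used for propagation.
#' @return A `term_counts` object: list with `counts` (named integer over
#'   all terms of the graph) and `total` (number of distinct proteins
#'   considered that carry at least one annotation).
#' @export
propagate_counts <- function(ontology, corpus, proteins = NULL,
                             relations = DEFAULT_RELATIONS) {
  prots <- names(corpus$direct)
  if (!is.null(proteins)) {
    prots <- intersect(proteins, prots)
    if (!length(prots))
      warning("protein subset shares no protein with the corpus; total is 0")
  }
  ids <- ontology$terms$id
  n <- length(ids)
  idx <- seq_len(n); names(idx) <- ids
  anc <- ancestor_closure(ontology, relations)
  counts <- integer(n)
  total <- 0L
  for (p in prots) {
    d <- corpus$direct[[p]]
    d <- d[d %in% ids]
    if (!length(d)) next
    di <- idx[d]
    u <- unique(c(di, unlist(anc[di], use.names = FALSE)))
    counts[u] <- counts[u] + 1L
    total <- total + 1L
  }
  names(counts) <- ids
  structure(list(counts = counts, total = total), class = "term_counts")
}

#' @export
print.term_counts <- function(x, ...) {
  cat("term_counts:", length(x$counts), "terms,", x$total,
      "annotated proteins\n")
  invisible(x)
}

#' Default pairwise enrichment margins for a three-fraction experiment
#'
#' The canonical cytosolic/membrane/nucleus design uses a 30% ratio margin
#' for nucleus-vs-cytosolic and membrane-vs-nucleus and a 50% margin for
#' membrane-vs-cytosolic.
#' @return Named numeric vector; names are `"a:b"` unordered fraction pairs.
#' @export
default_fraction_margins <- function() {
  c("cytosolic:nucleus" = 0.30,
    "membrane:nucleus" = 0.30,
    "cytosolic:membrane" = 0.50)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

#' Assign proteins to fractions from abundance ratios
#'
#' A protein is assigned to fraction F when its intensity ratio over every
#' other fraction exceeds the margin configured for that pair:
#' `I_F / I_G - 1 >= margin(F, G)` for all `G != F` (a zero denominator
#' with a positive numerator counts as infinite enrichment; 0/0 as zero).
#' Pair margins are symmetric. Proteins meeting no fraction's margins are
#' labelled `"non-specific"`.
#'
#' @param abundance Numeric matrix (or data.frame) of non-negative
#'   intensities; rows are proteins (rownames), columns are fractions.
#' @param margins Named numeric vector of pairwise margins with names
#'   `"a:b"` (order-free), a single unnamed numeric applied to all pairs,
#'   or `NULL` to use [default_fraction_margins()] when the columns are
#'   exactly the canonical cytosolic/membrane/nucleus trio.
#' @param method `"ratio"` (default) interprets a margin m as requiring
#'   `I_A/I_B >= 1 + m`; `"share"` requires `I_A/(I_A+I_B) >= (1 + m)/2`.
#' @return Named character vector mapping every protein to a fraction name
#'   or `"non-specific"`.
#' @export
assign_fractions <- function(abundance, margins = NULL,
                             method = c("ratio", "share")) {
  method <- match.arg(method)
  m <- as.matrix(abundance)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) stop("abundance table must have protein rownames")
  fractions <- colnames(m)
  if (length(fractions) < 2) stop("need at least 2 fraction columns")
  if (any(!is.finite(m))) stop("intensities must be finite")
  if (any(m < 0)) stop("negative intensity in abundance table")

  if (is.null(margins)) {
    if (setequal(fractions, c("cytosolic", "membrane", "nucleus"))) {
      margins <- default_fraction_margins()
    } else {
      stop("margins must be given for non-canonical fraction sets")
    }
  }
  if (is.null(names(margins))) {
    if (length(margins) != 1) stop("unnamed margins must be a single value")
    pairs <- utils::combn(sort(fractions), 2)
    val <- margins
    margins <- stats::setNames(rep(val, ncol(pairs)),
                               apply(pairs, 2, paste, collapse = ":"))
  }
  if (any(margins <= 0)) stop("margins must be > 0")
  named_fracs <- unique(unlist(strsplit(names(margins), ":", fixed = TRUE)))
  unknown <- setdiff(named_fracs, fractions)
  if (length(unknown))
    stop("unknown fraction in margins: ", paste(unknown, collapse = ", "))

  get_margin <- function(a, b) {
    key <- pair_key(a, b)
    if (!key %in% names(margins))
      stop("no margin configured for fraction pair ", key)
    margins[[key]]
  }

  enr <- function(ia, ib) {
    if (method == "ratio") {
      if (ib == 0) return(if (ia > 0) Inf else 0)
      ia / ib - 1
    } else {
      if (ia + ib == 0) return(0)
      2 * ia / (ia + ib) - 1
    }
  }

  out <- vapply(seq_len(nrow(m)), function(r) {
    for (f in fractions) {
      ok <- TRUE
      for (g in setdiff(fractions, f)) {
        if (enr(m[r, f], m[r, g]) < get_margin(f, g)) { ok <- FALSE; break }
      }
      if (ok) return(f)
    }
    "non-specific"
  }, character(1))
  stats::setNames(out, rownames(m))
}

#' Per-dataset propagated term counts
#'
#' Splits the proteins of a fraction assignment by label (each fraction
#' plus `"non-specific"`) and computes one propagated [propagate_counts()]
#' index per label. Each index's `total` counts the label's proteins that
#' carry at least one annotation in the namespace (unannotated proteins
#' cannot contribute to any term count).
#'
#' @param ontology A `go_ontology`.
#' @param corpus An `annotation_corpus`.
#' @param assignment Named character vector from [assign_fractions()].
#' @param relations Relation subset used for propagation.
#' @return Named list of `term_counts`, one per label.
#' @export
dataset_counts <- function(ontology, corpus, assignment,
                           relations = DEFAULT_RELATIONS) {
  labels <- sort(unique(assignment))
  out <- lapply(labels, function(lab) {
    prots <- names(assignment)[assignment == lab]
    idxobj <- suppressWarnings(
      propagate_counts(ontology, corpus, proteins = prots,
                       relations = relations))
    if (idxobj$total == 0L)
      warning("dataset '", lab, "' has no annotated proteins")
    idxobj
  })
  stats::setNames(out, labels)
}

#' Read an abundance table
#'
#' TSV with header `protein<TAB>fraction1<TAB>...`; returns a numeric
#' matrix with protein rownames.
#' @param file Path to the TSV file.
#' @return Numeric matrix, rows proteins, columns fractions.
#' @export
read_abundance <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a fraction assignment as a two-column TSV
#' @param assignment Named character vector from [assign_fractions()].
#' @param file Output path.
#' @export
write_assignment <- function(assignment, file) {
  utils::write.table(
    data.frame(protein = names(assignment), fraction = unname(assignment)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
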