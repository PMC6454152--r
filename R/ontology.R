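# Wang-style semantic similarity over OBO term DAGs.
#
# Each anchor term h induces tau-values over its ancestor closure T_h:
#   tau_h(h) = 1
#   tau_h(t) = max over children t' of t within T_h of w_e(t' -> t) * tau_h(t')
# equivalently the maximum product of edge weights over directed paths h -> t.
# Term similarity is the shared-ancestor contribution ratio; entity similarity
# is the best-match average over the two annotation sets.

#' Parse an OBO flat file into an OntologyDAG
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas, keeping non-obsolete terms and the
#' edge relations present in `weights` (`is_a` lines and
#' `relationship: <rel> <id>` lines). Edges with an unconfigured relation or
#' an endpoint that is not a parsed term are skipped, with a message
#' reporting the count. A cycle is a hard error.
#'
#' @param path path to an OBO file.
#' @param weights named numeric vector of semantic weights per relation,
#'   default `c(is_a = 0.8, part_of = 0.6)` (Gene Ontology convention; use
#'   `c(is_a = 0.7)` for phenotype ontologies).
#' @param namespace optional namespace name (e.g. `"biological_process"`);
#'   when given, only terms declaring it are kept. Default keeps all
#'   namespaces in one DAG.
#' @return An [OntologyDAG-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: T:2", "is_a: T:1", "", "[Term]", "id: T:1"), obo)
#' parseOBO(obo)
#' @export
parseOBO <- function(path, weights = c(is_a = 0.8, part_of = 0.6),
                     namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  keep <- lines[starts] == "[Term]"

  terms <- character()
  child <- character(); parent <- character(); relation <- character()
  nSkipped <- 0L
  for (s in which(keep)) {
    block <- lines[starts[s]:ends[s]]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE)[1])
    if (is.na(id)) next
    id <- sub("\\s*(!.*)?$", "", id)
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    if (!is.null(namespace)) {
      ns <- sub("^namespace:\\s*", "", grep("^namespace:", block, value = TRUE)[1])
      if (is.na(ns) || ns != namespace) next
    }
    terms <- c(terms, id)
    for (l in grep("^is_a:", block, value = TRUE)) {
      p <- sub("\\s*(!.*)?$", "", sub("^is_a:\\s*", "", l))
      child <- c(child, id); parent <- c(parent, p); relation <- c(relation, "is_a")
    }
    for (l in grep("^relationship:", block, value = TRUE)) {
      f <- strsplit(sub("\\s*!.*$", "", sub("^relationship:\\s*", "", l)), "\\s+")[[1]]
      if (length(f) < 2) next
      child <- c(child, id); parent <- c(parent, f[2]); relation <- c(relation, f[1])
    }
  }
  ed <- data.frame(child = child, parent = parent, relation = relation,
                   stringsAsFactors = FALSE)
  ok <- ed$relation %in% names(weights) & ed$child %in% terms &
    ed$parent %in% terms & ed$child != ed$parent
  nSkipped <- sum(!ok)
  if (nSkipped > 0)
    message("parseOBO: skipped ", nSkipped,
            " edge(s) with unconfigured relation or missing endpoint")
  ontologyDAG(terms = terms, edges = ed[ok, , drop = FALSE], weights = weights)
}

#' Read a two-column TSV annotation file (entity, term)
#'
#' Lines starting with `#` are comments. Annotations to terms absent from
#' `dag` are removed and entities left without terms are dropped (reported
#' via the returned [AnnotationMap-class]).
#'
#' @param path path to a TSV file with columns entity_id, term_id.
#' @param dag [OntologyDAG-class] against which terms are validated.
#' @return An [AnnotationMap-class].
#' @export
readAnnotations <- function(path, dag) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2
  if (any(bad)) warning("skipping ", sum(bad), " malformed annotation line(s)")
  fields <- fields[!bad]
  ent <- vapply(fields, `[`, "", 1L)
  trm <- vapply(fields, `[`, "", 2L)
  annotationMap(split(trm, ent), dag = dag)
}

# Internal: tau DP for one anchor given the DAG's igraph.  Returns a named
# numeric over the ancestor closure of h.
.tauDP <- function(dag, h) {
  g <- dag@graph
  # ancestor closure: everything reachable child -> parent from h
  anc <- igraph::subcomponent(g, h, mode = "out")
  sub <- igraph::induced_subgraph(g, anc)
  ord <- igraph::topo_sort(sub, mode = "out")  # children before parents
  nm <- igraph::V(sub)$name
  tau <- stats::setNames(numeric(length(nm)), nm)
  tau[h] <- 1
  ordNames <- igraph::V(sub)$name[as.integer(ord)]
  for (t in ordNames) {
    if (t == h) next
    ein <- igraph::incident(sub, t, mode = "in")  # edges child -> t
    heads <- igraph::tail_of(sub, ein)$name
    tau[t] <- max(igraph::E(sub)[ein]$weight * tau[heads])
  }
  tau
}

#' Tau-values of an anchor term
#'
#' Dynamic-programming computation of the semantic contribution of every
#' ancestor of `h` (including `h` itself, with value 1): the best product of
#' edge weights over directed paths from `h`.
#'
#' @param dag an [OntologyDAG-class].
#' @param h anchor term id.
#' @return A [TauVector-class].
#' @export
tauValues <- function(dag, h) {
  if (!h %in% dag@terms) stop("term not in ontology: ", h)
  new("TauVector", anchor = h, tau = .tauDP(dag, h))
}

#' Semantic similarity of two ontology terms
#'
#' Ratio of the summed tau contributions of the shared ancestors to the total
#' tau mass of both terms:
#' \deqn{s(h, b) = \frac{\sum_{t \in T_h \cap T_b} (\tau_h(t) + \tau_b(t))}
#'                     {\sum_{t \in T_h} \tau_h(t) + \sum_{t \in T_b} \tau_b(t)}}
#' Symmetric, in [0, 1], and 1 for identical terms.
#'
#' @param dag an [OntologyDAG-class].
#' @param h,b term ids.
#' @return similarity in [0, 1].
#' @export
termSimilarity <- function(dag, h, b) {
  th <- tauValues(dag, h)@tau
  tb <- tauValues(dag, b)@tau
  .termSimFromTau(th, tb)
}

.termSimFromTau <- function(th, tb) {
  common <- intersect(names(th), names(tb))
  denom <- sum(th) + sum(tb)
  if (!length(common)) return(0)
  (sum(th[common]) + sum(tb[common])) / denom
}

#' Similarity between one term and a term set
#'
#' The best pairwise similarity of `t` with any member of `terms`.
#'
#' @param dag an [OntologyDAG-class].
#' @param t a term id.
#' @param terms nonempty character vector of term ids.
#' @return similarity in [0, 1].
#' @export
termSetSimilarity <- function(dag, t, terms) {
  if (!length(terms)) stop("term set must be nonempty")
  max(vapply(terms, function(b) termSimilarity(dag, t, b), numeric(1)))
}

#' Semantic similarity of two annotated entities
#'
#' Best-match average of the pairwise term similarities between the two
#' annotation sets:
#' \deqn{s(g_1, g_2) = \frac{\sum_i \max_j s(t_{1i}, t_{2j}) +
#'                           \sum_j \max_i s(t_{2j}, t_{1i})}{n_1 + n_2}}
#'
#' @param dag an [OntologyDAG-class].
#' @param set1,set2 nonempty character vectors of term ids.
#' @return similarity in [0, 1]; symmetric; 1 when `set1 == set2`.
#' @export
entitySimilarity <- function(dag, set1, set2) {
  if (!length(set1) || !length(set2))
    stop("annotation sets must be nonempty; filter unannotated entities first")
  P <- outer(set1, set2,
             Vectorize(function(a, b) termSimilarity(dag, a, b)))
  .entitySimFromPairs(P)
}

.entitySimFromPairs <- function(P) {
  (sum(apply(P, 1, max)) + sum(apply(P, 2, max))) / (nrow(P) + ncol(P))
}

#' Pairwise entity similarity matrix from ontology annotations
#'
#' Computes the full symmetric matrix of [entitySimilarity()] values over a
#' set of annotated entities. Tau-vectors and pairwise term similarities are
#' computed once (over the sorted union of all annotated terms) and reused,
#' so the cost is one tau DP per distinct term plus one pass per entity pair.
#' Entities missing from the map or annotated only after filtering are
#' dropped with a warning.
#'
#' @param dag an [OntologyDAG-class].
#' @param annotations an [AnnotationMap-class].
#' @param entities ordered entity labels; default all annotated entities
#'   (sorted).
#' @return A [SimilarityMatrix-class].
#' @export
similarityMatrix <- function(dag, annotations, entities = annotatedEntities(annotations)) {
  known <- entities %in% annotatedEntities(annotations)
  if (!all(known)) {
    warning("dropping ", sum(!known), " entit(ies) without annotations: ",
            paste(utils::head(entities[!known], 5), collapse = ", "))
    entities <- entities[known]
  }
  if (!length(entities)) stop("no annotated entities left")
  sets <- annotations@annotations[entities]

  termsUsed <- sort(unique(unlist(sets)))
  tauCache <- lapply(termsUsed, function(t) .tauDP(dag, t))
  names(tauCache) <- termsUsed
  u <- length(termsUsed)
  # pairwise term similarity over the used terms
  TS <- matrix(0, u, u, dimnames = list(termsUsed, termsUsed))
  for (i in seq_len(u)) {
    for (j in i:u) {
      v <- .termSimFromTau(tauCache[[i]], tauCache[[j]])
      TS[i, j] <- v; TS[j, i] <- v
    }
  }
  # data-quality note: entities annotated only to ancestor-free (root) terms
  # are degenerate -- they score 1 against any entity sharing that root
  isolated <- termsUsed[vapply(tauCache, length, 1L) == 1L]
  rootOnly <- entities[vapply(sets, function(s) all(s %in% isolated), TRUE)]
  if (length(rootOnly) > 1)
    message("similarityMatrix: ", length(rootOnly),
            " entities are annotated only to root-level terms")

  nE <- length(entities)
  S <- matrix(1, nE, nE, dimnames = list(entities, entities))
  for (i in seq_len(nE)) {
    for (j in seq_len(nE)) {
      if (j <= i) next
      v <- .entitySimFromPairs(TS[sets[[i]], sets[[j]], drop = FALSE])
      S[i, j] <- v; S[j, i] <- v
    }
  }
  # guard against tiny negative/overshoot from arithmetic (none expected)
  S[S < 0] <- 0; S[S > 1] <- 1
  diag(S) <- 1
  new("SimilarityMatrix", labels = entities, values = S)
}

#' Write / read a SimilarityMatrix as TSV
#'
#' TSV with a header row of labels and a leading label column; round-trips
#' through [readSimilarityMatrix()].
#'
#' @param x a [SimilarityMatrix-class].
#' @param path output file path.
#' @export
writeSimilarityMatrix <- function(x, path) {
  df <- data.frame(label = x@labels, x@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSimilarityMatrix
#' @return `readSimilarityMatrix` returns the [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  similarityMatrixFromValues(v, labels)
}
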