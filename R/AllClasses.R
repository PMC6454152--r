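#' @import methods
#' @importFrom Matrix Matrix Diagonal rowSums colSums forceSymmetric drop0 t
NULL

# ---------------------------------------------------------------------------
# OntologyDAG: a typed, weighted, acyclic term graph (GO- or HPO-like).
# Edges are stored child -> parent; each relation type carries one weight
# in (0, 1) used by the Wang-style tau recursion.
# ---------------------------------------------------------------------------

#' OntologyDAG class
#'
#' Directed acyclic graph of ontology terms with typed, weighted edges.
#' Edges point from child to parent (towards the root) and each relation
#' type (`is_a`, `part_of`, ...) has a single semantic weight in (0, 1).
#'
#' @slot terms character vector of term identifiers.
#' @slot edges data.frame with columns `child`, `parent`, `relation`.
#' @slot weights named numeric vector mapping relation type to its weight.
#' @slot graph internal igraph object (child -> parent, `weight` edge attr).
#'
#' @seealso [parseOBO()], [randomDAG()], [tauValues()]
#' @export
setClass("OntologyDAG",
  representation(
    terms = "character",
    edges = "data.frame",
    weights = "numeric",
    graph = "ANY"
  )
)

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  ed <- object@edges
  if (!all(c("child", "parent", "relation") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns child, parent, relation")
  else {
    if (anyDuplicated(object@terms))
      msgs <- c(msgs, "duplicated term identifiers")
    if (nrow(ed)) {
      if (any(ed$child == ed$parent))
        msgs <- c(msgs, "self-edges are not allowed")
      if (!all(ed$relation %in% names(object@weights)))
        msgs <- c(msgs, "every edge relation must have a configured weight")
      if (!all(c(ed$child, ed$parent) %in% object@terms))
        msgs <- c(msgs, "edge endpoints must be listed terms")
    }
    if (length(object@weights) &&
        (any(object@weights <= 0) || any(object@weights >= 1)))
      msgs <- c(msgs, "relation weights must lie in (0, 1)")
    if (inherits(object@graph, "igraph") && !igraph::is_dag(object@graph))
      msgs <- c(msgs, "term graph contains a cycle")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OntologyDAG
#'
#' @param terms character vector of term identifiers.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (child -> parent, i.e. towards the root).
#' @param weights named numeric vector of per-relation semantic weights in
#'   (0, 1), e.g. `c(is_a = 0.8, part_of = 0.6)`.
#' @return An [OntologyDAG-class] object.
#' @export
ontologyDAG <- function(terms, edges = NULL, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  terms <- sort(unique(as.character(terms)))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$child, to = edges$parent,
                   weight = unname(weights[edges$relation]),
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (!length(bad)) bad <- edges$child[edges$child == edges$parent]
    stop("cycle detected in ontology involving term(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  new("OntologyDAG", terms = terms, edges = edges, weights = weights, graph = g)
}

#' @describeIn OntologyDAG-class number of terms
#' @param x,object an `OntologyDAG`
#' @export
setMethod("length", "OntologyDAG", function(x) length(x@terms))

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG with", length(object@terms), "terms and",
      nrow(object@edges), "edges\n")
  cat("  relations:",
      paste(sprintf("%s=%.2f", names(object@weights), object@weights),
            collapse = ", "), "\n")
})

#' Term identifiers of an ontology DAG
#' @param dag an [OntologyDAG-class]
#' @return character vector of term ids.
#' @export
ontologyTerms <- function(dag) dag@terms

# ---------------------------------------------------------------------------
# AnnotationMap: entity -> set of ontology terms
# ---------------------------------------------------------------------------

#' AnnotationMap class
#'
#' Maps entities (genes or diseases) to non-empty sets of ontology terms.
#' Entities whose annotations were entirely filtered out are recorded in
#' `dropped`.
#'
#' @slot annotations named list; each element a character vector of term ids.
#' @slot dropped character vector of entities removed for lacking terms.
#' @export
setClass("AnnotationMap",
  representation(annotations = "list", dropped = "character")
)

setValidity("AnnotationMap", function(object) {
  ann <- object@annotations
  if (length(ann) && is.null(names(ann))) return("annotations must be named")
  if (any(lengths(ann) == 0)) return("entities with empty term sets must be dropped")
  TRUE
})

#' Construct an AnnotationMap, dropping entities with no valid terms
#'
#' @param annotations named list of character vectors (entity -> term ids).
#' @param dag optional [OntologyDAG-class]; terms absent from it are removed
#'   (with a message reporting the count).
#' @return An [AnnotationMap-class].
#' @export
annotationMap <- function(annotations, dag = NULL) {
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  nUnknown <- 0L
  if (!is.null(dag)) {
    annotations <- lapply(annotations, function(x) {
      keep <- x %in% dag@terms
      nUnknown <<- nUnknown + sum(!keep)
      x[keep]
    })
  }
  if (nUnknown > 0)
    message("annotationMap: removed ", nUnknown, " annotation(s) to unknown terms")
  empty <- names(annotations)[lengths(annotations) == 0]
  if (length(empty)) {
    warning("dropping ", length(empty), " entit(ies) without annotations: ",
            paste(utils::head(empty, 5), collapse = ", "),
            if (length(empty) > 5) ", ..." else "")
    annotations <- annotations[lengths(annotations) > 0]
  }
  annotations <- annotations[order(names(annotations))]
  new("AnnotationMap", annotations = annotations, dropped = as.character(empty))
}

setMethod("show", "AnnotationMap", function(object) {
  cat("AnnotationMap:", length(object@annotations), "entities,",
      length(unique(unlist(object@annotations))), "distinct terms",
      if (length(object@dropped)) sprintf("(%d dropped)", length(object@dropped)) else "",
      "\n")
})

#' @rdname annotationMap
#' @param map an `AnnotationMap`
#' @param entity entity identifier
#' @return `annotatedTerms` returns the term set of one entity.
#' @export
annotatedTerms <- function(map, entity) {
  if (!entity %in% names(map@annotations)) stop("unknown entity: ", entity)
  map@annotations[[entity]]
}

#' @rdname annotationMap
#' @return `annotatedEntities` returns all entity identifiers.
#' @export
annotatedEntities <- function(map) names(map@annotations)

# ---------------------------------------------------------------------------
# TauVector: Wang tau-values of one anchor term over its ancestor closure
# ---------------------------------------------------------------------------

#' TauVector class
#'
#' Semantic contribution values of all terms in the ancestor closure of an
#' anchor term: the anchor gets 1, every ancestor the best path product of
#' edge weights from the anchor.
#'
#' @slot anchor the anchor term id.
#' @slot tau named numeric vector of tau-values in (0, 1].
#' @export
setClass("TauVector", representation(anchor = "character", tau = "numeric"))

setValidity("TauVector", function(object) {
  tv <- object@tau
  if (is.null(names(tv))) return("tau must be named")
  if (!object@anchor %in% names(tv)) return("anchor must be in tau domain")
  if (abs(tv[[object@anchor]] - 1) > 0) return("tau of the anchor must be 1")
  if (any(tv <= 0) || any(tv > 1)) return("tau values must lie in (0, 1]")
  TRUE
})

setMethod("show", "TauVector", function(object) {
  cat("TauVector for", object@anchor, "over", length(object@tau), "terms\n")
})

# ---------------------------------------------------------------------------
# SimilarityMatrix: symmetric [0,1] affinity over diseases or genes
# ---------------------------------------------------------------------------

#' SimilarityMatrix class
#'
#' Symmetric pairwise similarity in [0, 1] over a labelled set of entities,
#' with unit diagonal. Used as the adjacency matrix of the disease- or
#' gene-similarity affinity graph.
#'
#' @slot labels ordered entity labels.
#' @slot values numeric matrix of similarities.
#' @export
setClass("SimilarityMatrix",
  representation(labels = "character", values = "matrix")
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "matrix must be square")
  if (length(object@labels) != nrow(v))
    msgs <- c(msgs, "labels must match matrix dimension")
  if (anyDuplicated(object@labels)) msgs <- c(msgs, "labels must be unique")
  if (length(v)) {
    if (max(abs(v - base::t(v))) > 1e-12) msgs <- c(msgs, "matrix must be symmetric")
    if (min(v) < 0 || max(v) > 1) msgs <- c(msgs, "values must lie in [0, 1]")
    if (max(abs(diag(v) - 1)) > 1e-12) msgs <- c(msgs, "diagonal must equal 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityMatrix
#' @param values square numeric matrix.
#' @param labels entity labels (defaults to `rownames(values)`).
#' @return A [SimilarityMatrix-class].
#' @export
similarityMatrixFromValues <- function(values, labels = rownames(values)) {
  if (is.null(labels)) stop("labels required")
  values <- as.matrix(values)
  values <- (values + base::t(values)) / 2
  dimnames(values) <- list(labels, labels)
  new("SimilarityMatrix", labels = as.character(labels), values = values)
}

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat("SimilarityMatrix over", length(object@labels), "entities",
      if (length(off)) sprintf("(off-diagonal mean %.3f)", mean(off)) else "", "\n")
})

#' @describeIn SimilarityMatrix-class coerce to a base matrix
#' @param x a `SimilarityMatrix`
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)

#' Labels of a SimilarityMatrix
#' @param x a [SimilarityMatrix-class]
#' @export
simLabels <- function(x) x@labels

# ---------------------------------------------------------------------------
# AssociationMatrix: n x m non-negative disease-gene association matrix
# ---------------------------------------------------------------------------

#' AssociationMatrix class
#'
#' Labelled n x m non-negative matrix of disease-gene association strengths.
#' Binary after construction from curated records; prior augmentation may
#' introduce fractional weights.
#'
#' @slot assoc sparse `dgCMatrix` of association weights (rows = diseases).
#' @slot diseases ordered disease labels.
#' @slot genes ordered gene labels.
#' @export
setClass("AssociationMatrix",
  representation(assoc = "ANY", diseases = "character", genes = "character")
)

setValidity("AssociationMatrix", function(object) {
  msgs <- character()
  A <- object@assoc
  if (nrow(A) != length(object@diseases) || ncol(A) != length(object@genes))
    msgs <- c(msgs, "label lengths must match matrix dimensions")
  if (anyDuplicated(object@diseases)) msgs <- c(msgs, "disease labels must be unique")
  if (anyDuplicated(object@genes)) msgs <- c(msgs, "gene labels must be unique")
  if (length(A) && min(A) < 0) msgs <- c(msgs, "association weights must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationMatrix
#'
#' @param mat numeric or Matrix matrix of non-negative association weights;
#'   rows are diseases, columns genes.
#' @param diseases,genes labels (default taken from `dimnames(mat)`).
#' @return An [AssociationMatrix-class].
#' @export
associationMatrix <- function(mat, diseases = rownames(mat), genes = colnames(mat)) {
  if (is.null(diseases) || is.null(genes)) stop("disease and gene labels required")
  A <- as(as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  dimnames(A) <- list(diseases, genes)
  new("AssociationMatrix", assoc = A,
      diseases = as.character(diseases), genes = as.character(genes))
}

setMethod("show", "AssociationMatrix", function(object) {
  A <- object@assoc
  cat("AssociationMatrix:", nrow(A), "diseases x", ncol(A), "genes,",
      sum(A != 0), "associations",
      if (isBinary(object)) "(binary)" else "(weighted)", "\n")
})

#' @describeIn AssociationMatrix-class dense matrix of association weights
#' @param x an `AssociationMatrix`
#' @param ... unused
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) as.matrix(x@assoc))

#' @describeIn AssociationMatrix-class `c(n diseases, m genes)`
#' @export
setMethod("dim", "AssociationMatrix", function(x) dim(x@assoc))

#' Accessors for disease and gene labels
#'
#' @param x an [AssociationMatrix-class], [JointLaplacian-class] or
#'   [Embedding-class]
#' @return character vector of labels.
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))

#' @rdname diseaseNames
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname diseaseNames
#' @export
setMethod("diseaseNames", "AssociationMatrix", function(x) x@diseases)

#' @rdname diseaseNames
#' @export
setMethod("geneNames", "AssociationMatrix", function(x) x@genes)

#' Is the association matrix binary (0/1)?
#' @param x an [AssociationMatrix-class]
#' @export
isBinary <- function(x) {
  v <- x@assoc@x
  length(v) == 0 || all(v %in% c(0, 1))
}

# ---------------------------------------------------------------------------
# Hyperparameters
# ---------------------------------------------------------------------------

#' Hyperparameters class
#'
#' Number of requested eigenvectors `k` and the affinity-graph weights
#' `alpha` (disease similarity) and `beta` (gene similarity).
#'
#' @slot k integer >= 2, number of smallest eigenvectors requested.
#' @slot alpha non-negative weight of the disease-similarity Laplacian.
#' @slot beta non-negative weight of the gene-similarity Laplacian.
#' @export
setClass("Hyperparameters",
  representation(k = "integer", alpha = "numeric", beta = "numeric")
)

setValidity("Hyperparameters", function(object) {
  if (object@k < 2) return("k must be >= 2")
  if (object@alpha < 0 || object@beta < 0) return("alpha and beta must be >= 0")
  TRUE
})

#' Construct embedding hyperparameters
#' @param k number of eigenvectors (>= 2); `k - 1` informative dimensions are
#'   retained after removing the constant null eigenvector.
#' @param alpha,beta non-negative regularization weights of the disease and
#'   gene affinity graphs.
#' @return A [Hyperparameters-class].
#' @export
hyperparameters <- function(k = 30, alpha = 0.2, beta = alpha) {
  new("Hyperparameters", k = as.integer(k), alpha = alpha, beta = beta)
}

setMethod("show", "Hyperparameters", function(object) {
  cat(sprintf("Hyperparameters: k=%d, alpha=%g, beta=%g\n",
              object@k, object@alpha, object@beta))
})

# ---------------------------------------------------------------------------
# JointLaplacian
# ---------------------------------------------------------------------------

#' JointLaplacian class
#'
#' The symmetric (n+m) x (n+m) Laplacian of the joint graph: bipartite
#' association edges between diseases and genes plus alpha- and beta-weighted
#' affinity edges within the disease and gene blocks. Rows sum to zero and
#' the matrix is positive semidefinite.
#'
#' @slot matrix sparse symmetric Matrix.
#' @slot diseases,genes node labels of the two blocks.
#' @slot alpha,beta the affinity weights used.
#' @export
setClass("JointLaplacian",
  representation(matrix = "ANY", diseases = "character", genes = "character",
                 alpha = "numeric", beta = "numeric")
)

setValidity("JointLaplacian", function(object) {
  L <- object@matrix
  msgs <- character()
  n <- length(object@diseases); m <- length(object@genes)
  if (nrow(L) != n + m || ncol(L) != n + m)
    msgs <- c(msgs, "matrix dimension must equal n + m")
  if (max(abs(L - Matrix::t(L))) > 1e-10) msgs <- c(msgs, "must be symmetric")
  if (max(abs(Matrix::rowSums(L))) > 1e-8)
    msgs <- c(msgs, "rows must sum to zero")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "JointLaplacian", function(object) {
  cat(sprintf("JointLaplacian: %d diseases + %d genes (alpha=%g, beta=%g), %d nonzeros\n",
              length(object@diseases), length(object@genes),
              object@alpha, object@beta, Matrix::nnzero(object@matrix)))
})

#' @rdname diseaseNames
#' @export
setMethod("diseaseNames", "JointLaplacian", function(x) x@diseases)

#' @rdname diseaseNames
#' @export
setMethod("geneNames", "JointLaplacian", function(x) x@genes)

#' @describeIn JointLaplacian-class the Laplacian as a sparse Matrix
#' @param x a `JointLaplacian`
#' @param ... unused
#' @export
setMethod("as.matrix", "JointLaplacian", function(x, ...) as.matrix(x@matrix))

# ---------------------------------------------------------------------------
# Embedding
# ---------------------------------------------------------------------------

#' Embedding class
#'
#' Joint spectral embedding of diseases and genes. The stacked coordinate
#' matrix has mutually orthogonal columns each of norm sqrt(2) (so that
#' crossprod equals twice the identity); null-space (constant) eigenvectors
#' have been removed.
#'
#' @slot diseaseCoords n x d matrix of disease coordinates.
#' @slot geneCoords m x d matrix of gene coordinates.
#' @slot eigenvalues the k computed smallest eigenvalues, ascending.
#' @slot nDropped number of null-space eigenvectors removed (1 for a
#'   connected joint graph).
#' @slot hp the [Hyperparameters-class] used.
#' @export
setClass("Embedding",
  representation(diseaseCoords = "matrix", geneCoords = "matrix",
                 eigenvalues = "numeric", nDropped = "integer",
                 hp = "Hyperparameters")
)

setValidity("Embedding", function(object) {
  msgs <- character()
  if (ncol(object@diseaseCoords) != ncol(object@geneCoords))
    msgs <- c(msgs, "disease and gene blocks must share dimensionality")
  if (is.unsorted(object@eigenvalues)) msgs <- c(msgs, "eigenvalues must be ascending")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Embedding", function(object) {
  cat(sprintf("Embedding: %d diseases + %d genes in %d dimensions (k=%d, %d null vector(s) dropped)\n",
              nrow(object@diseaseCoords), nrow(object@geneCoords),
              ncol(object@diseaseCoords), object@hp@k, object@nDropped))
})

#' @rdname diseaseNames
#' @export
setMethod("diseaseNames", "Embedding", function(x) rownames(x@diseaseCoords))

#' @rdname diseaseNames
#' @export
setMethod("geneNames", "Embedding", function(x) rownames(x@geneCoords))

#' Coordinate and spectrum accessors for an Embedding
#'
#' @param x an [Embedding-class]
#' @return `diseaseCoords`/`geneCoords` return coordinate matrices with one
#'   row per entity; `embeddingEigenvalues` the computed eigenvalues
#'   (ascending, including dropped null values).
#' @export
diseaseCoords <- function(x) x@diseaseCoords

#' @rdname diseaseCoords
#' @export
geneCoords <- function(x) x@geneCoords

#' @rdname diseaseCoords
#' @export
embeddingEigenvalues <- function(x) x@eigenvalues

# ---------------------------------------------------------------------------
# Evaluation containers
# ---------------------------------------------------------------------------

#' FoldAssignment class
#'
#' Random partition of the known associations into cross-validation folds.
#'
#' @slot pairs data.frame with columns `disease`, `gene`, `fold`.
#' @slot nFolds number of folds.
#' @slot seed RNG seed used.
#' @export
setClass("FoldAssignment",
  representation(pairs = "data.frame", nFolds = "integer", seed = "integer")
)

setValidity("FoldAssignment", function(object) {
  f <- object@pairs$fold
  if (any(f < 1L) || any(f > object@nFolds)) return("fold ids out of range")
  sz <- tabulate(f, object@nFolds)
  if (diff(range(sz)) > 1L) return("fold sizes must differ by at most 1")
  TRUE
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment:", nrow(object@pairs), "associations in",
      object@nFolds, "folds (seed", object@seed, ")\n")
})

#' NegativeSampleSet class
#'
#' A set of disease-gene pairs with no known association, sampled uniformly
#' without replacement from the zero entries of an association matrix.
#'
#' @slot pairs data.frame with columns `disease`, `gene`.
#' @slot seed RNG seed used.
#' @export
setClass("NegativeSampleSet",
  representation(pairs = "data.frame", seed = "integer")
)

setMethod("show", "NegativeSampleSet", function(object) {
  cat("NegativeSampleSet:", nrow(object@pairs), "pairs (seed", object@seed, ")\n")
})

#' EvaluationResult class
#'
#' Cross-validation outcome for one disease class: per-replicate AUC over the
#' negative-sample sets, their mean, a pooled ROC curve, and a per-disease
#' diagnostic table.
#'
#' @slot diseaseClass `"multiple-gene"` or `"single-gene"`.
#' @slot aucPerReplicate AUC for each negative-sample replicate.
#' @slot meanAuc mean of the replicate AUCs (the headline score).
#' @slot roc two-column matrix (FPR, TPR) of the pooled ROC curve.
#' @slot perDiseaseAuc data.frame of per-disease mean AUCs (diagnostic).
#' @slot hp [Hyperparameters-class] used.
#' @slot usePrior whether prior augmentation was applied.
#' @export
setClass("EvaluationResult",
  representation(diseaseClass = "character", aucPerReplicate = "numeric",
                 meanAuc = "numeric", roc = "matrix",
                 perDiseaseAuc = "data.frame", hp = "Hyperparameters",
                 usePrior = "logical")
)

setValidity("EvaluationResult", function(object) {
  if (length(object@aucPerReplicate) &&
      (min(object@aucPerReplicate) < 0 || max(object@aucPerReplicate) > 1))
    return("AUC values must lie in [0, 1]")
  TRUE
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult [%s]: mean AUC %.3f over %d negative sets (prior: %s)\n",
              object@diseaseClass, object@meanAuc,
              length(object@aucPerReplicate),
              if (object@usePrior) "yes" else "no"))
})

#' Mean cross-validated AUC of an evaluation result
#' @param x an [EvaluationResult-class]
#' @export
meanAuc <- function(x) x@meanAuc

#' @rdname meanAuc
#' @export
aucPerReplicate <- function(x) x@aucPerReplicate

#' @rdname meanAuc
#' @return `rocPoints` returns the pooled ROC curve as an (FPR, TPR) matrix.
#' @export
rocPoints <- function(x) x@roc

# ---------------------------------------------------------------------------
# SyntheticSpec
# ---------------------------------------------------------------------------

#' SyntheticSpec class
#'
#' Parameters of the planted-block synthetic benchmark: diseases and genes
#' are assigned to latent blocks; associations are dense within blocks and
#' sparse across; similarity matrices mirror the blocks with additive noise.
#'
#' @slot nDiseases,nGenes problem size.
#' @slot nBlocks number of latent blocks.
#' @slot pIn,pOut within- and cross-block association probabilities.
#' @slot simBase,simCross within-/cross-block baseline similarity.
#' @slot simNoise full width of the uniform similarity noise.
#' @slot nSingle number of diseases forced to exactly one association.
#' @slot seed master seed; all generation is a pure function of the spec.
#' @export
setClass("SyntheticSpec",
  representation(nDiseases = "integer", nGenes = "integer", nBlocks = "integer",
                 pIn = "numeric", pOut = "numeric",
                 simBase = "numeric", simCross = "numeric", simNoise = "numeric",
                 nSingle = "integer", seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@pOut > object@pIn) msgs <- c(msgs, "pOut must be <= pIn")
  if (object@pIn > 1 || object@pOut < 0) msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (object@nBlocks > min(object@nDiseases, object@nGenes))
    msgs <- c(msgs, "nBlocks must be <= min(nDiseases, nGenes)")
  if (object@nSingle > object@nDiseases)
    msgs <- c(msgs, "nSingle must be <= nDiseases")
  if (object@simNoise < 0) msgs <- c(msgs, "simNoise must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a synthetic benchmark specification
#'
#' Defaults describe the standard recovery benchmark: 60 diseases, 120 genes,
#' 4 blocks, within-block association probability 0.3 against a 0.01
#' background, similarities 0.8 within / 0.1 across blocks with +-0.1 uniform
#' noise.
#'
#' @param nDiseases,nGenes,nBlocks problem size and block count.
#' @param pIn,pOut within-/cross-block association probabilities.
#' @param simBase,simCross,simNoise similarity block levels and uniform noise
#'   full width.
#' @param nSingle number of diseases forced to exactly one (within-block)
#'   association, for single-gene-disease benchmarks.
#' @param seed master seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nDiseases = 60, nGenes = 120, nBlocks = 4,
                          pIn = 0.3, pOut = 0.01,
                          simBase = 0.8, simCross = 0.1, simNoise = 0.2,
                          nSingle = 0, seed = 1) {
  new("SyntheticSpec",
      nDiseases = as.integer(nDiseases), nGenes = as.integer(nGenes),
      nBlocks = as.integer(nBlocks), pIn = pIn, pOut = pOut,
      simBase = simBase, simCross = simCross, simNoise = simNoise,
      nSingle = as.integer(nSingle), seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d x %d, %d blocks, pIn=%g pOut=%g, nSingle=%d, seed=%d\n",
              object@nDiseases, object@nGenes, object@nBlocks,
              object@pIn, object@pOut, object@nSingle, object@seed))
})
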