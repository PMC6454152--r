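# Joint graph Laplacian and its spectral embedding.
#
# For n diseases and m genes with association matrix A (weights a_ij >= 0),
# disease similarity S^d and gene similarity S^g, the joint Laplacian is
#
#   L = [ D_r + alpha * L_d      -A          ]
#       [ -A^T                   D_c + beta * L_g ]
#
# with D_r = diag(row sums of A), D_c = diag(column sums of A) and
# L_d, L_g the unnormalized Laplacians of the two affinity graphs. L is the
# Laplacian of the union graph (bipartite association edges plus scaled
# affinity edges), hence symmetric PSD with zero row sums. Minimizing
# Tr(Z^T L Z) subject to Z^T Z = 2 I_k is solved by the k eigenvectors of
# the smallest eigenvalues (Ky Fan), each scaled to norm sqrt(2).

#' Assemble the joint graph Laplacian
#'
#' @param A an [AssociationMatrix-class] (binary or prior-augmented).
#' @param Sd disease [SimilarityMatrix-class], labels matching `A`'s diseases.
#' @param Sg gene [SimilarityMatrix-class], labels matching `A`'s genes.
#' @param hp [Hyperparameters-class]; `alpha` scales the disease affinity
#'   graph, `beta` the gene affinity graph.
#' @return A [JointLaplacian-class].
#' @export
buildLaplacian <- function(A, Sd, Sg, hp) {
  if (!identical(Sd@labels, A@diseases))
    stop("disease labels of A and Sd disagree")
  if (!identical(Sg@labels, A@genes))
    stop("gene labels of A and Sg disagree")
  M <- A@assoc
  n <- nrow(M); m <- ncol(M)
  sd <- Sd@values; sg <- Sg@values
  Ld <- diag(rowSums(sd), n) - sd
  Lg <- diag(rowSums(sg), m) - sg
  L11 <- Matrix::Diagonal(x = Matrix::rowSums(M)) +
    hp@alpha * Matrix::Matrix(Ld, sparse = TRUE)
  L22 <- Matrix::Diagonal(x = Matrix::colSums(M)) +
    hp@beta * Matrix::Matrix(Lg, sparse = TRUE)
  L <- rbind(cbind(L11, -M), cbind(-Matrix::t(M), L22))
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)
  new("JointLaplacian", matrix = L, diseases = A@diseases, genes = A@genes,
      alpha = hp@alpha, beta = hp@beta)
}

# number of connected components of the joint graph underlying L
.nComponents <- function(L) {
  P <- L@matrix
  Matrix::diag(P) <- 0
  P <- Matrix::drop0(P)
  g <- igraph::graph_from_adjacency_matrix(abs(P) > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}

# k algebraically smallest eigenpairs; dense below denseLimit, otherwise
# shift-invert Lanczos (sparse Cholesky of L + sigma*I, igraph ARPACK).
.smallestEigen <- function(M, k, denseLimit = 500L, tol = 1e-9) {
  N <- nrow(M)
  if (N < denseLimit) {
    e <- eigen(as.matrix(M), symmetric = TRUE)
    idx <- N:(N - k + 1L)
    return(list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE]))
  }
  sigma <- 1e-6 * max(Matrix::diag(M))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M) +
                           Matrix::Diagonal(N, sigma), LDL = FALSE, perm = TRUE)
  fn <- function(x, extra) as.numeric(Matrix::solve(ch, x, system = "A"))
  res <- tryCatch(
    igraph::arpack(fn, sym = TRUE,
                   options = list(n = N, nev = k,
                                  ncv = min(N, max(2L * k + 2L, 20L)),
                                  which = "LM", maxiter = 3000, tol = tol)),
    error = function(e) stop("sparse eigensolver failed to converge (",
                             conditionMessage(e),
                             "); increase maxiter or lower k", call. = FALSE))
  vals <- 1 / res$values - sigma
  ord <- order(vals)
  V <- res$vectors
  if (is.null(dim(V))) V <- matrix(V, ncol = 1L)
  list(values = vals[ord], vectors = V[, ord, drop = FALSE])
}

# deterministic sign: make the entry of largest absolute value positive
# (earliest index on ties, which is what which.max returns)
.fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Solve the constrained trace minimization by eigendecomposition
#'
#' Computes the `k` algebraically smallest eigenpairs of the joint Laplacian,
#' scales each eigenvector to norm `sqrt(2)` (so the stacked coordinates Z
#' satisfy `t(Z) %*% Z = 2 I`), fixes signs deterministically, and removes
#' the null-space eigenvectors: one constant vector for a connected joint
#' graph, or all `c` component-indicator vectors when the graph has `c`
#' components (with a warning). The first n rows of the retained columns are
#' the disease coordinates, the last m rows the gene coordinates.
#'
#' @param L a [JointLaplacian-class].
#' @param hp [Hyperparameters-class]; `hp@k` eigenvectors are requested and
#'   `k - c` informative dimensions retained.
#' @param denseLimit below this total node count a dense eigendecomposition
#'   is used; above it, a shift-invert sparse Lanczos solver.
#' @return An [Embedding-class].
#' @export
solveEmbedding <- function(L, hp, denseLimit = 500L) {
  n <- length(L@diseases); m <- length(L@genes)
  N <- n + m
  k <- hp@k
  if (k >= N) stop("k must be smaller than n + m = ", N)
  ncomp <- .nComponents(L)
  if (ncomp > 1)
    warning("joint graph has ", ncomp, " connected components; dropping all ",
            ncomp, " null-space eigenvectors")
  if (k <= ncomp)
    stop("k = ", k, " leaves no informative dimensions after dropping ",
         ncomp, " null vector(s)")
  e <- .smallestEigen(L@matrix, k, denseLimit = denseLimit)
  V <- e$vectors
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/") * sqrt(2)  # column norms sqrt(2)
  V <- .fixSigns(V)
  keep <- (ncomp + 1L):k
  Vh <- V[, keep, drop = FALSE]
  R <- Vh[seq_len(n), , drop = FALSE]
  Q <- Vh[n + seq_len(m), , drop = FALSE]
  rownames(R) <- L@diseases
  rownames(Q) <- L@genes
  new("Embedding", diseaseCoords = R, geneCoords = Q,
      eigenvalues = e$values, nDropped = as.integer(ncomp), hp = hp)
}

#' Regularized embedding objective, computed directly
#'
#' Direct evaluation of the graph-regularized objective
#' \deqn{\sum_{ij} a_{ij} \lVert r_i - q_j \rVert^2
#'   + \frac{\alpha}{2} \sum_{ij} s^d_{ij} \lVert r_i - r_j \rVert^2
#'   + \frac{\beta}{2} \sum_{ij} s^g_{ij} \lVert q_i - q_j \rVert^2}
#' which is an independent check of the trace identity
#' `Tr(Z^T L Z)` with `Z = rbind(R, Q)`.
#'
#' @param A an [AssociationMatrix-class].
#' @param Sd,Sg disease/gene [SimilarityMatrix-class] objects.
#' @param hp [Hyperparameters-class] supplying `alpha` and `beta`.
#' @param R,Q coordinate matrices (n x d and m x d).
#' @return the objective value (non-negative).
#' @export
objectiveValue <- function(A, Sd, Sg, hp, R, Q) {
  M <- as.matrix(A@assoc)
  d2 <- function(X, Y) {
    outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% base::t(Y)
  }
  sum(M * d2(R, Q)) +
    hp@alpha / 2 * sum(Sd@values * d2(R, R)) +
    hp@beta / 2 * sum(Sg@values * d2(Q, Q))
}

#' Disease-gene distance matrix in the embedding
#'
#' Euclidean (geodesic) distances between every disease and gene coordinate.
#' The squared form is monotone-equivalent, so rankings are identical; the
#' unsquared norm is returned for interpretability.
#'
#' @param E an [Embedding-class].
#' @return n x m matrix of non-negative distances with label dimnames.
#' @export
geodesicDistances <- function(E) {
  R <- E@diseaseCoords; Q <- E@geneCoords
  D2 <- outer(rowSums(R^2), rowSums(Q^2), "+") - 2 * R %*% base::t(Q)
  D <- sqrt(pmax(D2, 0))
  dimnames(D) <- list(rownames(R), rownames(Q))
  D
}

#' Rank candidate genes for one disease
#'
#' All genes not in `exclude` ordered by ascending embedding distance to the
#' disease; distance ties are broken by gene label.
#'
#' @param E an [Embedding-class].
#' @param disease disease label present in the embedding.
#' @param exclude character vector of genes to omit (e.g. known training
#'   associations).
#' @return data.frame with columns `gene`, `distance`, `rank`.
#' @export
rankGenes <- function(E, disease, exclude = character()) {
  if (!disease %in% rownames(E@diseaseCoords))
    stop("unknown disease: ", disease)
  r <- E@diseaseCoords[disease, ]
  Q <- E@geneCoords
  d <- sqrt(rowSums(sweep(Q, 2L, r)^2))
  keep <- !(names(d) %in% exclude)
  d <- d[keep]
  ord <- order(d, names(d))
  out <- data.frame(gene = names(d)[ord], distance = unname(d[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "disease") <- disease
  out
}

#' Write an Embedding to TSV files
#'
#' Writes `diseases.tsv` and `genes.tsv` (label + coordinates) plus
#' `eigenvalues.tsv` into `dir`.
#'
#' @param E an [Embedding-class].
#' @param dir output directory (created if missing).
#' @export
writeEmbedding <- function(E, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(M, f) {
    df <- data.frame(label = rownames(M), M, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(E@diseaseCoords, "diseases.tsv")
  wr(E@geneCoords, "genes.tsv")
  utils::write.table(data.frame(eigenvalue = E@eigenvalues),
                     file.path(dir, "eigenvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
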