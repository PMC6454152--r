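# Seeded synthetic generators: random weighted term DAGs with annotations,
# and planted-block disease-gene benchmarks. Everything is a pure function
# of its arguments plus the seed, so fixtures are reproducible and need no
# downloads.

#' Generate a random single-rooted weighted term DAG
#'
#' Term 1 is the root; every later term receives 1..`maxParents` parents
#' among the earlier terms, each edge with a relation type drawn from
#' `names(weights)`. The construction is acyclic by design and deterministic
#' given `seed`.
#'
#' @param nTerms number of terms (>= 1).
#' @param maxParents maximum number of parents per non-root term
#'   (`maxParents = 1` yields a tree).
#' @param weights named numeric vector of per-relation weights in (0, 1).
#' @param seed RNG seed.
#' @return An [OntologyDAG-class].
#' @export
randomDAG <- function(nTerms, maxParents = 2,
                      weights = c(is_a = 0.8, part_of = 0.6), seed = 1) {
  if (nTerms < 1) stop("nTerms must be >= 1")
  ids <- sprintf("T%03d", seq_len(nTerms))
  edges <- withr::with_seed(seed, {
    ch <- character(); pa <- character(); rel <- character()
    for (i in seq_len(nTerms)[-1]) {
      np <- sample.int(min(maxParents, i - 1L), 1L)
      parents <- sample.int(i - 1L, np)
      ch <- c(ch, rep(ids[i], np))
      pa <- c(pa, ids[parents])
      rel <- c(rel, sample(names(weights), np, replace = TRUE))
    }
    data.frame(child = ch, parent = pa, relation = rel,
               stringsAsFactors = FALSE)
  })
  ontologyDAG(ids, edges, weights)
}

#' Generate random entity annotations over a DAG
#'
#' Each entity is annotated with a uniform random number of distinct terms
#' between `minTerms` and `maxTerms`.
#'
#' @param dag an [OntologyDAG-class].
#' @param entities entity labels (or an integer count; labels `E01`, ...).
#' @param minTerms,maxTerms annotation set size range.
#' @param seed RNG seed.
#' @return An [AnnotationMap-class].
#' @export
randomAnnotations <- function(dag, entities, minTerms = 1, maxTerms = 4,
                              seed = 1) {
  if (is.numeric(entities) && length(entities) == 1)
    entities <- sprintf("E%02d", seq_len(entities))
  terms <- dag@terms
  maxTerms <- min(maxTerms, length(terms))
  ann <- withr::with_seed(seed, {
    lapply(stats::setNames(entities, entities), function(e) {
      sz <- sample(seq(minTerms, maxTerms), 1L)
      sample(terms, sz)
    })
  })
  annotationMap(ann)
}

# block-structured similarity with additive uniform noise, unit diagonal
.blockSimilarity <- function(blocks, base, cross, noise, labels) {
  n <- length(blocks)
  S <- ifelse(outer(blocks, blocks, "=="), base, cross)
  if (noise > 0) {
    E <- matrix(stats::runif(n * n, -noise / 2, noise / 2), n, n)
    S <- S + (E + base::t(E)) / 2
  }
  S[S < 0] <- 0; S[S > 1] <- 1
  diag(S) <- 1
  dimnames(S) <- list(labels, labels)
  new("SimilarityMatrix", labels = labels, values = S)
}

#' Generate a planted-block disease-gene benchmark
#'
#' Diseases and genes are assigned to `nBlocks` latent blocks (round-robin);
#' each (disease, gene) association is drawn independently with probability
#' `pIn` within a block and `pOut` across. `nSingle` randomly chosen
#' diseases instead get exactly one association (drawn within their block,
#' or uniformly when `pIn == pOut`), emulating single-gene diseases. Every
#' disease is guaranteed at least one association and every gene at least
#' one associated disease by forced draws. Block-structured disease and gene
#' similarity matrices with additive uniform noise are generated alongside.
#'
#' When `pIn == pOut` the benchmark carries no recoverable association
#' structure (the null model): all forced draws are uniform, so downstream
#' cross-validation should score near 0.5.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `assoc` ([AssociationMatrix-class]),
#'   `Sd`, `Sg` ([SimilarityMatrix-class]), `diseaseBlocks`, `geneBlocks`
#'   (named integer vectors), and `singleDiseases` (labels of the forced
#'   single-association diseases).
#' @export
plantedAssociations <- function(spec) {
  validObject(spec)
  n <- spec@nDiseases; m <- spec@nGenes; B <- spec@nBlocks
  dLab <- sprintf("D%03d", seq_len(n))
  gLab <- sprintf("G%03d", seq_len(m))
  dBlock <- rep_len(seq_len(B), n)
  gBlock <- rep_len(seq_len(B), m)
  nullModel <- spec@pIn == spec@pOut

  out <- withr::with_seed(spec@seed, {
    single <- if (spec@nSingle > 0) sort(sample.int(n, spec@nSingle)) else integer()
    P <- ifelse(outer(dBlock, gBlock, "=="), spec@pIn, spec@pOut)
    M <- matrix(stats::runif(n * m) < P, n, m) * 1
    # forced single-association diseases
    for (i in single) {
      M[i, ] <- 0
      pool <- if (nullModel) seq_len(m) else which(gBlock == dBlock[i])
      M[i, pool[sample.int(length(pool), 1L)]] <- 1
    }
    # every other disease needs at least one association
    for (i in setdiff(which(rowSums(M) == 0), single)) {
      pool <- if (nullModel) seq_len(m) else which(gBlock == dBlock[i])
      M[i, pool[sample.int(length(pool), 1L)]] <- 1
    }
    # every gene needs at least one associated disease; use non-single
    # diseases so the single-gene bookkeeping stays exact
    multi <- setdiff(seq_len(n), single)
    for (j in which(colSums(M) == 0)) {
      pool <- if (nullModel) multi else intersect(which(dBlock == gBlock[j]), multi)
      if (!length(pool)) pool <- multi
      if (!length(pool)) pool <- seq_len(n)
      M[pool[sample.int(length(pool), 1L)], j] <- 1
    }
    Sd <- .blockSimilarity(dBlock, spec@simBase, spec@simCross,
                           spec@simNoise, dLab)
    Sg <- .blockSimilarity(gBlock, spec@simBase, spec@simCross,
                           spec@simNoise, gLab)
    list(M = M, Sd = Sd, Sg = Sg, single = single)
  })

  list(assoc = associationMatrix(out$M, dLab, gLab),
       Sd = out$Sd, Sg = out$Sg,
       diseaseBlocks = stats::setNames(dBlock, dLab),
       geneBlocks = stats::setNames(gBlock, gLab),
       singleDiseases = dLab[out$single])
}
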