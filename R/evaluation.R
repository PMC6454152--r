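# Cross-validation protocol: the known associations are split into folds;
# per round the held-out third is zeroed, priors are recomputed for every
# disease with a held-out association, the embedding is re-solved on the
# training matrix, and held-out positives plus sampled negatives are scored
# by negated embedding distance. AUC is reported separately for
# multiple-gene and single-gene diseases, averaged over five independent
# negative-sample sets of the same total size as the positives.

#' Randomly partition known associations into folds
#'
#' Uniform random partition of the nonzero (disease, gene) pairs into
#' `nFolds` groups whose sizes differ by at most one; deterministic given
#' `seed`.
#'
#' @param A a binary [AssociationMatrix-class].
#' @param nFolds number of folds (>= 2).
#' @param seed RNG seed.
#' @return A [FoldAssignment-class].
#' @export
makeFolds <- function(A, nFolds = 3, seed = 1) {
  if (nFolds < 2) stop("nFolds must be >= 2")
  M <- A@assoc
  idx <- which(as.matrix(M) != 0, arr.ind = TRUE)
  nPos <- nrow(idx)
  if (nPos < nFolds) stop("fewer associations than folds")
  fold <- withr::with_seed(seed, {
    rep_len(seq_len(nFolds), nPos)[sample.int(nPos)]
  })
  pairs <- data.frame(disease = A@diseases[idx[, 1]],
                      gene = A@genes[idx[, 2]],
                      fold = fold, stringsAsFactors = FALSE)
  new("FoldAssignment", pairs = pairs, nFolds = as.integer(nFolds),
      seed = as.integer(seed))
}

#' Sample negative disease-gene pairs
#'
#' Uniform sample without replacement from the zero entries of `A`;
#' deterministic given `seed` and disjoint from the known associations by
#' construction.
#'
#' @param A an [AssociationMatrix-class].
#' @param count number of pairs to draw.
#' @param seed RNG seed.
#' @return A [NegativeSampleSet-class].
#' @export
sampleNegatives <- function(A, count, seed = 1) {
  M <- as.matrix(A@assoc)
  zeros <- which(M == 0, arr.ind = TRUE)
  if (count > nrow(zeros))
    stop("requested ", count, " negatives but only ", nrow(zeros),
         " zero pairs exist")
  take <- withr::with_seed(seed, sample.int(nrow(zeros), count))
  pairs <- data.frame(disease = A@diseases[zeros[take, 1]],
                      gene = A@genes[zeros[take, 2]],
                      stringsAsFactors = FALSE)
  new("NegativeSampleSet", pairs = pairs, seed = as.integer(seed))
}

#' ROC curve and AUC from positive and negative scores
#'
#' AUC is the Mann-Whitney statistic: the proportion of (positive, negative)
#' score pairs ranked correctly, counting ties as 1/2 (computed exactly via
#' midranks). Higher scores must mean "more association-like", so callers
#' scoring by distance pass the negated distance. The ROC curve is the
#' threshold sweep from the highest score down, starting at (0, 0) and
#' ending at (1, 1).
#'
#' @param scoresPos,scoresNeg nonempty numeric score vectors.
#' @return list with `auc` (scalar) and `roc` (matrix with columns
#'   `fpr`, `tpr`).
#' @export
rocAuc <- function(scoresPos, scoresNeg) {
  P <- length(scoresPos); N <- length(scoresNeg)
  if (P == 0 || N == 0) stop("both score vectors must be nonempty")
  r <- rank(c(scoresPos, scoresNeg), ties.method = "average")
  auc <- (sum(r[seq_len(P)]) - P * (P + 1) / 2) / (P * N)
  sc <- c(scoresPos, scoresNeg)
  lab <- rep(c(1L, 0L), c(P, N))
  ord <- order(sc, decreasing = TRUE)
  sSorted <- sc[ord]
  tp <- cumsum(lab[ord]); fp <- cumsum(1L - lab[ord])
  last <- !duplicated(sSorted, fromLast = TRUE)  # one point per threshold
  roc <- rbind(c(0, 0), cbind(fpr = fp[last] / N, tpr = tp[last] / P))
  colnames(roc) <- c("fpr", "tpr")
  list(auc = auc, roc = roc)
}

# internal: score lookup for a set of (disease, gene) pairs in a distance
# matrix; returns negated distances
.scorePairs <- function(D, pairs) {
  -D[cbind(match(pairs$disease, rownames(D)), match(pairs$gene, colnames(D)))]
}

#' Cross-validate the embedding on an association matrix
#'
#' Runs `nFolds`-fold cross-validation: each round zeroes one fold of
#' associations, recomputes the similarity-weighted prior for every disease
#' with a held-out association (when `usePrior`), re-solves the embedding on
#' the training matrix, and scores that round's held-out positives and every
#' negative-sample set by negated embedding distance. One AUC per negative
#' set is computed for each disease class (multiple-gene vs single-gene,
#' classified on the full matrix), pooling positives and negatives across
#' rounds; the class result is the mean over the negative sets.
#'
#' The `nNegSets` negative sets are drawn once from the zero entries of the
#' full matrix and shared across rounds; each is restricted to the disease
#' class under evaluation, and scored with each round's embedding.
#'
#' @param A binary [AssociationMatrix-class].
#' @param Sd,Sg disease and gene [SimilarityMatrix-class] objects.
#' @param hp [Hyperparameters-class].
#' @param nFolds number of CV folds (default 3).
#' @param nNegSets number of negative-sample replicates (default 5).
#' @param seed master seed; the fold seed and the negative-set seeds are
#'   derived from it by fixed offsets.
#' @param usePrior whether to add recomputed priors to diseases with
#'   held-out associations (default TRUE).
#' @param denseLimit passed to [solveEmbedding()].
#' @return list with elements `multiple` and `single`, each an
#'   [EvaluationResult-class].
#' @export
crossValidate <- function(A, Sd, Sg, hp, nFolds = 3, nNegSets = 5, seed = 1,
                          usePrior = TRUE, denseLimit = 500L) {
  folds <- makeFolds(A, nFolds, seed = seed)
  pairs <- folds@pairs
  nPos <- nrow(pairs)
  negSets <- lapply(seq_len(nNegSets), function(s)
    sampleNegatives(A, nPos, seed = seed + 100L + s))
  classes <- diseaseClasses(A)

  posScore <- numeric(nPos)
  negScore <- vector("list", nFolds)  # [[fold]] matrix: pairs x negset

  M <- as.matrix(A@assoc)
  for (f in seq_len(nFolds)) {
    test <- pairs[pairs$fold == f, , drop = FALSE]
    train <- M
    train[cbind(match(test$disease, A@diseases),
                match(test$gene, A@genes))] <- 0
    Atr <- associationMatrix(train, A@diseases, A@genes)
    if (usePrior) {
      held <- unique(test$disease)
      priors <- lapply(held, function(d) priorVector(Atr, Sd, d))
      names(priors) <- held
      Atr <- augmentAssociations(Atr, priors, mode = "add")
    }
    E <- solveEmbedding(buildLaplacian(Atr, Sd, Sg, hp), hp,
                        denseLimit = denseLimit)
    D <- geodesicDistances(E)
    posScore[pairs$fold == f] <- .scorePairs(D, test)
    negScore[[f]] <- vapply(negSets, function(ns) .scorePairs(D, ns@pairs),
                            numeric(nPos))
  }

  evalClass <- function(classDiseases, className) {
    inClassPos <- pairs$disease %in% classDiseases
    if (!any(inClassPos))
      stop("no held-out positives for class ", className)
    aucs <- numeric(nNegSets)
    poolPosAll <- posScore[inClassPos]
    poolNegAll <- c()
    perDisease <- list()
    for (s in seq_len(nNegSets)) {
      inClassNeg <- negSets[[s]]@pairs$disease %in% classDiseases
      negPool <- unlist(lapply(seq_len(nFolds), function(f)
        negScore[[f]][inClassNeg, s]))
      aucs[s] <- rocAuc(poolPosAll, negPool)$auc
      if (s == 1) poolNegAll <- negPool else poolNegAll <- c(poolNegAll, negPool)
    }
    # per-disease diagnostic: each disease's positives vs the class negatives
    perD <- vapply(unique(pairs$disease[inClassPos]), function(d) {
      dp <- posScore[pairs$disease == d]
      mean(vapply(seq_len(nNegSets), function(s) {
        inClassNeg <- negSets[[s]]@pairs$disease %in% classDiseases
        rocAuc(dp, unlist(lapply(seq_len(nFolds), function(f)
          negScore[[f]][inClassNeg, s])))$auc
      }, numeric(1)))
    }, numeric(1))
    new("EvaluationResult",
        diseaseClass = className,
        aucPerReplicate = aucs,
        meanAuc = mean(aucs),
        roc = rocAuc(rep(poolPosAll, nNegSets), poolNegAll)$roc,
        perDiseaseAuc = data.frame(disease = names(perD), auc = unname(perD),
                                   stringsAsFactors = FALSE),
        hp = hp, usePrior = usePrior)
  }

  out <- list()
  out$multiple <- if (length(classes$multiple) &&
                      any(pairs$disease %in% classes$multiple))
    evalClass(classes$multiple, "multiple-gene") else NULL
  out$single <- if (length(classes$single) &&
                    any(pairs$disease %in% classes$single))
    evalClass(classes$single, "single-gene") else NULL
  out
}

#' Grid search over embedding hyperparameters
#'
#' Runs [crossValidate()] for every combination of `kGrid` and `alphaGrid`
#' (with `beta = alpha` unless `betaGrid` is given) and tabulates the mean
#' AUC per disease class. Grid points with `k >= n + m` are skipped with a
#' warning.
#'
#' @param A,Sd,Sg as in [crossValidate()].
#' @param kGrid,alphaGrid numeric grids; defaults follow the standard
#'   protocol (`k` in 20...1500, `alpha` in 0...0.5).
#' @param betaGrid optional; default equal to `alphaGrid` elementwise.
#' @param ... further arguments passed to [crossValidate()] (e.g. `seed`,
#'   `usePrior`).
#' @return data.frame with columns `k`, `alpha`, `beta`, `aucMultiple`,
#'   `aucSingle`, plus attribute `best` naming the argmax row per class.
#' @export
gridSearch <- function(A, Sd, Sg,
                       kGrid = c(20, 30, 50, 100, 500, 800, 1000, 1200, 1500),
                       alphaGrid = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5),
                       betaGrid = NULL, ...) {
  N <- sum(dim(A))
  bad <- kGrid >= N
  if (any(bad)) {
    warning("skipping k values >= n + m: ", paste(kGrid[bad], collapse = ", "))
    kGrid <- kGrid[!bad]
  }
  if (!length(kGrid)) stop("no valid k values in grid")
  rows <- list()
  for (k in kGrid) {
    for (ia in seq_along(alphaGrid)) {
      a <- alphaGrid[ia]
      b <- if (is.null(betaGrid)) a else betaGrid[ia]
      res <- crossValidate(A, Sd, Sg, hyperparameters(k, a, b), ...)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, alpha = a, beta = b,
        aucMultiple = if (is.null(res$multiple)) NA_real_ else res$multiple@meanAuc,
        aucSingle = if (is.null(res$single)) NA_real_ else res$single@meanAuc)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "best") <- list(
    multiple = if (all(is.na(out$aucMultiple))) NA_integer_ else
      which.max(out$aucMultiple),
    single = if (all(is.na(out$aucSingle))) NA_integer_ else
      which.max(out$aucSingle))
  out
}
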