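test_that("the joint Laplacian reduces to textbook cases", {
  # single association, no affinity graphs: the one-edge Laplacian
  A <- associationMatrix(matrix(1, 1, 1), "d1", "g1")
  S1 <- similarityMatrixFromValues(matrix(1, 1, 1, dimnames = list("d1", "d1")))
  S2 <- similarityMatrixFromValues(matrix(1, 1, 1, dimnames = list("g1", "g1")))
  L <- buildLaplacian(A, S1, S2, hyperparameters(2, alpha = 0, beta = 0))
  expect_equal(as.matrix(L), matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  # alpha = beta = 0: the unnormalized Laplacian of the bipartite graph,
  # cross-checked against igraph
  inst <- randomInstance(5, 7, seed = 3)
  L0 <- buildLaplacian(inst$A, inst$Sd, inst$Sg, hyperparameters(4, 0, 0))
  g <- igraph::graph_from_biadjacency_matrix(as.matrix(inst$A))
  Lg <- igraph::laplacian_matrix(g, sparse = FALSE)
  expect_equal(as.matrix(L0), Lg, ignore_attr = TRUE)
  # label mismatches are refused
  expect_error(buildLaplacian(inst$A, inst$Sg, inst$Sg, hyperparameters(4)),
               "labels")
})

test_that("the Laplacian is symmetric, zero-row-sum and PSD on random instances", {
  for (s in 1:20) {
    nm <- withr::with_seed(s, c(sample(2:10, 1), sample(2:12, 1)))
    inst <- randomInstance(nm[1], nm[2], seed = s)
    L <- buildLaplacian(inst$A, inst$Sd, inst$Sg,
                        hyperparameters(3, inst$alpha, inst$beta))
    M <- as.matrix(L)
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_lt(max(abs(rowSums(M))), 1e-10)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("the direct objective equals the Laplacian trace form", {
  for (s in 1:20) {
    inst <- randomInstance(6, 8, seed = s + 50)
    hp <- hyperparameters(4, inst$alpha, inst$beta)
    L <- buildLaplacian(inst$A, inst$Sd, inst$Sg, hp)
    Z <- withr::with_seed(s, matrix(stats::rnorm(14 * 4), 14, 4))
    R <- Z[1:6, ]; Q <- Z[7:14, ]
    direct <- objectiveValue(inst$A, inst$Sd, inst$Sg, hp, R, Q)
    traceForm <- sum(Z * as.matrix(L@matrix %*% Z))
    expect_equal(direct, traceForm, tolerance = 1e-10)
  }
  # degenerate anchors of the identity
  inst <- randomInstance(3, 3, seed = 1)
  hp <- hyperparameters(2, inst$alpha, inst$beta)
  Zc <- matrix(1, 3, 2)
  expect_equal(objectiveValue(inst$A, inst$Sd, inst$Sg, hp, Zc, Zc), 0,
               tolerance = 1e-12)
  A1 <- associationMatrix(matrix(1, 1, 1), "d1", "g1")
  S1 <- similarityMatrixFromValues(matrix(1, 1, 1, dimnames = list("d1", "d1")))
  S2 <- similarityMatrixFromValues(matrix(1, 1, 1, dimnames = list("g1", "g1")))
  expect_equal(objectiveValue(A1, S1, S2, hyperparameters(2, 0, 0),
                              matrix(0, 1, 1), matrix(1, 1, 1)), 1)
})

test_that("the eigen solution satisfies the constraint and the Ky Fan bound", {
  for (s in 1:5) {
    inst <- randomInstance(8, 10, seed = s + 80)
    hp <- hyperparameters(5, inst$alpha, inst$beta)
    L <- buildLaplacian(inst$A, inst$Sd, inst$Sg, hp)
    E <- solveEmbedding(L, hp)
    # connected graph: exactly one zero eigenvalue dropped
    expect_identical(E@nDropped, 1L)
    expect_lt(embeddingEigenvalues(E)[1], 1e-8)
    Z <- rbind(diseaseCoords(E), geneCoords(E))
    expect_lt(max(abs(crossprod(Z) - 2 * diag(ncol(Z)))), 1e-8)
    # objective equals twice the sum of the k smallest eigenvalues
    obj <- sum(Z * as.matrix(L@matrix %*% Z)) +
      2 * embeddingEigenvalues(E)[1]  # add back the dropped null direction
    expect_equal(obj, 2 * sum(embeddingEigenvalues(E)), tolerance = 1e-8)
    # no random constraint-satisfying Z does better
    full <- withr::with_seed(s, {
      vapply(1:100, function(i) {
        Zr <- randomConstraintZ(18, hp@k)
        sum(Zr * as.matrix(L@matrix %*% Zr))
      }, numeric(1))
    })
    expect_true(all(2 * sum(embeddingEigenvalues(E)) <= full + 1e-10))
  }
})

test_that("the null eigenvector of a connected joint graph is constant", {
  b <- plantedAssociations(syntheticSpec(nDiseases = 12, nGenes = 18,
                                         nBlocks = 3, seed = 2))
  hp <- hyperparameters(5, 0.2)
  L <- buildLaplacian(b$assoc, b$Sd, b$Sg, hp)
  e <- dgembed:::.smallestEigen(L@matrix, 3)
  expect_lt(e$values[1], 1e-8)
  u0 <- e$vectors[, 1]
  expect_lt(diff(range(u0)) / mean(abs(u0)), 1e-6)
})

test_that("disconnected joint graphs drop every null direction with a warning", {
  M <- matrix(0, 2, 2, dimnames = list(c("d1", "d2"), c("g1", "g2")))
  diag(M) <- 1
  A <- associationMatrix(M)
  Sid <- similarityMatrixFromValues(diag(1, 2), c("d1", "d2"))
  Sig <- similarityMatrixFromValues(diag(1, 2), c("g1", "g2"))
  hp <- hyperparameters(3, 0.5)
  L <- buildLaplacian(A, Sid, Sig, hp)
  expect_warning(E <- solveEmbedding(L, hp), "2 connected components")
  expect_identical(E@nDropped, 2L)
  expect_identical(ncol(diseaseCoords(E)), 1L)
  expect_lt(max(embeddingEigenvalues(E)[1:2]), 1e-8)
  expect_error(suppressWarnings(solveEmbedding(L, hyperparameters(2, 0.5))),
               "no informative dimensions")
  expect_error(solveEmbedding(L, hyperparameters(10, 0.5)), "smaller than")
})

test_that("solves are deterministic and the sparse path matches the dense path", {
  b <- plantedAssociations(syntheticSpec(nDiseases = 25, nGenes = 50,
                                         nBlocks = 2, seed = 6))
  hp <- hyperparameters(8, 0.2)
  L <- buildLaplacian(b$assoc, b$Sd, b$Sg, hp)
  E1 <- solveEmbedding(L, hp)
  E2 <- solveEmbedding(L, hp)
  expect_identical(diseaseCoords(E1), diseaseCoords(E2))
  expect_identical(rankGenes(E1, "D001"), rankGenes(E2, "D001"))
  Es <- solveEmbedding(L, hp, denseLimit = 1L)  # force the iterative solver
  expect_equal(embeddingEigenvalues(Es), embeddingEigenvalues(E1),
               tolerance = 1e-7)
  expect_equal(geodesicDistances(Es), geodesicDistances(E1), tolerance = 1e-6)
})

test_that("geodesic distances match the entrywise norm and respond to scaling", {
  b <- plantedAssociations(syntheticSpec(nDiseases = 10, nGenes = 15,
                                         nBlocks = 2, seed = 8))
  hp <- hyperparameters(5, 0.1)
  E <- solveEmbedding(buildLaplacian(b$assoc, b$Sd, b$Sg, hp), hp)
  D <- geodesicDistances(E)
  R <- diseaseCoords(E); Q <- geneCoords(E)
  for (i in c(1, 5, 10)) for (j in c(2, 9, 15)) {
    expect_equal(D[i, j], sqrt(sum((R[i, ] - Q[j, ])^2)), tolerance = 1e-12)
  }
  expect_true(all(D >= 0))
  # scaling all coordinates by c > 0 leaves every ranking unchanged
  Escaled <- E
  Escaled@diseaseCoords <- 3.7 * R
  Escaled@geneCoords <- 3.7 * Q
  for (d in c("D001", "D007")) {
    expect_identical(rankGenes(Escaled, d)$gene, rankGenes(E, d)$gene)
  }
})

test_that("gene ranking is ascending with label tie-breaks and exclusions", {
  E <- new("Embedding",
           diseaseCoords = matrix(0, 1, 1, dimnames = list("dz", NULL)),
           geneCoords = matrix(c(2, 1, 3, 1), 4, 1,
                               dimnames = list(c("gA", "gB", "gC", "gD"), NULL)),
           eigenvalues = c(0, 1), nDropped = 1L,
           hp = hyperparameters(2, 0))
  rk <- rankGenes(E, "dz")
  expect_identical(rk$gene, c("gB", "gD", "gA", "gC"))  # tie 1,1 -> gB before gD
  expect_identical(rk$rank, 1:4)
  expect_true(!is.unsorted(rk$distance))
  expect_identical(rankGenes(E, "dz", exclude = "gB")$gene[1], "gD")
  expect_equal(nrow(rankGenes(E, "dz", exclude = c("gA", "gB", "gC", "gD"))), 0L)
  expect_error(rankGenes(E, "nope"), "unknown disease")
})

test_that("true associated genes rank better than decoys on planted data", {
  b <- plantedAssociations(syntheticSpec(nDiseases = 20, nGenes = 60,
                                         nBlocks = 2, seed = 11))
  hp <- hyperparameters(6, 0.2)
  E <- solveEmbedding(buildLaplacian(b$assoc, b$Sd, b$Sg, hp), hp)
  M <- as.matrix(b$assoc)
  medTrue <- medDecoy <- numeric(0)
  for (d in rownames(M)[1:8]) {
    rk <- rankGenes(E, d)
    truth <- colnames(M)[M[d, ] == 1]
    medTrue <- c(medTrue, stats::median(rk$rank[rk$gene %in% truth]))
    medDecoy <- c(medDecoy, stats::median(rk$rank[!rk$gene %in% truth]))
  }
  expect_lt(mean(medTrue), mean(medDecoy))
})
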