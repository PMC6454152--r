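# Shared fixtures and independent oracles. The oracles deliberately avoid the
# package's computation paths: tau values by exhaustive path enumeration over
# the raw edge list, AUC by the O(P*N) pairwise count, similarities by direct
# formula expansion.

# 5-term toy ontology: root a; b is_a a; c part_of a; d is_a b, d part_of c;
# e is_a c. Gives two paths d -> a with products 0.64 and 0.36.
toyDAG <- function() {
  ontologyDAG(
    c("a", "b", "c", "d", "e"),
    data.frame(
      child = c("b", "c", "d", "d", "e"),
      parent = c("a", "a", "b", "c", "c"),
      relation = c("is_a", "part_of", "is_a", "part_of", "is_a"),
      stringsAsFactors = FALSE
    ),
    weights = c(is_a = 0.8, part_of = 0.6)
  )
}

# exhaustive max-path-product tau oracle over the raw edge list
bruteTau <- function(dag, h) {
  ed <- dag@edges
  w <- dag@weights
  best <- new.env(parent = emptyenv())
  assign(h, 1, envir = best)
  visit <- function(t, prod) {
    up <- ed[ed$child == t, , drop = FALSE]
    for (r in seq_len(nrow(up))) {
      p <- up$parent[r]
      pr <- prod * unname(w[[up$relation[r]]])
      cur <- if (exists(p, envir = best)) get(p, envir = best) else -Inf
      if (pr > cur) assign(p, pr, envir = best)
      visit(p, pr)
    }
  }
  visit(h, 1)
  out <- unlist(as.list(best))
  out[order(names(out))]
}

# direct expansion of the shared-ancestor ratio from two tau oracles
bruteTermSim <- function(dag, h, b) {
  th <- bruteTau(dag, h); tb <- bruteTau(dag, b)
  common <- intersect(names(th), names(tb))
  if (!length(common)) return(0)
  (sum(th[common]) + sum(tb[common])) / (sum(th) + sum(tb))
}

# best-match-average entity similarity from the pairwise brute-force values
bruteEntitySim <- function(dag, s1, s2) {
  P <- outer(s1, s2, Vectorize(function(a, b) bruteTermSim(dag, a, b)))
  (sum(apply(P, 1, max)) + sum(apply(P, 2, max))) / (length(s1) + length(s2))
}

# O(P*N) pairwise Mann-Whitney oracle, ties as 1/2
bruteAuc <- function(pos, neg) {
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# random labelled association + similarity instance for Laplacian tests
randomInstance <- function(n, m, seed, maxAlpha = 0.5, density = 0.3) {
  withr::with_seed(seed, {
    M <- matrix(stats::rbinom(n * m, 1, density), n, m)
    if (all(M == 0)) M[1, 1] <- 1
    dl <- sprintf("d%02d", seq_len(n)); gl <- sprintf("g%02d", seq_len(m))
    dimnames(M) <- list(dl, gl)
    mkSym <- function(q, lab) {
      S <- matrix(stats::runif(q * q), q, q)
      S <- (S + t(S)) / 2; diag(S) <- 1
      dimnames(S) <- list(lab, lab)
      similarityMatrixFromValues(S, lab)
    }
    list(A = associationMatrix(M, dl, gl),
         Sd = mkSym(n, dl), Sg = mkSym(m, gl),
         alpha = stats::runif(1, 0, maxAlpha),
         beta = stats::runif(1, 0, maxAlpha))
  })
}

# random orthonormal-column matrix scaled so crossprod(Z) = 2 I
randomConstraintZ <- function(N, k) {
  Z <- qr.Q(qr(matrix(stats::rnorm(N * k), N, k)))
  Z * sqrt(2)
}

writeTempOBO <- function(lines) {
  f <- withr::local_tempfile(fileext = ".obo",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
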