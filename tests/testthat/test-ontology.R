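test_that("parseOBO builds the DAG, drops obsolete terms and foreign relations", {
  f <- writeTempOBO(c(
    "format-version: 1.2", "",
    "[Term]", "id: a", "",
    "[Term]", "id: b", "is_a: a ! root", "",
    "[Term]", "id: c", "is_a: b", "relationship: part_of a", "",
    "[Term]", "id: old", "is_a: a", "is_obsolete: true", "",
    "[Term]", "id: d", "relationship: regulates a", "",
    "[Typedef]", "id: part_of"
  ))
  expect_message(dag <- parseOBO(f), "skipped 1")  # the regulates edge
  expect_setequal(ontologyTerms(dag), c("a", "b", "c", "d"))
  expect_equal(nrow(dag@edges), 3L)
  # part_of edge carries weight 0.6: one-step tau from c through part_of
  tau <- tauValues(dag, "c")@tau
  expect_identical(unname(tau["a"]), max(0.6, 0.8 * 0.8))
})

test_that("parseOBO rejects cyclic ontologies naming an offender", {
  f <- writeTempOBO(c("[Term]", "id: x", "is_a: y", "",
                      "[Term]", "id: y", "is_a: x"))
  expect_error(parseOBO(f), "cycle.*x|cycle.*y")
})

test_that("tau values follow the max-path-product recursion", {
  dag <- toyDAG()
  # one-step chain: anchor 1, parent gets the edge weight
  tb <- tauValues(dag, "b")@tau
  expect_identical(tb, c(a = 0.8, b = 1))
  # two paths d -> a with products 0.64 and 0.36: max wins
  td <- tauValues(dag, "d")@tau
  expect_identical(unname(td["a"]), 0.8 * 0.8)
  expect_identical(unname(td[c("b", "c", "d")]), c(0.8, 0.6, 1))
  # the root is its own closure
  expect_identical(tauValues(dag, "a")@tau, c(a = 1))
  expect_error(tauValues(dag, "nope"), "not in ontology")
})

test_that("DP tau values equal the brute-force path-product oracle exactly", {
  for (s in 1:40) {
    dag <- randomDAG(sample(2:15, 1), maxParents = 3, seed = s)
    h <- withr::with_seed(s, sample(ontologyTerms(dag), 1))
    got <- tauValues(dag, h)@tau
    expect_identical(got[order(names(got))], bruteTau(dag, h), label = paste("seed", s))
  }
})

test_that("term similarity is the shared-ancestor ratio", {
  dag <- toyDAG()
  expect_identical(termSimilarity(dag, "d", "d"), 1)
  # d vs e share {a, c}: hand expansion
  # tau_d = (a .64, b .8, c .6, d 1), tau_e = (a .48, c .8, e 1)
  expect_equal(termSimilarity(dag, "d", "e"), 2.52 / 5.32, tolerance = 1e-15)
  expect_identical(termSimilarity(dag, "d", "e"), termSimilarity(dag, "e", "d"))
  # two roots with no shared ancestor
  dag2 <- ontologyDAG(c("r1", "r2"), NULL)
  expect_identical(termSimilarity(dag2, "r1", "r2"), 0)
})

test_that("term-set similarity is the best match over the set", {
  dag <- toyDAG()
  expect_identical(termSetSimilarity(dag, "d", c("a", "d", "e")), 1)
  expect_identical(termSetSimilarity(dag, "d", "e"), termSimilarity(dag, "d", "e"))
  vals <- vapply(c("a", "b", "e"), function(t) termSimilarity(dag, "d", t), 1)
  expect_identical(termSetSimilarity(dag, "d", c("a", "b", "e")), max(vals))
  expect_error(termSetSimilarity(dag, "d", character()), "nonempty")
})

test_that("entity similarity is the symmetric best-match average", {
  dag <- toyDAG()
  expect_identical(entitySimilarity(dag, c("d", "e"), c("d", "e")), 1)
  s1 <- c("d", "b"); s2 <- c("e", "c", "a")
  expect_equal(entitySimilarity(dag, s1, s2), bruteEntitySim(dag, s1, s2),
               tolerance = 1e-15)
  expect_identical(entitySimilarity(dag, s1, s2), entitySimilarity(dag, s2, s1))
  dag2 <- ontologyDAG(c("r1", "r2"), NULL)
  expect_identical(entitySimilarity(dag2, "r1", "r2"), 0)
  expect_error(entitySimilarity(dag, character(), "a"), "nonempty")
})

test_that("similarityMatrix matches uncached pairwise recomputation", {
  dag <- randomDAG(12, maxParents = 2, seed = 7)
  ann <- randomAnnotations(dag, 4, minTerms = 2, maxTerms = 4, seed = 7)
  S <- similarityMatrix(dag, ann)
  expect_true(validObject(S))
  ents <- simLabels(S)
  for (i in seq_along(ents)) {
    for (j in seq_along(ents)) {
      expected <- if (i == j) 1 else
        entitySimilarity(dag, annotatedTerms(ann, ents[i]),
                         annotatedTerms(ann, ents[j]))
      expect_equal(as.matrix(S)[i, j], expected, tolerance = 1e-12)
    }
  }
  # deterministic: identical inputs give bitwise-identical matrices
  expect_identical(as.matrix(similarityMatrix(dag, ann)), as.matrix(S))
})

test_that("similarityMatrix drops and reports unannotated entities", {
  dag <- toyDAG()
  ann <- annotationMap(list(e1 = c("d", "e"), e2 = "b"))
  expect_warning(S <- similarityMatrix(dag, ann, entities = c("e1", "e2", "ghost")),
                 "ghost")
  expect_identical(simLabels(S), c("e1", "e2"))
  # identical annotation sets give similarity 1
  ann2 <- annotationMap(list(x = c("d", "e"), y = c("d", "e")))
  expect_equal(as.matrix(similarityMatrix(dag, ann2)),
               matrix(1, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))))
})

test_that("growing an entity's annotation with an unrelated root lowers similarity", {
  # extra ancestor-free term joins T_h, inflating the denominator only
  dag <- toyDAG()
  dagExt <- ontologyDAG(c(ontologyTerms(dag), "f"), dag@edges, dag@weights)
  base <- entitySimilarity(dagExt, "d", "e")
  expect_lte(entitySimilarity(dagExt, c("d", "f"), "e"), base)
})

test_that("annotation TSV reader validates terms and drops empty entities", {
  dag <- toyDAG()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "g1\td", "g1\te", "g2\tb", "g3\tUNKNOWN"), f)
  expect_warning(expect_message(ann <- readAnnotations(f, dag), "unknown terms"),
                 "g3")
  expect_identical(annotatedEntities(ann), c("g1", "g2"))
  expect_identical(annotatedTerms(ann, "g1"), c("d", "e"))
  expect_identical(ann@dropped, "g3")
})

test_that("similarity matrices round-trip through TSV", {
  inst <- randomInstance(4, 3, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSimilarityMatrix(inst$Sd, f)
  back <- readSimilarityMatrix(f)
  expect_identical(simLabels(back), simLabels(inst$Sd))
  expect_equal(as.matrix(back), as.matrix(inst$Sd), tolerance = 1e-12)
})

test_that("parseOBO can restrict to one namespace", {
  f <- writeTempOBO(c(
    "[Term]", "id: a", "namespace: biological_process", "",
    "[Term]", "id: b", "namespace: biological_process", "is_a: a", "",
    "[Term]", "id: c", "namespace: cellular_component", "is_a: a"
  ))
  expect_setequal(ontologyTerms(parseOBO(f)), c("a", "b", "c"))
  bp <- parseOBO(f, namespace = "biological_process")
  expect_setequal(ontologyTerms(bp), c("a", "b"))
  expect_equal(nrow(bp@edges), 1L)
})
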