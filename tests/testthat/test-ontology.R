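## in-code OBO fixture: two namespaces, a diamond DAG, one obsolete term
writeTestOBO <- function(extraLines = character(0)) {
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0001", "name: mf root",
    "namespace: molecular_function",
    "",
    "[Term]", "id: GO:0002", "name: binding",
    "namespace: molecular_function", "is_a: GO:0001 ! mf root",
    "",
    "[Term]", "id: GO:0003", "name: ion binding",
    "namespace: molecular_function", "is_a: GO:0002 ! binding",
    "",
    "[Term]", "id: GO:0004", "name: metal ion binding",
    "namespace: molecular_function", "is_a: GO:0003 ! ion binding",
    "relationship: part_of GO:0002 ! binding",
    "",
    "[Term]", "id: GO:0005", "name: gone",
    "namespace: molecular_function", "is_a: GO:0002", "is_obsolete: true",
    "",
    "[Term]", "id: GO:0101", "name: cc root",
    "namespace: cellular_component",
    "",
    "[Term]", "id: GO:0102", "name: membrane",
    "namespace: cellular_component", "is_a: GO:0101",
    extraLines), f)
  f
}

test_that("readOBO builds the DAG, drops obsolete terms and finds roots", {
  onto <- readOBO(writeTestOBO())
  expect_setequal(igraph::V(onto@graph)$name,
                  c("GO:0001", "GO:0002", "GO:0003", "GO:0004",
                    "GO:0101", "GO:0102"))
  expect_identical(unname(onto@roots[c("molecular_function",
                                       "cellular_component")]),
                   c("GO:0001", "GO:0101"))
  expect_setequal(termAncestors(onto, "GO:0004"),
                  c("GO:0003", "GO:0002", "GO:0001"))
  expect_error(termAncestors(onto, "GO:9999"), "absent")
})

test_that("evidence filtering keeps the stated code sets", {
  tab <- data.frame(
    protein_id = c("P1", "P1", "P2", "P2", "P3"),
    term_id = c("GO:0002", "GO:0003", "GO:0002", "GO:0004", "GO:0002"),
    evidence = c("IDA", "IEA", "TAS", "WEIRD", "EXP"))
  expect_warning(expo <- filterByEvidence(tab, "EXP_only"), "WEIRD")
  expect_setequal(expo$evidence, c("IDA", "TAS", "EXP"))
  expect_warning(both <- filterByEvidence(tab, "EXP_and_IEA"), "WEIRD")
  expect_setequal(both$evidence, c("IDA", "IEA", "TAS", "EXP"))
  empty <- tab[0, ]
  expect_identical(filterByEvidence(empty, "EXP_only"), empty)
})

test_that("annotation propagation closes over ancestry, excluding the root", {
  onto <- readOBO(writeTestOBO())
  ## term directly under the root: nothing to add
  t1 <- data.frame(protein_id = "P1", term_id = "GO:0002")
  expect_identical(propagateAnnotations(t1, onto)$term_id, "GO:0002")
  ## chain closes upward
  t2 <- data.frame(protein_id = "P1", term_id = "GO:0003")
  expect_setequal(propagateAnnotations(t2, onto)$term_id,
                  c("GO:0003", "GO:0002"))
  ## idempotence and monotonicity
  p1 <- propagateAnnotations(t2, onto)
  expect_identical(propagateAnnotations(p1, onto), p1)
  expect_true(all(t2$term_id %in% p1$term_id))
  expect_error(propagateAnnotations(
    data.frame(protein_id = "P1", term_id = "GO:404"), onto), "GO:404")
})

test_that("propagation matches a brute-force transitive closure on a random DAG", {
  withr::with_seed(8, {
    terms <- sprintf("T%02d", 1:12)
    edges <- NULL
    for (i in 2:12) {
      parents <- sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))
      edges <- rbind(edges, cbind(terms[i], terms[parents]))
    }
  })
  obo <- c("format-version: 1.2", unlist(lapply(terms, function(t) {
    c("", "[Term]", paste0("id: ", t), paste0("name: ", t),
      "namespace: molecular_function",
      paste0("is_a: ", edges[edges[, 1] == t, 2]))
  })))
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, f)
  onto <- readOBO(f)
  closure <- bruteAncestors(edges, terms)
  annot <- data.frame(protein_id = "P1", term_id = terms[c(12, 9)])
  got <- propagateAnnotations(annot, onto)$term_id
  want <- setdiff(unique(c(terms[c(12, 9)],
                           terms[closure[12, ]], terms[closure[9, ]])),
                  onto@roots)
  expect_setequal(got, want)
})

test_that("information content follows -log2(prob)", {
  expect_equal(informationContent(1), 0)
  expect_equal(informationContent(0.5), 1)
  expect_equal(informationContent(2^-10), 10)
  expect_error(informationContent(0), "\\(0, 1\\]")
  expect_error(informationContent(1.2), "\\(0, 1\\]")
  probs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(informationContent(probs)) < 0))
})

test_that("selectTerms applies count bounds, EC depth and class weights", {
  mkTab <- function(counts) {
    do.call(rbind, lapply(names(counts), function(t)
      data.frame(protein_id = sprintf("P%04d", seq_len(counts[[t]])),
                 term_id = t)))
  }
  tab <- mkTab(c(lo = 49, edge = 50, mid = 120, hi = 5001))
  space <- selectTerms(tab, 50, 5000, nProteins = 6000)
  expect_setequal(termIds(space), c("edge", "mid"))
  ## lexicographic order
  expect_identical(termIds(space), sort(termIds(space)))
  ## EC mode keeps only depth 3-4 identifiers
  ec <- mkTab(c("1.2" = 60, "1.2.3" = 60, "1.2.3.4" = 60))
  spEC <- selectTerms(ec, 50, 5000, ecMode = TRUE, nProteins = 200)
  expect_setequal(termIds(spEC), c("1.2.3", "1.2.3.4"))
  ## w_j = N / N_j+
  tw <- mkTab(c(t1 = 50))
  expect_equal(unname(classWeights(selectTerms(tw, 50, 5000,
                                               nProteins = 200))), 4)
  expect_error(selectTerms(mkTab(c(t1 = 3)), 50, 5000), "min_count")
})

test_that("encodeLabels produces complementary indicator pairs with correct counts", {
  recs <- list(
    new("ProteinRecord", id = "P1", sequence = "AAA",
        labels = c(tA = 1, tB = 0)),
    new("ProteinRecord", id = "P2", sequence = "CCC",
        labels = c(tA = 1, tB = 1)),
    new("ProteinRecord", id = "P3", sequence = "DDD",
        labels = c(tA = 0, tB = 0)))
  space <- new("LabelSpace", termIds = c("tA", "tB"),
               termNames = c("tA", "tB"), counts = c(2, 1), ic = c(1, 2),
               weights = c(1.5, 3), nProteins = 3)
  y <- encodeLabels(recs, space)
  expect_true(all(y[, , 1] + y[, , 2] == 1))
  expect_equal(unname(colSums(y[, , 1])), c(2, 1))
  ## protein with no terms: all (0, 1)
  expect_equal(unname(y["P3", , ]), rbind(c(0, 1), c(0, 1)))
})
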