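## small helper: residueCoordinates with one CA (and optionally CB) per residue
caOnly <- function(xyz, seqstr = NULL) {
  L <- nrow(xyz)
  if (is.null(seqstr)) seqstr <- paste(rep("A", L), collapse = "")
  residueCoordinates(seqstr, lapply(seq_len(L), function(i) {
    m <- xyz[i, , drop = FALSE]; rownames(m) <- "CA"; m
  }))
}

test_that("CA-CA contacts use a strict distance threshold", {
  xyz <- rbind(c(0, 0, 0), c(9.9, 0, 0))
  expect_equal(adjacency(buildContactMap(xyz, "CA_CA", 10))[1, 2], 1)
  xyz2 <- rbind(c(0, 0, 0), c(10.0, 0, 0))
  expect_equal(adjacency(buildContactMap(xyz2, "CA_CA", 10))[1, 2], 0)
})

test_that("contact maps equal the brute-force all-pairs computation", {
  withr::with_seed(5, xyz <- matrix(rnorm(150, sd = 8), 50, 3))
  cm <- buildContactMap(xyz, "CA_CA", 10)
  D <- bruteDistMatrix(xyz)
  expected <- (D < 10) * 1
  diag(expected) <- 0
  expect_identical(adjacency(cm), expected)
  ## symmetry, zero diagonal, and threshold monotonicity
  A <- adjacency(cm)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  A8 <- adjacency(buildContactMap(xyz, "CA_CA", 8))
  expect_true(all(A8 <= A))
})

test_that("bead chains are chain-adjacent under the default threshold", {
  xyz <- sampleChain(60, seed = 13)
  A <- adjacency(buildContactMap(xyz, "CA_CA", 10))
  expect_true(all(A[cbind(1:59, 2:60)] == 1))
})

test_that("ANY-ANY and NBR-NBR modes follow their distance rules", {
  ## two residues whose CAs are far apart but side-chain atoms close
  atoms1 <- rbind(CA = c(0, 0, 0), CB = c(3, 0, 0))
  atoms2 <- rbind(CA = c(10, 0, 0), CB = c(8, 0, 0))
  rc <- residueCoordinates("KK", list(atoms1, atoms2))
  expect_equal(adjacency(buildContactMap(rc, "ANY_ANY", 6.5))[1, 2], 1)
  expect_equal(adjacency(buildContactMap(rc, "CA_CA", 6.5))[1, 2], 0)
  ## NBR-NBR: lysine radius 5.4 -> cutoff 10.8 on CB-CB distance 5
  expect_equal(adjacency(buildContactMap(rc, "NBR_NBR"))[1, 2], 1)
  ## glycine uses CA; alanine pair radius 3.4 + 3.4 < CB distance
  rcGA <- residueCoordinates("GA", list(rbind(CA = c(0, 0, 0)),
                                        rbind(CA = c(9, 0, 0),
                                              CB = c(7, 0, 0))))
  expect_equal(adjacency(buildContactMap(rcGA, "NBR_NBR"))[1, 2], 0)
  ## error paths: missing CA, unknown residue code
  noCA <- residueCoordinates("AA", list(rbind(CB = c(0, 0, 0)),
                                        rbind(CA = c(1, 0, 0))))
  expect_error(buildContactMap(noCA, "CA_CA"), "without a CA")
  rcX <- residueCoordinates("AX", list(atoms1, atoms2))
  expect_error(buildContactMap(rcX, "NBR_NBR"), "X")
})

test_that("filterByLength keeps the inclusive 60-1000 window in order", {
  mk <- function(L) new("ProteinRecord", id = paste0("P", L),
                        sequence = paste(rep("A", L), collapse = ""))
  recs <- lapply(c(59, 60, 1000, 1001), mk)
  suppressMessages(kept <- filterByLength(recs, 60, 1000))
  expect_identical(vapply(kept, proteinId, character(1)), c("P60", "P1000"))
  expect_identical(filterByLength(list(), 60, 1000), list())
  same <- lapply(c(80, 80), mk)
  expect_length(filterByLength(same, 80, 80), 2)
})

test_that("perturbContactMap flips symmetrically at the requested rate", {
  xyz <- sampleChain(200, seed = 17)
  cm <- buildContactMap(xyz, "CA_CA", 10)
  expect_identical(adjacency(perturbContactMap(cm, 0, seed = 1)),
                   adjacency(cm))
  zero <- new("ContactMap", adjacency = matrix(0, 5, 5), mode = "CA_CA",
              threshold = 10)
  flipped <- adjacency(perturbContactMap(zero, 1, seed = 1))
  expect_true(all(flipped[upper.tri(flipped)] == 1))
  expect_true(all(diag(flipped) == 0))

  pert <- perturbContactMap(cm, 0.1, seed = 23)
  A0 <- adjacency(cm); A1 <- adjacency(pert)
  expect_identical(A1, t(A1))
  ut <- upper.tri(A0)
  rate <- mean(A0[ut] != A1[ut])
  n <- sum(ut)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("PDB files parse into dense residue coordinates", {
  pdb <- c(
    "ATOM      1  N   ALA A   3      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   3      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB  ALA A   3      12.919   6.898  -5.040  1.00  0.00           C",
    "ATOM      4  N   GLY A   7       9.580   4.871  -4.442  1.00  0.00           N",
    "ATOM      5  CA  GLY A   7       8.752   4.306  -3.384  1.00  0.00           C",
    "ATOM      6  CA ASER A   9       5.000   4.000  -3.000  0.40  0.00           C",
    "ATOM      7  CA BSER A   9       6.000   4.000  -3.000  0.60  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  rc <- readPDBCoordinates(f, chain = "A")
  expect_equal(rc$sequence, "AGS")
  expect_length(rc$atoms, 3)
  ## author numbering (3, 7, 9) remapped densely, recorded as attribute
  expect_length(attr(rc, "author_numbering"), 3)
  ## altloc resolved to the highest-occupancy conformer
  expect_equal(unname(rc$atoms[[3]]["CA", 1]), 6.0)
  cm <- buildContactMap(rc, "CA_CA", 10)
  expect_equal(nrow(adjacency(cm)), 3)
})

test_that("edge lists are written 0-based with i < j", {
  A <- matrix(0, 4, 4); A[1, 3] <- A[3, 1] <- 1; A[2, 4] <- A[4, 2] <- 1
  cm <- new("ContactMap", adjacency = A, mode = "CA_CA", threshold = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(cm, f)
  el <- read.table(f)
  expect_identical(unname(as.matrix(el)), rbind(c(0L, 2L), c(1L, 3L)))
})
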