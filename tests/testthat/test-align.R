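test_that("identity alignment scores the diagonal sum without gaps", {
  al <- globalAlign("ACDE", "ACDE", SCHEME)
  m <- SCHEME@matrix
  expect_equal(alignmentScore(al), sum(diag(m[c("A", "C", "D", "E"),
                                              c("A", "C", "D", "E")])))
  expect_false(grepl("-", al@alignedA))
  expect_false(grepl("-", al@alignedB))
})

test_that("global and local scores are symmetric in their arguments", {
  set.seed(11)
  for (k in 1:20) {
    a <- randomSeq(sample(3:15, 1))
    b <- randomSeq(sample(3:15, 1))
    expect_equal(alignmentScore(globalAlign(a, b, SCHEME)),
                 alignmentScore(globalAlign(b, a, SCHEME)))
    expect_equal(alignmentScore(localAlign(a, b, SCHEME)),
                 alignmentScore(localAlign(b, a, SCHEME)))
  }
})

test_that("short alignments match the brute-force enumeration oracle", {
  set.seed(7)
  sub <- c("A", "C", "D", "E")
  for (k in 1:50) {
    a <- randomSeq(sample(1:5, 1), sub)
    b <- randomSeq(sample(1:5, 1), sub)
    expect_equal(alignmentScore(globalAlign(a, b, SCHEME)),
                 immfam:::bruteGlobalScore(a, b, SCHEME),
                 info = paste(a, b))
    expect_equal(alignmentScore(localAlign(a, b, SCHEME)),
                 immfam:::bruteLocalScore(a, b, SCHEME),
                 info = paste(a, b))
  }
})

test_that("scores agree with an independent aligner", {
  # cross-check against Biostrings' affine-gap implementation
  requireNamespace("Biostrings", quietly = TRUE)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(13)
  for (k in 1:15) {
    a <- randomSeq(sample(5:40, 1))
    b <- randomSeq(sample(5:40, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 0.5)
    expect_equal(alignmentScore(globalAlign(a, b, SCHEME)),
                 Biostrings::score(ref))
    refL <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 0.5)
    expect_equal(alignmentScore(localAlign(a, b, SCHEME)),
                 max(0, Biostrings::score(refL)))
  }
})

test_that("increasing the gap-opening penalty never raises the score", {
  set.seed(19)
  for (k in 1:10) {
    a <- randomSeq(sample(5:20, 1))
    b <- randomSeq(sample(5:20, 1))
    s1 <- alignmentScore(globalAlign(a, b, defaultScoringScheme(5, 0.5)))
    s2 <- alignmentScore(globalAlign(a, b, defaultScoringScheme(12, 0.5)))
    expect_lte(s2, s1)
  }
})

test_that("tracebacks are deterministic and internally consistent", {
  set.seed(23)
  for (k in 1:10) {
    a <- randomSeq(12)
    b <- randomSeq(15)
    al1 <- globalAlign(a, b, SCHEME)
    al2 <- globalAlign(a, b, SCHEME)
    expect_identical(alignedRows(al1), alignedRows(al2))
    # score recomputable from the gapped rows
    expect_equal(immfam:::pairScoreFromAligned(al1@alignedA, al1@alignedB,
                                               SCHEME),
                 alignmentScore(al1))
    # gap removal reproduces the inputs
    expect_equal(gsub("-", "", al1@alignedA), a)
    expect_equal(gsub("-", "", al1@alignedB), b)
  }
})

test_that("local alignment finds exact substrings and empty optima", {
  inner <- "WCWHMKF"
  outer <- paste0("AAAA", inner, "GGGG")
  al <- localAlign(inner, outer, SCHEME)
  expect_equal(al@bSpan, c(5L, 11L))
  expect_equal(al@aSpan, c(1L, 7L))
  expect_equal(alignmentScore(al), immfam:::selfScore(inner, SCHEME))
  # all-mismatch pair under a matrix with no positive off-diagonals
  m <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "D", "E"),
                                        c("A", "C", "D", "E")))
  diag(m) <- 2
  sc <- scoringScheme(m, 10, 0.5)
  al2 <- localAlign("AC", "DE", sc)
  expect_equal(alignmentScore(al2), 0)
  expect_equal(al2@aSpan, c(0L, 0L))
  expect_equal(nchar(al2@alignedA), 0L)
})

test_that("percent identity follows the column-counting contract", {
  expect_equal(percentIdentity(globalAlign("ACDE", "ACDE", SCHEME)), 100)
  expect_equal(percentIdentity(globalAlign("AAAA", "AAAT", SCHEME)), 75)
  set.seed(29)
  for (k in 1:10) {
    a <- randomSeq(sample(4:20, 1))
    b <- randomSeq(sample(4:20, 1))
    p1 <- percentIdentity(globalAlign(a, b, SCHEME))
    p2 <- percentIdentity(globalAlign(b, a, SCHEME))
    expect_gte(p1, 0)
    expect_lte(p1, 100)
    expect_equal(p1, p2)
  }
})

test_that("percent similarity counts positive-scoring pairs", {
  expect_equal(percentSimilarity(globalAlign("ACDE", "ACDE", SCHEME),
                                 SCHEME), 100)
  expect_gt(SCHEME@matrix["I", "V"], 0)
  expect_equal(percentSimilarity(globalAlign("I", "V", SCHEME), SCHEME),
               100)
  set.seed(31)
  for (k in 1:10) {
    a <- randomSeq(sample(4:20, 1))
    b <- randomSeq(sample(4:20, 1))
    al <- globalAlign(a, b, SCHEME)
    expect_gte(percentSimilarity(al, SCHEME), percentIdentity(al))
  }
})

test_that("p-distance complements identity on gap-free alignments", {
  expect_equal(pDistance(globalAlign("ACDE", "ACDE", SCHEME)), 0)
  expect_equal(pDistance(globalAlign("AAAA", "TTTT", SCHEME)), 1)
  set.seed(37)
  for (k in 1:10) {
    a <- randomSeq(12)
    b <- randomSeq(12)
    al <- globalAlign(a, b, SCHEME)
    if (!grepl("-", al@alignedA) && !grepl("-", al@alignedB))
      expect_equal(pDistance(al), 1 - percentIdentity(al) / 100)
  }
})
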