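test_that("the reference protein recovers its own key residues", {
  p <- extractKeyResidues(REFS@fkbpReference, REFS@fkbpReference,
                          keyPositions(REFS, "FKBP"), SCHEME,
                          family = "FKBP")
  expect_equal(keyResidues(p), keyResidueString(REFS, "FKBP"))
  expect_equal(conservedPercent(p, REFS)@percent, 100L)
})

test_that("a single substitution changes exactly its own slot", {
  s <- REFS@fkbpReference@sequence
  substr(s, 88, 88) <- "A"
  p <- extractKeyResidues(s, REFS@fkbpReference,
                          keyPositions(REFS, "FKBP"), SCHEME,
                          family = "FKBP")
  ref <- keyResidueString(REFS, "FKBP")
  idx88 <- which(keyPositions(REFS, "FKBP")$position == 88)
  expect_equal(substr(keyResidues(p), idx88, idx88), "A")
  same <- seq_len(nchar(ref))[-idx88]
  expect_equal(strsplit(keyResidues(p), "")[[1]][same],
               strsplit(ref, "")[[1]][same])
})

test_that("key residues are recovered from mutated synthetic domains", {
  cfg <- generatorConfig(nProteins = 60L, seed = 67L,
                         keyMutationRate = 0.1,
                         backgroundMutationRate = 0.1,
                         signalProbs = c(tat_cleaved = 0, tat_anchored = 0,
                                         er = 0, nls = 0, none = 1),
                         multiDomainProb = 0, rkLinkerProb = 0)
  fam <- generateFamily(cfg)
  seqs <- sequences(fam$records)
  exact <- vapply(seq_len(nrow(fam$truth)), function(i) {
    famLab <- fam$truth$family[i]
    p <- extractKeyResidues(seqs[[i]], referenceProtein(REFS, famLab),
                            keyPositions(REFS, famLab), SCHEME,
                            family = famLab)
    identical(keyResidues(p), fam$truth$key_residues[i])
  }, logical(1))
  expect_gte(mean(exact), 0.95)
})

test_that("conservation percentages reproduce the printed table rows", {
  expect_equal(conservedPercent(tableRow(TABLE1, "OsFKBP13")$os,
                                REFS)@percent, 86L)
  expect_equal(conservedPercent(tableRow(TABLE2, "OsCYP17")$os,
                                REFS)@percent, 43L)
  r <- conservedPercent(tableRow(TABLE1, "OsFKBP13")$os, REFS)
  expect_equal(r@conservedCount, 12L)
  expect_equal(r@total, 14L)
})

test_that("profile similarity works in both modes", {
  r164 <- tableRow(TABLE1, "OsFKBP16-4")
  expect_equal(pairSimilarityPercent(r164$os, r164$at, "identity"), 93L)
  p <- tableRow(TABLE1, "OsFKBP13")$os
  expect_equal(pairSimilarityPercent(p, p, "identity"), 100L)
  expect_equal(pairSimilarityPercent(p, p, "matrix_positive", SCHEME), 100L)
  set.seed(71)
  pos <- keyPositions(REFS, "FKBP")$position
  for (k in 1:25) {
    a <- new("KeyResidueProfile", proteinId = "a", family = "FKBP",
             residues = randomSeq(14), positions = as.integer(pos))
    b <- new("KeyResidueProfile", proteinId = "b", family = "FKBP",
             residues = randomSeq(14), positions = as.integer(pos))
    expect_gte(pairSimilarityPercent(a, b, "matrix_positive", SCHEME),
               pairSimilarityPercent(a, b, "identity"))
  }
})

test_that("column conservation counts profiles retaining the residue", {
  osAll <- Filter(Negate(is.null), lapply(TABLE1$rows, `[[`, "os"))
  expect_equal(length(osAll), 28L)
  idx88 <- which(TABLE1$positions == 88)
  expect_equal(columnConservation(osAll, idx88, REFS), 0L)
  ref <- extractKeyResidues(REFS@fkbpReference, REFS@fkbpReference,
                            keyPositions(REFS, "FKBP"), SCHEME, "FKBP")
  for (i in c(1L, 7L, 14L))
    expect_equal(columnConservation(list(ref), i, REFS), 100L)
  nonCons <- new("KeyResidueProfile", proteinId = "x", family = "FKBP",
                 residues = strrep("G", 14),
                 positions = ref@positions)
  expect_equal(columnConservation(list(ref, nonCons <- nonCons), 1L, REFS),
               50L)
})

test_that("rounding is half away from zero", {
  expect_equal(roundHalfUp(85.5), 86L)
  expect_equal(roundHalfUp(100 * 12 / 14), 86L)
  expect_equal(roundHalfUp(100 * 10 / 14), 71L)
  expect_equal(roundHalfUp(-2.5), -3L)
})
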