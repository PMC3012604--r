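noSignalProbs <- c(tat_cleaved = 0, tat_anchored = 0, er = 0, nls = 0,
                   none = 1)

test_that("the zero-mutation limit reproduces the ancestor core", {
  cfg <- generatorConfig(nProteins = 1L, fkbpProportion = 1,
                         keyMutationRate = 0, backgroundMutationRate = 0,
                         signalProbs = noSignalProbs, multiDomainProb = 0,
                         rkLinkerProb = 0, seed = 103L)
  fam <- generateFamily(cfg)
  expect_equal(unname(sequences(fam$records)),
               REFS@fkbpReference@sequence)
  expect_equal(fam$truth$n_domains, 1L)
  expect_equal(fam$truth$domain_starts, "1")
  expect_equal(fam$truth$domain_ends,
               as.character(nchar(REFS@fkbpReference@sequence)))
  expect_equal(fam$truth$key_residues, keyResidueString(REFS, "FKBP"))
})

test_that("forced Tat-with-cleavage puts every protein in the lumen", {
  cfg <- generatorConfig(nProteins = 25L,
                         signalProbs = c(tat_cleaved = 1, tat_anchored = 0,
                                         er = 0, nls = 0, none = 0),
                         seed = 107L)
  fam <- generateFamily(cfg)
  expect_true(all(fam$truth$compartment == "chloroplast_lumen"))
  expect_true(all(!is.na(fam$truth$cleavage_site)))
})

test_that("empirical substitution rate tracks the configured rate", {
  rho <- 0.1
  cfg <- generatorConfig(nProteins = 200L, keyMutationRate = rho,
                         backgroundMutationRate = rho,
                         signalProbs = noSignalProbs, multiDomainProb = 0,
                         rkLinkerProb = 0, seed = 7L)
  fam <- generateFamily(cfg)
  seqs <- sequences(fam$records)
  diffs <- 0L
  sites <- 0L
  for (i in seq_len(nrow(fam$truth))) {
    anc <- if (fam$truth$family[i] == "FKBP") REFS@fkbpReference
           else REFS@cypReference
    a <- immfam:::seqChars(anc@sequence)
    b <- immfam:::seqChars(seqs[[i]])
    keyPos <- keyPositions(REFS, fam$truth$family[i])$position
    nonKey <- setdiff(seq_along(a), keyPos)
    diffs <- diffs + sum(a[nonKey] != b[nonKey])
    sites <- sites + length(nonKey)
  }
  expect_lt(abs(diffs / sites - rho), 0.02)
})

test_that("the same seed regenerates records and truth byte-identically", {
  cfg <- generatorConfig(nProteins = 30L, seed = 109L)
  f1 <- generateFamily(cfg)
  f2 <- generateFamily(cfg)
  expect_identical(sequences(f1$records), sequences(f2$records))
  expect_identical(f1$truth, f2$truth)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  writeFasta(f1$records, p1)
  writeFasta(f2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("truth compartments are self-consistent with the precedence rule", {
  fam <- generateFamily(generatorConfig(nProteins = 120L, seed = 113L))
  expected <- vapply(fam$truth$signal, function(sig)
    switch(sig, tat_cleaved = "chloroplast_lumen",
           tat_anchored = "chloroplast_membrane_anchored", er = "ER",
           nls = "nucleus", none = "cytosol"), character(1))
  expect_equal(fam$truth$compartment, unname(expected))
  # implanted coordinates lie within the sequence
  lens <- nchar(sequences(fam$records))
  for (col in c("rr_position", "h_end", "cleavage_site", "rk_end",
                "nls_end")) {
    v <- fam$truth[[col]]
    expect_true(all(is.na(v) | (v >= 1 & v <= lens)))
  }
})

test_that("a clean family scores perfect recovery metrics", {
  cfg <- generatorConfig(nProteins = 12L, keyMutationRate = 0,
                         backgroundMutationRate = 0,
                         signalProbs = noSignalProbs, multiDomainProb = 0,
                         rkLinkerProb = 0, seed = 127L)
  fam <- generateFamily(cfg)
  res <- classifyProteins(fam$records)
  m <- scoreRecovery(fam$truth, res)
  expect_equal(m$domainCountAccuracy, 1)
  expect_equal(m$boundaryMae, 0)
  expect_equal(m$compartmentAccuracy, 1)
  expect_equal(m$tatFpr, 0)
  # mismatched id sets are rejected
  expect_error(scoreRecovery(fam$truth[-1, ], res), "different record")
})

test_that("higher key-mutation rates depress conservation", {
  consMean <- function(kappa, seed) {
    cfg <- generatorConfig(nProteins = 60L, keyMutationRate = kappa,
                           backgroundMutationRate = 0.05,
                           signalProbs = noSignalProbs,
                           multiDomainProb = 0, rkLinkerProb = 0,
                           seed = seed)
    fam <- generateFamily(cfg)
    vals <- vapply(seq_len(nrow(fam$truth)), function(i) {
      ref <- keyResidueString(REFS, fam$truth$family[i])
      a <- immfam:::seqChars(ref)
      b <- immfam:::seqChars(fam$truth$key_residues[i])
      100 * mean(a == b)
    }, numeric(1))
    mean(vals)
  }
  expect_lt(consMean(0.5, 131L), consMean(0.05, 131L))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generatorConfig(signalProbs = c(tat_cleaved = 0.5,
                                               tat_anchored = 0.5, er = 0.5,
                                               nls = 0, none = 0)),
               "sum to 1")
  expect_error(generatorConfig(keyMutationRate = 1.5), "\\[0, 1\\]")
  expect_error(generatorConfig(nProteins = 0), ">= 1")
})
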