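test_that("an implanted exact reference domain is found with tight bounds", {
  fk <- REFS@fkbpReference@sequence
  set.seed(41)
  prot <- paste0("M", randomSeq(25, immfam:::.NEUTRAL), fk,
                 randomSeq(15, immfam:::.NEUTRAL))
  hits <- scanPpiaseDomains(prot, REFS, SCHEME)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$family, "FKBP")
  trueStart <- 27L
  trueEnd <- 26L + nchar(fk)
  expect_lte(abs(hits$start - trueStart), 2L)
  expect_lte(abs(hits$end - trueEnd), 2L)
  expect_equal(hits$normalizedScore, 1)
})

test_that("a triple-domain construct yields three ordered hits", {
  set.seed(43)
  core <- immfam:::seqChars(REFS@cypReference@sequence)
  copies <- lapply(1:3, function(k)
    paste(immfam:::.mutateCore(core, integer(0), 0, 0.1), collapse = ""))
  prot <- paste0(copies[[1]], "GSTNQ", copies[[2]], "GSTNQ", copies[[3]])
  hits <- scanPpiaseDomains(prot, REFS, SCHEME)
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$family == "CYP"))
  expect_true(all(diff(hits$start) > 0))
  # non-overlap invariant
  expect_true(all(hits$start[-1] > hits$end[-3]))
})

test_that("uniform random sequence produces no hits at the default cutoff", {
  set.seed(47)
  prot <- randomSeq(300)
  hits <- scanPpiaseDomains(prot, REFS, SCHEME, minNormalized = 0.3)
  expect_equal(nrow(hits), 0L)
})

test_that("the representative domain is the most conserved copy", {
  h <- data.frame(family = "FKBP", start = c(1L, 120L, 240L),
                  end = c(100L, 220L, 340L), rawScore = c(1, 2, 3),
                  normalizedScore = c(0.41, 0.77, 0.52))
  expect_equal(selectRepresentativeDomain(h)$start, 120L)
  expect_equal(selectRepresentativeDomain(h[1, ])$start, 1L)
  expect_error(selectRepresentativeDomain(h[0, ]), "empty")
  # tie -> smallest start
  h$normalizedScore <- c(0.7, 0.7, 0.5)
  expect_equal(selectRepresentativeDomain(h)$start, 1L)
})

test_that("a lightly mutated middle copy becomes the representative", {
  set.seed(53)
  core <- immfam:::seqChars(REFS@fkbpReference@sequence)
  mut <- function(rate) paste(immfam:::.mutateCore(core, integer(0), 0,
                                                   rate), collapse = "")
  prot <- paste0(mut(0.25), "GSTNQ", mut(0.02), "GSTNQ", mut(0.25))
  hits <- scanPpiaseDomains(prot, REFS, SCHEME)
  expect_equal(nrow(hits), 3L)
  rep <- selectRepresentativeDomain(hits)
  # the middle copy starts after the first core + linker
  expect_gt(rep$start, 108L)
  expect_lt(rep$end, 2L * 108L + 12L)
})

test_that("Arg/Lys-rich detection finds implanted blocks only", {
  pos <- paste0(strrep("A", 50), strrep("KR", 10), strrep("A", 50))
  spans <- detectRkRich(pos, window = 10L, minFraction = 0.5,
                        minLength = 20L)
  expect_equal(nrow(spans), 1L)
  expect_lte(spans$start, 51L)
  expect_gte(spans$end, 70L)
  expect_lte(51L - spans$start, 10L)
  expect_lte(spans$end - 70L, 10L)
  expect_equal(nrow(detectRkRich(strrep("A", 200))), 0L)
})

test_that("implanted R/K linkers are recovered at generator defaults", {
  cfg <- generatorConfig(nProteins = 100L, rkLinkerProb = 1,
                         signalProbs = c(tat_cleaved = 0, tat_anchored = 0,
                                         er = 0, nls = 0, none = 1),
                         multiDomainProb = 0, seed = 59L)
  fam <- generateFamily(cfg)
  seqs <- sequences(fam$records)
  found <- vapply(seq_len(nrow(fam$truth)), function(i) {
    spans <- detectRkRich(seqs[[i]])
    any(spans$start <= fam$truth$rk_end[i] &
          spans$end >= fam$truth$rk_start[i])
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("architecture classification builds SD/MD and composition", {
  oneHit <- data.frame(family = "FKBP", start = 10L, end = 110L,
                       rawScore = 1, normalizedScore = 0.9)
  arch <- classifyArchitecture(oneHit, proteinId = "p1")
  expect_equal(arch@sdMd, "SD")
  expect_equal(arch@composition, "FKBP")

  threeHits <- data.frame(family = "FKBP", start = c(1L, 120L, 240L),
                          end = c(100L, 220L, 340L), rawScore = 1:3,
                          normalizedScore = c(0.8, 0.9, 0.7))
  aux <- data.frame(feature = c("TPR", "CaM"), start = c(350L, 420L),
                    end = c(400L, 450L))
  arch2 <- classifyArchitecture(threeHits, aux, "p2")
  expect_equal(arch2@sdMd, "MD")
  expect_equal(arch2@composition, "FKBP×3+TPR+CaM")

  cypHit <- data.frame(family = "CYP", start = 1L, end = 160L,
                       rawScore = 1, normalizedScore = 0.9)
  aux3 <- data.frame(feature = c("RRM", "zinc-finger", "RK"),
                     start = c(200L, 300L, 380L), end = c(280L, 330L, 450L))
  arch3 <- classifyArchitecture(cypHit, aux3, "p3")
  expect_equal(arch3@sdMd, "MD")
  expect_equal(arch3@composition, "CYP+RRM+zinc-finger+RK")
})

test_that("scan is capped at maxCopies and masking terminates it", {
  core <- REFS@fkbpReference@sequence
  prot <- paste(rep(core, 5), collapse = "GSTNQ")
  hits <- scanPpiaseDomains(prot, REFS, SCHEME, maxCopies = 4L)
  expect_equal(nrow(hits), 4L)
  hits2 <- scanPpiaseDomains(prot, REFS, SCHEME, maxCopies = 2L)
  expect_equal(nrow(hits2), 2L)
})
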