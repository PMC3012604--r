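test_that("mature mass follows the average-mass bookkeeping", {
  m <- matureMass(strrep("G", 10))
  expect_equal(m$da, 10 * 57.0519 + 18.0153, tolerance = 1e-9)
  expect_equal(m$kda, 1L)
  # cleavage leaves the suffix
  s <- paste0("MLLLLAHA", strrep("G", 10))
  expect_equal(matureMass(s, cleavagePosition = 8L)$da,
               matureMass(strrep("G", 10))$da)
  expect_error(matureMass("ACDE", cleavagePosition = 4L), "empty mature")
  # mass strictly increases when residues are appended
  set.seed(73)
  for (k in 1:10) {
    a <- randomSeq(sample(5:30, 1))
    expect_gt(matureMass(paste0(a, randomSeq(1)))$da, matureMass(a)$da)
  }
})

mkRef <- function(id, seq, suffix, comp = "cytosol", arch = "FKBP") {
  list(record = ProteinRecord(id, seq), compartment = comp,
       composition = arch, suffix = suffix)
}

test_that("ortholog gates require identity, location and architecture", {
  base <- REFS@fkbpReference@sequence
  set.seed(79)
  nearSeq <- paste(immfam:::.mutateCore(immfam:::seqChars(base),
                                        integer(0), 0, 0.1), collapse = "")
  refs <- list(mkRef("AtFKBP13", base, "13"),
               mkRef("AtFKBP99", randomSeq(110), "99"))
  cand <- list(record = ProteinRecord("q", nearSeq),
               compartment = "cytosol", composition = "FKBP")
  a <- assignOrtholog(cand, refs)
  expect_equal(a@orthologId, "AtFKBP13")
  expect_equal(a@orthologSuffix, "13")
  expect_gt(a@identityPercent, 50)

  candWrongLoc <- cand
  candWrongLoc$compartment <- "nucleus"
  a2 <- assignOrtholog(candWrongLoc, refs)
  expect_true(is.na(a2@orthologId))

  candWrongArch <- cand
  candWrongArch$composition <- "FKBP×2"
  expect_true(is.na(assignOrtholog(candWrongArch, refs)@orthologId))

  expect_true(is.na(assignOrtholog(cand, list())@orthologId))
})

mkAsn <- function(id, refId, suffix, sim) {
  new("OrthologAssignment", candidateId = id, orthologId = refId,
      orthologSuffix = suffix, identityPercent = sim,
      similarityPercent = sim, locationMatch = TRUE,
      architectureMatch = TRUE)
}

test_that("paralog letters follow decreasing similarity", {
  cands <- list(
    list(id = "g1", family = "CYP", assignment = mkAsn("g1", "AtCYP40",
                                                       "40", 73),
         massDa = 40000, record = ProteinRecord("g1", randomSeq(50))),
    list(id = "g2", family = "CYP", assignment = mkAsn("g2", "AtCYP40",
                                                       "40", 70),
         massDa = 40500, record = ProteinRecord("g2", randomSeq(50))))
  nm <- assignNames(cands, "Os")
  expect_equal(nameString(nm[["g1"]]), "OsCYP40a")
  expect_equal(nameString(nm[["g2"]]), "OsCYP40b")
  # permuting the input changes nothing
  nm2 <- assignNames(rev(cands), "Os")
  expect_equal(nameString(nm2[["g1"]]), "OsCYP40a")
  expect_equal(nameString(nm2[["g2"]]), "OsCYP40b")
})

test_that("three shared-ortholog paralogs letter a/b/c", {
  cands <- lapply(seq_len(3), function(i)
    list(id = paste0("c", i), family = "FKBP",
         assignment = mkAsn(paste0("c", i), "AtFKBP62", "62",
                            c(77, 75, 73)[i]),
         massDa = 62000, record = ProteinRecord(paste0("c", i),
                                                randomSeq(60))))
  nm <- assignNames(cands[c(2, 3, 1)], "Os")
  expect_equal(nameString(nm[["c1"]]), "OsFKBP62a")
  expect_equal(nameString(nm[["c2"]]), "OsFKBP62b")
  expect_equal(nameString(nm[["c3"]]), "OsFKBP62c")
  letters3 <- sort(unname(vapply(nm, function(x) x@paralogLetter,
                                 character(1))))
  expect_equal(letters3, c("a", "b", "c"))
})

test_that("candidates without an ortholog get molecular-weight names", {
  cands <- list(list(id = "solo", family = "FKBP", assignment = NULL,
                     massDa = 46210,
                     record = ProteinRecord("solo", randomSeq(80))))
  nm <- assignNames(cands, "Os")
  expect_equal(nameString(nm[["solo"]]), "OsFKBP46")
})

test_that("trigger-factor candidates are named <prefix>TIG", {
  cands <- list(list(id = "tf", family = "TIG", assignment = NULL,
                     massDa = 55000,
                     record = ProteinRecord("tf", randomSeq(80))))
  expect_equal(nameString(assignNames(cands, "Os")[["tf"]]), "OsTIG")
})

test_that("names are unique and letters contiguous from 'a'", {
  set.seed(83)
  cands <- lapply(1:8, function(i)
    list(id = paste0("m", i), family = "CYP", assignment = NULL,
         massDa = 18000 + (i %% 2) * 4000,
         record = ProteinRecord(paste0("m", i), randomSeq(60))))
  nm <- assignNames(cands, "Os")
  full <- vapply(nm, nameString, character(1))
  expect_equal(anyDuplicated(full), 0L)
  for (sfx in c("18", "22")) {
    grp <- vapply(nm, function(x)
      if (x@suffix == sfx) x@paralogLetter else NA_character_, character(1))
    expect_equal(sort(unname(grp[!is.na(grp)])), letters[1:4])
  }
})
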