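test_that("two-sequence MSA equals the global pairwise alignment", {
  set.seed(87)
  a <- randomSeq(30)
  b <- randomSeq(25)
  msa <- progressiveMsa(c(x = a, y = b), SCHEME)
  al <- globalAlign(a, b, SCHEME)
  expect_equal(unname(msa["x"]), al@alignedA)
  expect_equal(unname(msa["y"]), al@alignedB)
})

test_that("identical sequences align without gaps", {
  s <- randomSeq(40)
  msa <- progressiveMsa(c(a = s, b = s, c = s), SCHEME)
  expect_false(any(grepl("-", msa)))
  expect_equal(unname(nchar(msa)), rep(40L, 3))
})

test_that("the guide tree never hurts the sum-of-pairs score", {
  # structured triples: two close relatives plus one distant sequence in
  # unfavourable input order, so input-order merging must not win
  set.seed(89)
  naiveMerge <- function(seqs, scheme) {
    prof <- list(rows = unname(seqs[1]), ids = names(seqs)[1])
    for (k in 2:length(seqs)) {
      other <- list(rows = unname(seqs[k]), ids = names(seqs)[k])
      res <- immfam:::align_profiles_cpp(
        immfam:::.profileCounts(prof$rows, scheme),
        immfam:::.profileCounts(other$rows, scheme),
        scheme@matrix, scheme@gapOpen, scheme@gapExtend,
        length(prof$rows), length(other$rows))
      prof <- list(rows = c(immfam:::.applyMapping(prof$rows, res$idxA),
                            immfam:::.applyMapping(other$rows, res$idxB)),
                   ids = c(prof$ids, other$ids))
    }
    stats::setNames(prof$rows, prof$ids)
  }
  for (k in 1:5) {
    anc <- immfam:::seqChars(randomSeq(60))
    near1 <- paste(immfam:::.mutateCore(anc, integer(0), 0, 0.05),
                   collapse = "")
    near2 <- paste(immfam:::.mutateCore(anc, integer(0), 0, 0.05),
                   collapse = "")
    far <- paste(immfam:::.mutateCore(anc, integer(0), 0, 0.5),
                 collapse = "")
    seqs <- c(a = near1, b = far, c = near2)
    expect_gte(spScore(progressiveMsa(seqs, SCHEME), SCHEME),
               spScore(naiveMerge(seqs, SCHEME), SCHEME) - 1e-9)
  }
})

test_that("p-distance matrices follow the gap-free column rule", {
  msa <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL")
  expect_equal(unname(pDistanceMatrix(msa)["a", "b"]), 0)
  msa2 <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKW")
  expect_equal(unname(pDistanceMatrix(msa2)["a", "b"]), 0.1)
  expect_error(pDistanceMatrix(c(a = "A-", b = "-A")), "gap-free")
  # consistency with the pairwise p-distance
  set.seed(91)
  for (k in 1:5) {
    a <- randomSeq(25)
    b <- randomSeq(25)
    al <- globalAlign(a, b, SCHEME)
    D <- pDistanceMatrix(c(x = al@alignedA, y = al@alignedB))
    expect_equal(unname(D["x", "y"]), pDistance(al))
  }
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  co <- stats::cophenetic(tr)
  expect_equal(co[rownames(D), colnames(D)], D)
  lens <- sort(tr$edge.length)
  expect_equal(lens, sort(c((5 + 9 - 10) / 2, (5 + 10 - 9) / 2,
                            (9 + 10 - 5) / 2)))
})

test_that("NJ exactly recovers additive trees up to 8 taxa", {
  set.seed(93)
  for (k in 1:25) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n)
    true$edge.length <- stats::runif(nrow(true$edge), 0.1, 1)
    D <- stats::cophenetic(true)
    est <- neighborJoining(D)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(stats::cophenetic(est)[rownames(D), colnames(D)] -
                        D)), 1e-8)
  }
  expect_error(neighborJoining(matrix(0, 2, 2)), "three taxa")
})

test_that("negative NJ branch estimates are clamped and flagged", {
  D <- matrix(c(0, 2, 2, 2, 0, 5, 2, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clamped"))
})

test_that("Newick output round-trips and quotes awkward labels", {
  star <- list(edge = matrix(c(4L, 4L, 4L, 1L, 2L, 3L), 3, 2),
               tip.label = c("A", "B", "C"), edge.length = c(1, 1, 1),
               Nnode = 1L)
  class(star) <- "phylo"
  txt <- writeNewickTree(star)
  expect_match(txt, "^\\(.*\\);$")
  expect_setequal(readNewickTree(txt)$tip.label, c("A", "B", "C"))
  set.seed(97)
  for (k in 1:5) {
    tr <- ape::rtree(sample(4:9, 1))
    tr2 <- readNewickTree(writeNewickTree(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
  }
  starQ <- star
  starQ$tip.label <- c("a b", "B", "C")
  expect_match(writeNewickTree(starQ), "'a b'", fixed = TRUE)
})

test_that("synthetic clades are recovered as monophyletic splits", {
  set.seed(101)
  ok <- 0L
  runs <- 10L
  for (r in seq_len(runs)) {
    core <- immfam:::seqChars(REFS@fkbpReference@sequence)
    ancestors <- lapply(1:3, function(k)
      immfam:::.mutateCore(core, integer(0), 0, 0.3))
    seqs <- c()
    for (cl in 1:3) for (j in 1:4) {
      seqs[paste0("C", cl, "_", j)] <-
        paste(immfam:::.mutateCore(ancestors[[cl]], integer(0), 0, 0.05),
              collapse = "")
    }
    tree <- neighborJoining(pDistanceMatrix(progressiveMsa(seqs, SCHEME)))
    good <- all(vapply(1:3, function(cl)
      isMonophyleticSplit(tree, paste0("C", cl, "_", 1:4)), logical(1)))
    ok <- ok + good
  }
  expect_gte(ok / runs, 0.9)
})
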