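# Family phylogeny: progressive multiple alignment, p-distance matrix,
# neighbor joining, Newick serialization.

# Residue-count profile of a set of gapped rows: K x L matrix over the
# scheme's alphabet, gaps excluded.
.profileCounts <- function(rows, scheme) {
  letters <- rownames(scheme@matrix)
  L <- nchar(rows[1])
  counts <- matrix(0, nrow = length(letters), ncol = L,
                   dimnames = list(letters, NULL))
  for (r in rows) {
    ch <- seqChars(r)
    idx <- match(ch, letters)
    keep <- !is.na(idx)
    tab <- table(factor(idx[keep], levels = seq_along(letters)),
                 factor(which(keep), levels = seq_len(L)))
    counts <- counts + as.matrix(tab)
  }
  counts
}

.applyMapping <- function(rows, idx) {
  vapply(rows, function(r) {
    ch <- seqChars(r)
    out <- rep("-", length(idx))
    out[idx > 0L] <- ch[idx[idx > 0L]]
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Progressive multiple sequence alignment
#'
#' Classic progressive strategy: pairwise global alignments give a
#' p-distance matrix, average-linkage (UPGMA) clustering gives the guide
#' tree, and profiles are merged bottom-up by profile-profile affine-gap
#' alignment with sum-of-pairs column scoring. A heuristic, not an
#' optimal MSA.
#'
#' @param x a [ProteinSet-class] or named character vector of sequences
#'   (>= 2).
#' @param scheme a [ScoringScheme-class].
#' @return Named character vector of gapped rows (equal length), in input
#'   order.
#' @export
progressiveMsa <- function(x, scheme = defaultScoringScheme()) {
  seqs <- if (is(x, "ProteinSet")) sequences(x) else x
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (n == 2L) {
    al <- globalAlign(seqs[[1]], seqs[[2]], scheme)
    return(stats::setNames(c(al@alignedA, al@alignedB), names(seqs)))
  }
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    al <- globalAlign(seqs[[i]], seqs[[j]], scheme)
    D[i, j] <- D[j, i] <- tryCatch(pDistance(al), error = function(e) 1)
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profiles <- vector("list", nrow(hc$merge))
  leafProfile <- function(i) list(rows = unname(seqs[i]),
                                  ids = names(seqs)[i])
  getProfile <- function(ref) {
    if (ref < 0L) leafProfile(-ref) else profiles[[ref]]
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- getProfile(hc$merge[k, 1])
    b <- getProfile(hc$merge[k, 2])
    res <- align_profiles_cpp(.profileCounts(a$rows, scheme),
                              .profileCounts(b$rows, scheme),
                              scheme@matrix, scheme@gapOpen,
                              scheme@gapExtend, length(a$rows),
                              length(b$rows))
    profiles[[k]] <- list(rows = c(.applyMapping(a$rows, res$idxA),
                                   .applyMapping(b$rows, res$idxB)),
                          ids = c(a$ids, b$ids))
  }
  final <- profiles[[nrow(hc$merge)]]
  rows <- stats::setNames(final$rows, final$ids)[names(seqs)]
  # drop columns gapped in every row (cannot arise from merging, but the
  # contract promises it)
  ch <- do.call(rbind, strsplit(rows, ""))
  keep <- colSums(ch != "-") > 0L
  stats::setNames(apply(ch[, keep, drop = FALSE], 1L, paste,
                        collapse = ""), names(rows))
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Sum over all row pairs of the affine-gap score of the induced pairwise
#' alignment (columns gapped in both rows dropped).
#'
#' @param msa named character vector of gapped rows.
#' @param scheme a [ScoringScheme-class].
#' @return Numeric score.
#' @export
spScore <- function(msa, scheme = defaultScoringScheme()) {
  n <- length(msa)
  s <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    s <- s + pairScoreFromAligned(msa[[i]], msa[[j]], scheme)
  s
}

#' p-distance matrix of a multiple alignment
#'
#' Pairwise proportion of differing sites among columns gap-free in both
#' rows of the pair.
#'
#' @param msa named character vector of gapped rows (>= 2).
#' @return Symmetric matrix with zero diagonal and the row names as
#'   labels.
#' @export
pDistanceMatrix <- function(msa) {
  n <- length(msa)
  if (n < 2L) stop("need at least two rows")
  ch <- do.call(rbind, strsplit(msa, ""))
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    both <- ch[i, ] != "-" & ch[j, ] != "-"
    if (!any(both))
      stop("rows '", names(msa)[i], "' and '", names(msa)[j],
           "' share no gap-free columns")
    D[i, j] <- D[j, i] <- sum(ch[i, both] != ch[j, both]) / sum(both)
  }
  D
}

# Pairwise p-distances from individual global alignments; defined for any
# pair of non-empty sequences, unlike the MSA-induced matrix. Used by the
# pipeline as a fallback when the family MSA leaves a pair without shared
# gap-free columns.
pairwisePDistances <- function(seqs, scheme) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    al <- globalAlign(seqs[[i]], seqs[[j]], scheme)
    D[i, j] <- D[j, i] <- tryCatch(pDistance(al), error = function(e) 1)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (exact on additive matrices). Negative
#' branch-length estimates are clamped to zero and the tree is flagged
#' via `attr(tree, "clamped")`.
#'
#' @param D symmetric distance matrix with labels (>= 3 taxa, zero
#'   diagonal, finite entries).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least three taxa")
  if (!isSymmetric(unname(D)) || any(!is.finite(D)) ||
      any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be symmetric, finite, with zero diagonal")
  tree <- ape::nj(D)
  clamped <- any(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

.quoteNewickLabel <- function(lab) {
  if (grepl("[][():;, ']", lab))
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  else lab
}

#' Serialize a tree to Newick
#'
#' Parenthesized Newick with branch lengths, ';'-terminated. Labels
#' containing Newick metacharacters are single-quoted.
#'
#' @param tree an `ape::phylo` tree.
#' @param file optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
writeNewickTree <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nTip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  len <- function(e) {
    if (is.null(tree$edge.length)) ""
    else paste0(":", format(tree$edge.length[e], digits = 10,
                            scientific = FALSE, trim = TRUE))
  }
  serialize <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(.quoteNewickLabel(tree$tip.label[node]))
    inner <- vapply(kids, function(e)
      paste0(serialize(tree$edge[e, 2]), len(e)), character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  txt <- paste0(serialize(nTip + 1L), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Parse a Newick string or file
#'
#' @param x Newick text or a path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
readNewickTree <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x)
  tr <- ape::read.tree(text = paste(x, collapse = ""))
  if (is.null(tr)) stop("failed to parse Newick input")
  tr
}

#' Is a set of tips a split (unrooted clade) of a tree?
#'
#' TRUE when some edge of the unrooted tree separates exactly `tips` from
#' the remaining leaves, i.e. the set is monophyletic under some rooting.
#'
#' @param tree an `ape::phylo` tree.
#' @param tips character vector of tip labels.
#' @return Logical.
#' @export
isMonophyleticSplit <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip label(s)")
  parts <- ape::prop.part(tree)
  target <- sort(idx)
  comp <- sort(setdiff(seq_along(tree$tip.label), idx))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}
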