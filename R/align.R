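# Pairwise affine-gap alignment and alignment statistics.

.buildPairAlignment <- function(res, scheme, mode) {
  letters <- rownames(scheme@matrix)
  toStr <- function(idx) {
    if (!length(idx)) return("")
    ch <- ifelse(idx == 0L, "-", letters[pmax(idx, 1L)])
    paste(ch, collapse = "")
  }
  new("PairAlignment", alignedA = toStr(res$ai), alignedB = toStr(res$bi),
      score = res$score, mode = mode,
      aSpan = c(res$a_start, res$a_end), bSpan = c(res$b_start, res$b_end))
}

#' Global (Needleman-Wunsch-style) affine-gap alignment
#'
#' True global alignment: terminal gaps are penalized. A gap of length L
#' costs `gapOpen + L * gapExtend`. The traceback is deterministic
#' (ties prefer diagonal, then gap in the second sequence, then gap in the
#' first).
#'
#' @param a,b [ProteinRecord-class] objects or sequence strings (non-empty).
#' @param scheme a [ScoringScheme-class].
#' @return A [PairAlignment-class].
#' @examples
#' al <- globalAlign("ACDE", "ACDE")
#' alignmentScore(al)  # 24 under BLOSUM62
#' @export
globalAlign <- function(a, b, scheme = defaultScoringScheme()) {
  sa <- asSequence(a)
  sb <- asSequence(b)
  if (!nchar(sa) || !nchar(sb)) stop("sequences must be non-empty")
  res <- align_pair_cpp(seqToIdx(sa, scheme), seqToIdx(sb, scheme),
                        scheme@matrix, scheme@gapOpen, scheme@gapExtend,
                        FALSE)
  .buildPairAlignment(res, scheme, "global")
}

#' Local (Smith-Waterman-style) affine-gap alignment
#'
#' Score is always >= 0; when no positive-scoring alignment exists the
#' result is the empty alignment with score 0 and zero-length spans.
#'
#' @inheritParams globalAlign
#' @return A [PairAlignment-class].
#' @export
localAlign <- function(a, b, scheme = defaultScoringScheme()) {
  sa <- asSequence(a)
  sb <- asSequence(b)
  if (!nchar(sa) || !nchar(sb)) stop("sequences must be non-empty")
  res <- align_pair_cpp(seqToIdx(sa, scheme), seqToIdx(sb, scheme),
                        scheme@matrix, scheme@gapOpen, scheme@gapExtend,
                        TRUE)
  .buildPairAlignment(res, scheme, "local")
}

#' Percent identity of a pairwise alignment
#'
#' 100 x identical columns / denominator. Gap columns never count as
#' identical. The default denominator counts every aligned column
#' including gap columns; "shorter_seq" divides by the length of the
#' shorter aligned (sub)sequence instead.
#'
#' @param al a [PairAlignment-class] (non-empty).
#' @param denominator "aligned_columns" or "shorter_seq".
#' @return Percentage in `[0, 100]`.
#' @export
percentIdentity <- function(al,
                            denominator = c("aligned_columns",
                                            "shorter_seq")) {
  denominator <- match.arg(denominator)
  if (!nchar(al@alignedA)) stop("empty alignment")
  a <- seqChars(al@alignedA)
  b <- seqChars(al@alignedB)
  ident <- sum(a == b & a != "-")
  den <- if (denominator == "aligned_columns") length(a)
         else min(sum(a != "-"), sum(b != "-"))
  100 * ident / den
}

#' Percent similarity of a pairwise alignment
#'
#' Like [percentIdentity()] but counting every column whose substitution
#' score is positive (identities included).
#'
#' @inheritParams percentIdentity
#' @param scheme the [ScoringScheme-class] providing the substitution
#'   scores.
#' @return Percentage in `[0, 100]`.
#' @export
percentSimilarity <- function(al, scheme = defaultScoringScheme(),
                              denominator = c("aligned_columns",
                                              "shorter_seq")) {
  denominator <- match.arg(denominator)
  if (!nchar(al@alignedA)) stop("empty alignment")
  a <- seqChars(al@alignedA)
  b <- seqChars(al@alignedB)
  both <- a != "-" & b != "-"
  pos <- both & scheme@matrix[cbind(match(a, rownames(scheme@matrix)),
                                    match(b, rownames(scheme@matrix)))] > 0
  pos[is.na(pos)] <- FALSE
  den <- if (denominator == "aligned_columns") length(a)
         else min(sum(a != "-"), sum(b != "-"))
  100 * sum(pos) / den
}

#' p-distance of a global pairwise alignment
#'
#' Proportion of mismatched columns among columns gap-free in both rows.
#'
#' @param al a global [PairAlignment-class].
#' @return Value in `[0, 1]`.
#' @export
pDistance <- function(al) {
  if (!nchar(al@alignedA)) stop("empty alignment")
  a <- seqChars(al@alignedA)
  b <- seqChars(al@alignedB)
  both <- a != "-" & b != "-"
  if (!any(both)) stop("alignment has no gap-free columns")
  sum(a[both] != b[both]) / sum(both)
}

# Score a pair of pre-aligned (gapped) rows under a scheme: substitution
# scores for residue columns plus affine penalties for each maximal gap
# run. Columns gapped in both rows are dropped first (relevant when the
# rows come out of a multiple alignment). Used as an internal consistency
# check and by the sum-of-pairs MSA score.
pairScoreFromAligned <- function(rowA, rowB, scheme) {
  a <- seqChars(rowA)
  b <- seqChars(rowB)
  keep <- !(a == "-" & b == "-")
  a <- a[keep]
  b <- b[keep]
  if (!length(a)) return(0)
  m <- scheme@matrix
  res <- a != "-" & b != "-"
  s <- sum(m[cbind(match(a[res], rownames(m)), match(b[res], rownames(m)))])
  gapRuns <- function(v) {
    r <- rle(v == "-")
    r$lengths[r$values]
  }
  runs <- c(gapRuns(a), gapRuns(b))
  s - sum(scheme@gapOpen * (runs > 0)) - scheme@gapExtend * sum(runs)
}
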