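# Key-residue conservation: the central statistic of the classification.

#' Extract the residues at the reference key positions
#'
#' Globally aligns the record to the family reference protein and reads
#' off, for each key position of the reference, the record residue in
#' that aligned column ('-' when the record row is gapped there).
#'
#' @param record a [ProteinRecord-class] or sequence string (typically the
#'   representative PPIase domain of the protein).
#' @param reference the reference [ProteinRecord-class] (hFKBP12/hCypA).
#' @param positions integer vector of 1-based reference positions, or the
#'   data.frame from [keyPositions()].
#' @param scheme a [ScoringScheme-class].
#' @param family "FKBP" or "CYP" (stored on the profile).
#' @param proteinId identifier stored on the profile (default: the
#'   record's id).
#' @return A [KeyResidueProfile-class].
#' @export
extractKeyResidues <- function(record, reference, positions,
                               scheme = defaultScoringScheme(),
                               family = c("FKBP", "CYP"),
                               proteinId = NULL) {
  family <- match.arg(family)
  if (is.data.frame(positions)) positions <- positions$position
  positions <- as.integer(positions)
  if (is.null(proteinId)) proteinId <- asProteinId(record, "query")
  al <- globalAlign(reference, record, scheme)
  refRow <- seqChars(al@alignedA)
  recRow <- seqChars(al@alignedB)
  refPos <- cumsum(refRow != "-")
  out <- vapply(positions, function(p) {
    col <- match(p, refPos)
    # match() finds the first column with that reference position; gap
    # columns after it repeat the same count, residue columns are unique
    r <- recRow[col]
    if (refRow[col] == "-") r <- "-"
    r
  }, character(1))
  new("KeyResidueProfile", proteinId = proteinId, family = family,
      residues = paste(out, collapse = ""), positions = positions)
}

#' Conservation of a profile against the human reference residues
#'
#' Counts key positions at which the profile retains the reference
#' residue exactly ('-' never conserved) and rounds the percentage half
#' away from zero, the convention of the printed family tables.
#'
#' @param profile a [KeyResidueProfile-class].
#' @param refs a [ReferenceSet-class].
#' @return A [ConservationResult-class].
#' @examples
#' refs <- loadReferences()
#' p <- new("KeyResidueProfile", proteinId = "x", family = "CYP",
#'          residues = "SQIQFWY", positions = refs@cypKeyPositions$position)
#' conservedPercent(p, refs)  # 3/7 = 43%
#' @export
conservedPercent <- function(profile, refs = loadReferences()) {
  ref <- keyPositions(refs, profile@family)
  if (length(profile@positions) != nrow(ref) ||
      !all(profile@positions == ref$position))
    stop("profile positions do not match the reference key positions")
  res <- seqChars(profile@residues)
  cons <- sum(res == ref$residue)
  new("ConservationResult", conservedCount = as.integer(cons),
      total = nrow(ref), percent = roundHalfUp(100 * cons / nrow(ref)))
}

#' Pairwise similarity of two key-residue profiles
#'
#' Identity mode counts positions with equal residues; matrix_positive
#' mode additionally counts pairs with a positive substitution score.
#' '-' never matches. Rounded half away from zero.
#'
#' @param a,b [KeyResidueProfile-class] objects of the same family.
#' @param mode "identity" or "matrix_positive".
#' @param scheme a [ScoringScheme-class] (matrix_positive mode).
#' @return Integer percentage.
#' @export
pairSimilarityPercent <- function(a, b,
                                  mode = c("identity", "matrix_positive"),
                                  scheme = defaultScoringScheme()) {
  mode <- match.arg(mode)
  if (a@family != b@family || !all(a@positions == b@positions))
    stop("profiles must share family and positions")
  ra <- seqChars(a@residues)
  rb <- seqChars(b@residues)
  match <- ra == rb & ra != "-"
  if (mode == "matrix_positive") {
    m <- scheme@matrix
    ia <- match(ra, rownames(m))
    ib <- match(rb, rownames(m))
    pos <- !is.na(ia) & !is.na(ib) & m[cbind(pmax(ia, 1L), pmax(ib, 1L))] > 0
    match <- match | (pos & ra != "-" & rb != "-")
  }
  roundHalfUp(100 * sum(match) / length(ra))
}

#' Per-position conservation across a set of profiles
#'
#' The bottom-row statistic of the family tables: the percentage of
#' profiles conserving the reference residue at one key position.
#'
#' @param profiles non-empty list of [KeyResidueProfile-class] objects of
#'   one family.
#' @param positionIndex index into the key-position list (1..14 or 1..7).
#' @param refs a [ReferenceSet-class].
#' @return Integer percentage.
#' @export
columnConservation <- function(profiles, positionIndex,
                               refs = loadReferences()) {
  if (!length(profiles)) stop("empty profile list")
  fam <- profiles[[1]]@family
  if (!all(vapply(profiles, function(p) p@family, character(1)) == fam))
    stop("profiles must all belong to one family")
  ref <- keyPositions(refs, fam)
  stopifnot(positionIndex >= 1L, positionIndex <= nrow(ref))
  res <- vapply(profiles, function(p)
    substr(p@residues, positionIndex, positionIndex), character(1))
  roundHalfUp(100 * sum(res == ref$residue[positionIndex]) / length(res))
}
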