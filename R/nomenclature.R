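# Ortholog assignment and the naming rules: ortholog-derived suffixes,
# molecular-weight fallback suffixes, paralog letters, trigger-factor
# exception.

#' Molecular mass of the (mature) protein
#'
#' Sum of average residue masses plus one water. When a cleavage position
#' is given the mass is computed for the suffix starting right after it
#' (the predicted mature protein). The kDa value is rounded half away
#' from zero and supplies the numeric suffix of molecular-weight-based
#' names.
#'
#' @param record a [ProteinRecord-class] or sequence string.
#' @param cleavagePosition `NULL` or the 1-based position of the last
#'   residue of the cleaved targeting signal.
#' @return List with `da` (exact mass, Da) and `kda` (integer).
#' @examples
#' matureMass(strrep("G", 10))  # 588.53 Da -> 1 kDa
#' @export
matureMass <- function(record, cleavagePosition = NULL) {
  s <- asSequence(record)
  if (!is.null(cleavagePosition)) {
    if (cleavagePosition >= nchar(s))
      stop("cleavage position leaves an empty mature sequence")
    s <- substr(s, cleavagePosition + 1L, nchar(s))
  }
  ch <- seqChars(s)
  masses <- residueMasses()
  if (any(!ch %in% names(masses)))
    stop("sequence contains residues without a defined mass: ",
         paste(setdiff(unique(ch), names(masses)), collapse = ", "))
  da <- sum(masses[ch]) + 18.0153
  list(da = da, kda = roundHalfUp(da / 1000))
}

#' Assign an ortholog to a classified candidate
#'
#' A reference protein is accepted as the candidate's ortholog when all
#' three gates hold: global percent identity strictly above
#' `idThreshold`, the same predicted subcellular location, and the same
#' domain-architecture composition. Among passing references the one with
#' the highest identity wins (ties: higher similarity, then lexicographic
#' reference id).
#'
#' @param candidate list with elements `record` (a
#'   [ProteinRecord-class]), `compartment` and `composition`.
#' @param references list of reference entries, each a list with
#'   `record`, `compartment`, `composition` and `suffix` (the reference
#'   name's suffix string, e.g. "20-1").
#' @param idThreshold identity gate in percent (default 50).
#' @param scheme a [ScoringScheme-class].
#' @return An [OrthologAssignment-class]; `orthologId` is `NA` when no
#'   reference passes (the candidate then falls through to
#'   molecular-weight naming).
#' @export
assignOrtholog <- function(candidate, references, idThreshold = 50,
                           scheme = defaultScoringScheme()) {
  candId <- asProteinId(candidate$record, "candidate")
  empty <- new("OrthologAssignment", candidateId = candId,
               orthologId = NA_character_, orthologSuffix = NA_character_,
               identityPercent = NA_real_, similarityPercent = NA_real_,
               locationMatch = FALSE, architectureMatch = FALSE)
  if (!length(references)) return(empty)
  stats <- lapply(references, function(ref) {
    al <- globalAlign(candidate$record, ref$record, scheme)
    idPct <- percentIdentity(al)
    simPct <- percentSimilarity(al, scheme)
    loc <- identical(candidate$compartment, ref$compartment)
    arch <- identical(candidate$composition, ref$composition)
    list(id = asProteinId(ref$record, "reference"), suffix = ref$suffix,
         identity = idPct, similarity = simPct, loc = loc, arch = arch,
         pass = idPct > idThreshold && loc && arch)
  })
  passing <- Filter(function(s) s$pass, stats)
  if (!length(passing)) {
    bestAll <- stats[[order(-vapply(stats, `[[`, numeric(1), "identity"),
                            vapply(stats, `[[`, character(1), "id"))[1L]]]
    empty@identityPercent <- bestAll$identity
    empty@similarityPercent <- bestAll$similarity
    return(empty)
  }
  o <- order(-vapply(passing, `[[`, numeric(1), "identity"),
             -vapply(passing, `[[`, numeric(1), "similarity"),
             vapply(passing, `[[`, character(1), "id"))
  best <- passing[[o[1L]]]
  new("OrthologAssignment", candidateId = candId, orthologId = best$id,
      orthologSuffix = best$suffix, identityPercent = best$identity,
      similarityPercent = best$similarity, locationMatch = best$loc,
      architectureMatch = best$arch)
}

#' Assign immunophilin names to a set of classified candidates
#'
#' Naming rules: a candidate with an accepted ortholog inherits the
#' ortholog's suffix; otherwise the suffix is the mature mass in kDa;
#' trigger-factor-like candidates are named `<prefix>TIG`. When two or
#' more candidates end up with the same family token and suffix,
#' lowercase letters a, b, c, ... are appended: in decreasing order of
#' similarity to the shared ortholog, or, for molecular-weight groups, in
#' decreasing order of mean pairwise identity within the group (ties by
#' candidate id). Naming is a pure function of its inputs: permuting the
#' candidates never changes the result.
#'
#' @param candidates list of candidate entries: each a list with `id`,
#'   `family` ("FKBP", "CYP", "TIG" or "IMM"), `assignment` (an
#'   [OrthologAssignment-class] or `NULL`), `massDa` (numeric) and
#'   `record` (used only to order molecular-weight paralog groups).
#' @param organismPrefix prefix token, e.g. "Os".
#' @param scheme a [ScoringScheme-class].
#' @return Named list (by candidate id) of [ImmunophilinName-class].
#' @export
assignNames <- function(candidates, organismPrefix = "Os",
                        scheme = defaultScoringScheme()) {
  entries <- lapply(candidates, function(cand) {
    hasOrth <- !is.null(cand$assignment) &&
      !is.na(cand$assignment@orthologId)
    token <- cand$family
    suffix <- if (token == "TIG") {
      ""
    } else if (hasOrth) {
      cand$assignment@orthologSuffix
    } else {
      as.character(roundHalfUp(cand$massDa / 1000))
    }
    list(id = cand$id, token = token, suffix = suffix,
         hasOrth = hasOrth,
         similarity = if (hasOrth) cand$assignment@similarityPercent
                      else NA_real_,
         record = cand$record)
  })
  ids <- vapply(entries, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicated candidate ids")
  keys <- vapply(entries, function(e) paste0(e$token, "|", e$suffix),
                 character(1))
  letterOf <- stats::setNames(rep("", length(entries)), ids)
  for (key in unique(keys)) {
    idx <- which(keys == key)
    if (length(idx) < 2L) next
    grp <- entries[idx]
    if (all(vapply(grp, `[[`, logical(1), "hasOrth"))) {
      o <- order(-vapply(grp, `[[`, numeric(1), "similarity"),
                 vapply(grp, `[[`, character(1), "id"))
    } else {
      # molecular-weight (or mixed) group: mean pairwise identity
      meanIdent <- vapply(seq_along(grp), function(i) {
        others <- setdiff(seq_along(grp), i)
        mean(vapply(others, function(j) {
          percentIdentity(globalAlign(grp[[i]]$record, grp[[j]]$record,
                                      scheme))
        }, numeric(1)))
      }, numeric(1))
      o <- order(-vapply(grp, `[[`, logical(1), "hasOrth"),
                 -meanIdent, vapply(grp, `[[`, character(1), "id"))
    }
    # a..z, then aa, ab, ... for synthetic-scale paralog groups
    seqLetters <- c(letters,
                    as.vector(t(outer(letters, letters, paste0))))
    if (length(idx) > length(seqLetters))
      stop("paralog group too large to letter")
    letterOf[ids[idx][o]] <- seqLetters[seq_along(idx)]
  }
  out <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    new("ImmunophilinName", prefix = organismPrefix, familyToken = e$token,
        suffix = e$suffix, paralogLetter = unname(letterOf[e$id]))
  })
  names(out) <- ids
  full <- vapply(out, nameString, character(1))
  if (anyDuplicated(full))
    stop("internal error: name collision after lettering")
  out
}
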