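# show() methods and small accessors.

setMethod("show", "ProteinRecord", function(object) {
  cat("ProteinRecord", object@id,
      if (nzchar(object@organism)) paste0("[", object@organism, "]") else "",
      "\n  ", nchar(object@sequence), "aa\n")
})

setMethod("show", "ProteinSet", function(object) {
  cat("ProteinSet with", length(object@ids), "records\n")
  n <- min(6L, length(object@ids))
  for (i in seq_len(n))
    cat("  ", object@ids[i], " (", nchar(object@sequences[i]), " aa)\n",
        sep = "")
  if (length(object@ids) > n) cat("  ...\n")
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme:", object@name, "| gap open", object@gapOpen,
      "extend", object@gapExtend, "\n")
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet\n  FKBP reference:", object@fkbpReference@id,
      paste0("(", nchar(object@fkbpReference@sequence), " aa), key residues "),
      paste(object@fkbpKeyPositions$residue, collapse = ""), "\n")
  cat("  CYP reference: ", object@cypReference@id,
      paste0("(", nchar(object@cypReference@sequence), " aa), key residues "),
      paste(object@cypKeyPositions$residue, collapse = ""), "\n")
})

setMethod("show", "PairAlignment", function(object) {
  cat(object@mode, "alignment, score", format(object@score), "\n")
  w <- 60L
  la <- nchar(object@alignedA)
  if (la == 0L) {
    cat("  (empty alignment)\n")
    return(invisible(NULL))
  }
  for (o in seq(1L, la, by = w)) {
    cat("  ", substr(object@alignedA, o, min(o + w - 1L, la)), "\n",
        "  ", substr(object@alignedB, o, min(o + w - 1L, la)), "\n", sep = "")
  }
})

setMethod("show", "TatSignal", function(object) {
  cat("TatSignal: RR at", object@rrPosition, "| h-region",
      object@hRegion[1], "-", object@hRegion[2],
      if (object@anchored) "| no cleavage site (anchored)" else
        paste("| cleavage at", object@cleavageSite), "\n")
})

setMethod("show", "TargetingCall", function(object) {
  cat("TargetingCall:", object@compartment, "\n")
  if (nrow(object@evidence))
    for (i in seq_len(nrow(object@evidence)))
      cat("  ", object@evidence$signal[i], " ", object@evidence$start[i],
          "-", object@evidence$end[i], " ", object@evidence$detail[i], "\n",
          sep = "")
})

setMethod("show", "DomainArchitecture", function(object) {
  cat("DomainArchitecture", object@proteinId, "|", object@sdMd, "|",
      object@composition, "\n")
})

setMethod("show", "KeyResidueProfile", function(object) {
  cat("KeyResidueProfile", object@proteinId, "[", object@family, "]",
      object@residues, "\n")
})

setMethod("show", "ConservationResult", function(object) {
  cat("Conserved:", object@conservedCount, "/", object@total, "=",
      object@percent, "%\n")
})

setMethod("show", "ImmunophilinName", function(object) {
  cat(nameString(object), "\n")
})

setMethod("show", "ClassifiedSet", function(object) {
  cat("ClassifiedSet:", nrow(object@inventory), "records")
  if (length(object@errors)) cat(",", length(object@errors), "failed")
  cat("\n")
  print(utils::head(object@inventory[, c("id", "name", "family", "sd_md",
                                         "compartment",
                                         "conserved_percent")], 10L))
})

#' @describeIn ProteinSet-class number of records
#' @param x a `ProteinSet`.
#' @export
setMethod("length", "ProteinSet", function(x) length(x@ids))

#' Extract one record from a [ProteinSet-class]
#'
#' @param x a `ProteinSet`.
#' @param i index or record id.
#' @return A [ProteinRecord-class].
#' @export
setMethod("[[", "ProteinSet", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  if (is.na(i) || i < 1L || i > length(x@ids)) stop("record not found")
  new("ProteinRecord", id = x@ids[i], description = x@descriptions[i],
      sequence = x@sequences[i], organism = x@organisms[i])
})

#' Record identifiers of a [ProteinSet-class]
#' @param x a `ProteinSet`.
#' @return Character vector of ids.
#' @export
proteinIds <- function(x) {
  stopifnot(is(x, "ProteinSet"))
  x@ids
}

#' Sequences of a [ProteinSet-class] as a named character vector
#' @param x a `ProteinSet`.
#' @return Named character vector of sequences.
#' @export
sequences <- function(x) {
  stopifnot(is(x, "ProteinSet"))
  stats::setNames(x@sequences, x@ids)
}

#' Alignment score of a [PairAlignment-class]
#' @param x a `PairAlignment`.
#' @return Numeric score.
#' @export
alignmentScore <- function(x) {
  stopifnot(is(x, "PairAlignment"))
  x@score
}

#' Gapped rows of a [PairAlignment-class]
#' @param x a `PairAlignment`.
#' @return Character vector `c(a, b)` of the two gapped rows.
#' @export
alignedRows <- function(x) {
  stopifnot(is(x, "PairAlignment"))
  c(x@alignedA, x@alignedB)
}

#' Predicted compartment of a [TargetingCall-class]
#' @param x a `TargetingCall`.
#' @return Compartment string.
#' @export
compartment <- function(x) {
  stopifnot(is(x, "TargetingCall"))
  x@compartment
}

#' Domain hits of a [DomainArchitecture-class]
#' @param x a `DomainArchitecture`.
#' @return data.frame of hits.
#' @export
domainHits <- function(x) {
  stopifnot(is(x, "DomainArchitecture"))
  x@hits
}

#' Residue string of a [KeyResidueProfile-class]
#' @param x a `KeyResidueProfile`.
#' @return Residue string.
#' @export
keyResidues <- function(x) {
  stopifnot(is(x, "KeyResidueProfile"))
  x@residues
}

#' Format an [ImmunophilinName-class] as the printed gene name
#' @param x an `ImmunophilinName`.
#' @return Single string, e.g. "OsFKBP62a".
#' @export
nameString <- function(x) {
  stopifnot(is(x, "ImmunophilinName"))
  paste0(x@prefix, x@familyToken, x@suffix, x@paralogLetter)
}

#' Inventory table of a [ClassifiedSet-class]
#' @param x a `ClassifiedSet`.
#' @return data.frame with one row per input record.
#' @export
inventory <- function(x) {
  stopifnot(is(x, "ClassifiedSet"))
  x@inventory
}
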