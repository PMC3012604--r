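# Shared internal helpers.

# The 20 standard amino acids (one-letter) in alphabetical order.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Sequence alphabet accepted in ProteinRecord: standard residues plus X.
AA_ALPHABET <- c(AA_STANDARD, "X")

#' Round to nearest integer, halves away from zero
#'
#' The rounding convention used for every printed percentage and kDa value
#' (e.g. 12/14 = 85.71... -> 86).
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
roundHalfUp <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Split a sequence string into a character vector of residues.
seqChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Accept a ProteinRecord or a plain string; return the sequence string.
asSequence <- function(x) {
  if (is(x, "ProteinRecord")) return(x@sequence)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("expected a ProteinRecord or a single sequence string")
}

# Accept a ProteinRecord or a string; return an identifier for reporting.
asProteinId <- function(x, default = "") {
  if (is(x, "ProteinRecord")) return(x@id)
  default
}

# Merge integer spans (two-column matrix/data.frame start,end), joining
# overlapping or adjacent spans. Returns a data.frame(start, end).
mergeSpans <- function(starts, ends) {
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(starts, ends)
  starts <- starts[o]
  ends <- ends[o]
  outS <- starts[1]
  outE <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= outE[length(outE)] + 1L) {
      outE[length(outE)] <- max(outE[length(outE)], ends[k])
    } else {
      outS <- c(outS, starts[k])
      outE <- c(outE, ends[k])
    }
  }
  data.frame(start = outS, end = outE)
}

# Runs of TRUE in a logical vector -> data.frame(start, end).
trueRuns <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
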