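# Substitution matrices and the default scoring scheme.

#' Read a substitution matrix in NCBI text layout
#'
#' Parses the whitespace-separated matrix format used by NCBI tools
#' ('#' comment lines, a header row of residue letters, one labelled row
#' per residue).
#'
#' @param path path to the matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
readScoringMatrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, character(1), 1L)
  vals <- lapply(rows, function(r) as.integer(r[-1]))
  if (any(vapply(vals, length, integer(1)) != length(hdr)))
    stop("matrix row length does not match header")
  m <- do.call(rbind, vals)
  rownames(m) <- lab
  colnames(m) <- hdr
  m
}

#' Construct a [ScoringScheme-class]
#'
#' @param matrix symmetric substitution matrix with residue dimnames.
#' @param gapOpen gap-opening penalty (positive).
#' @param gapExtend gap-extension penalty per residue (positive).
#' @param name matrix name.
#' @return A `ScoringScheme`.
#' @export
scoringScheme <- function(matrix, gapOpen = 10, gapExtend = 0.5,
                          name = "custom") {
  new("ScoringScheme", matrix = matrix, gapOpen = gapOpen,
      gapExtend = gapExtend, name = name)
}

#' The packaged default scoring scheme
#'
#' BLOSUM62 over the 20 standard residues plus X, gap open 10, gap
#' extension 0.5. X is treated conservatively: it matches nothing, scoring
#' the minimum of its partner's row (and the global minimum against
#' itself), so masked stretches can never contribute positively.
#'
#' @param gapOpen gap-opening penalty.
#' @param gapExtend gap-extension penalty.
#' @return A [ScoringScheme-class].
#' @examples
#' sc <- defaultScoringScheme()
#' sc@matrix["I", "V"]
#' @export
defaultScoringScheme <- function(gapOpen = 10, gapExtend = 0.5) {
  key <- "blosum62_x"
  if (is.null(.immfamCache[[key]])) {
    raw <- readScoringMatrix(system.file("extdata", "BLOSUM62.txt",
                                         package = "immfam"))
    m <- raw[AA_STANDARD, AA_STANDARD]
    full <- matrix(0L, 21L, 21L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    full[AA_STANDARD, AA_STANDARD] <- m
    for (r in AA_STANDARD) {
      v <- min(m[r, ])
      full["X", r] <- v
      full[r, "X"] <- v
    }
    full["X", "X"] <- min(m)
    .immfamCache[[key]] <- full
  }
  scoringScheme(.immfamCache[[key]], gapOpen, gapExtend, "BLOSUM62")
}

# Map a sequence string to 1-based indices into the scheme's matrix.
seqToIdx <- function(s, scheme) {
  idx <- match(seqChars(s), rownames(scheme@matrix))
  if (anyNA(idx))
    stop("sequence contains characters absent from the scoring matrix")
  idx
}

# Self-alignment score of a sequence (sum of diagonal entries).
selfScore <- function(s, scheme) {
  idx <- seqToIdx(s, scheme)
  sum(scheme@matrix[cbind(idx, idx)])
}
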