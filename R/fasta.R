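# FASTA input/output.
#
# A deliberately strict reader: malformed headers, empty bodies and illegal
# characters are reported with the offending record id and line number,
# which generic parsers do not surface.

#' Read a protein FASTA file
#'
#' Headers are split into an id (first token) and a description (rest);
#' wrapped sequence bodies are concatenated and uppercased; a single
#' terminal '*' (stop) is stripped. Only the 20 standard residues plus X
#' are accepted.
#'
#' @param path path to a FASTA file.
#' @param organism organism tag stored on every record (default "").
#' @return A [ProteinSet-class].
#' @examples
#' f <- system.file("extdata", "hFKBP12.fasta", package = "immfam")
#' readFasta(f)
#' @export
readFasta <- function(path, organism = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonEmpty[1]]), ">"))
    stop("malformed FASTA (line ", nonEmpty[1],
         "): first non-empty line must start with '>'")
  ids <- character(0)
  descs <- character(0)
  seqs <- character(0)
  curId <- NULL
  curDesc <- ""
  curSeq <- character(0)
  curHeaderLine <- 0L
  flush <- function() {
    if (is.null(curId)) return()
    body <- paste(curSeq, collapse = "")
    body <- toupper(body)
    body <- sub("\\*$", "", body)
    if (!nzchar(body))
      stop("empty sequence body for record '", curId, "' (header at line ",
           curHeaderLine, ")")
    ids <<- c(ids, curId)
    descs <<- c(descs, curDesc)
    seqs <<- c(seqs, body)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      flush()
      hdr <- trimws(sub("^>", "", line))
      if (!nzchar(hdr))
        stop("malformed FASTA header at line ", ln, ": missing id")
      sp <- regexpr("\\s", hdr)
      if (sp == -1L) {
        curId <- hdr
        curDesc <- ""
      } else {
        curId <- substr(hdr, 1L, sp - 1L)
        curDesc <- trimws(substr(hdr, sp + 1L, nchar(hdr)))
      }
      curSeq <- character(0)
      curHeaderLine <- ln
    } else {
      if (is.null(curId))
        stop("malformed FASTA (line ", ln, "): sequence before any header")
      chunk <- toupper(gsub("\\s", "", line))
      bad <- regmatches(chunk, gregexpr(paste0("[^", paste(AA_ALPHABET,
                                                           collapse = ""),
                                               "*]"), chunk))[[1]]
      if (length(bad))
        stop("illegal character(s) ", paste(unique(bad), collapse = ", "),
             " in record '", curId, "' at line ", ln)
      curSeq <- c(curSeq, chunk)
    }
  }
  flush()
  if (anyDuplicated(ids))
    stop("duplicated record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ProteinSet(ids, seqs, descs, organism)
}

#' Write a [ProteinSet-class] to FASTA
#'
#' Round-trip safe: `readFasta(writeFasta(x))` reproduces ids, descriptions
#' and sequences exactly.
#'
#' @param x a [ProteinSet-class] (non-empty).
#' @param path output path.
#' @param width body line width (positive integer).
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(x, path, width = 60L) {
  stopifnot(is(x, "ProteinSet"))
  if (length(x@ids) == 0L) stop("cannot write an empty ProteinSet")
  width <- as.integer(width)
  if (width < 1L) stop("width must be a positive integer")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(x@ids)) {
    hdr <- paste0(">", x@ids[i],
                  if (nzchar(x@descriptions[i]))
                    paste0(" ", x@descriptions[i]) else "")
    writeLines(hdr, con)
    s <- x@sequences[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}
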