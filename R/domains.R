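# PPIase-domain scanning and architecture classification.

#' Scan a protein for PPIase (FKBP/CYP) domain copies
#'
#' Greedy iterative search: at each step the best local alignment of either
#' family reference domain (hFKBP12 is itself a lone FKBP domain; hCypA a
#' lone CYP domain) against the not-yet-masked protein is taken; if its
#' normalized score (raw / reference self-score) reaches `minNormalized`
#' the hit is recorded and its span masked with X (which scores the row
#' minimum, so masked residues cannot re-hit); the scan stops below the
#' threshold or after `maxCopies` hits. Masking rather than splitting
#' preserves coordinates, and guarantees hits never overlap.
#'
#' @param record a [ProteinRecord-class] or sequence string.
#' @param references a [ReferenceSet-class].
#' @param scheme a [ScoringScheme-class].
#' @param minNormalized acceptance threshold on the normalized score, in
#'   (0, 1].
#' @param maxCopies maximum number of domain copies to report.
#' @return data.frame(family, start, end, rawScore, normalizedScore),
#'   sorted by start; zero rows when nothing reaches the threshold.
#' @export
scanPpiaseDomains <- function(record, references = loadReferences(),
                              scheme = defaultScoringScheme(),
                              minNormalized = 0.3, maxCopies = 4L) {
  stopifnot(minNormalized > 0, minNormalized <= 1)
  seq <- asSequence(record)
  refSeq <- c(FKBP = references@fkbpReference@sequence,
              CYP = references@cypReference@sequence)
  self <- vapply(refSeq, selfScore, numeric(1), scheme = scheme)
  cur <- seq
  hits <- data.frame(family = character(0), start = integer(0),
                     end = integer(0), rawScore = numeric(0),
                     normalizedScore = numeric(0))
  for (k in seq_len(maxCopies)) {
    bestFam <- NA_character_
    bestAl <- NULL
    bestNorm <- -Inf
    for (fam in c("FKBP", "CYP")) {
      al <- localAlign(refSeq[[fam]], cur, scheme)
      norm <- al@score / self[[fam]]
      if (norm > bestNorm) {
        bestNorm <- norm
        bestFam <- fam
        bestAl <- al
      }
    }
    if (bestNorm < minNormalized || bestAl@bSpan[1] == 0L) break
    span <- bestAl@bSpan
    hits <- rbind(hits, data.frame(family = bestFam, start = span[1],
                                   end = span[2], rawScore = bestAl@score,
                                   normalizedScore = min(bestNorm, 1)))
    substr(cur, span[1], span[2]) <-
      paste(rep("X", span[2] - span[1] + 1L), collapse = "")
  }
  hits[order(hits$start), , drop = FALSE]
}

#' Pick the representative (most conserved) domain
#'
#' For multi-domain proteins the conservation analysis uses the most
#' conserved copy; this returns the hit with maximal normalized score,
#' ties broken by smallest start.
#'
#' @param hits data.frame of domain hits from [scanPpiaseDomains()]
#'   (non-empty).
#' @return Single-row data.frame.
#' @export
selectRepresentativeDomain <- function(hits) {
  if (!NROW(hits)) stop("empty hit list")
  hits[order(-hits$normalizedScore, hits$start)[1L], , drop = FALSE]
}

#' Detect Arg/Lys-rich regions
#'
#' Compositional heuristic for the long Arg/Lys-rich linkers found in
#' several multi-domain immunophilins: maximal regions in which every
#' length-`window` subwindow contains at least `minFraction` R+K, merged
#' and trimmed to length >= `minLength`.
#'
#' @param record a [ProteinRecord-class] or sequence string.
#' @param window subwindow length (>= 5).
#' @param minFraction minimum (R+K)/window per subwindow.
#' @param minLength minimum reported span length.
#' @return data.frame(start, end); zero rows when none.
#' @export
detectRkRich <- function(record, window = 20L, minFraction = 0.4,
                         minLength = 30L) {
  stopifnot(window >= 5L)
  s <- seqChars(asSequence(record))
  n <- length(s)
  if (n < window)
    return(data.frame(start = integer(0), end = integer(0)))
  v <- as.integer(s %in% c("R", "K"))
  cs <- c(0L, cumsum(v))
  starts <- 1L:(n - window + 1L)
  winSum <- cs[starts + window] - cs[starts]
  qual <- starts[winSum >= window * minFraction]
  if (!length(qual))
    return(data.frame(start = integer(0), end = integer(0)))
  covered <- rep(FALSE, n)
  for (q in qual) covered[q:(q + window - 1L)] <- TRUE
  runs <- trueRuns(covered)
  runs[runs$end - runs$start + 1L >= minLength, , drop = FALSE]
}

#' Classify the domain architecture of a protein
#'
#' SD (single-domain) iff exactly one PPIase hit and no auxiliary
#' features; otherwise MD. The composition string lists domains and
#' auxiliary features in N-to-C order, collapsing consecutive repeats
#' ("FKBP×3+TPR+CaM").
#'
#' @param hits data.frame of PPIase hits ([scanPpiaseDomains()]).
#' @param auxFeatures optional data.frame(feature, start, end) of
#'   auxiliary features (externally supplied annotations and/or detected
#'   Arg/Lys-rich spans). Overlapping features are tolerated and reported
#'   as given.
#' @param proteinId record identifier stored on the result.
#' @return A [DomainArchitecture-class].
#' @export
classifyArchitecture <- function(hits, auxFeatures = NULL, proteinId = "") {
  if (is.null(auxFeatures) || !NROW(auxFeatures))
    auxFeatures <- data.frame(feature = character(0), start = integer(0),
                              end = integer(0))
  labels <- c(as.character(hits$family), as.character(auxFeatures$feature))
  starts <- c(hits$start, auxFeatures$start)
  comp <- ""
  if (length(labels)) {
    labels <- labels[order(starts)]
    r <- rle(labels)
    parts <- ifelse(r$lengths > 1L,
                    paste0(r$values, "×", r$lengths), r$values)
    comp <- paste(parts, collapse = "+")
  }
  sdMd <- if (NROW(hits) == 1L && nrow(auxFeatures) == 0L) "SD" else "MD"
  new("DomainArchitecture", proteinId = proteinId, hits = hits,
      auxFeatures = auxFeatures, sdMd = sdMd, composition = comp)
}

#' Read an auxiliary-feature annotation file
#'
#' Tab-separated `protein_id  feature  start  end` (1-based inclusive),
#' for features the pipeline does not detect itself (TPR, CCD, CaM, WD,
#' RRM, U-box, zinc-finger, TM, ...).
#'
#' @param path path to the annotation file.
#' @return data.frame(protein_id, feature, start, end).
#' @export
readAuxFeatures <- function(path) {
  d <- utils::read.delim(path, header = FALSE,
                         col.names = c("protein_id", "feature", "start",
                                       "end"),
                         colClasses = c("character", "character", "integer",
                                        "integer"))
  if (any(d$start > d$end)) stop("feature with start > end in ", path)
  d
}
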