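# Targeting-signal heuristics: twin-arginine (Tat) signals, ER signal /
# retention, nuclear localization signals, and the compartment call.

# Hydropathy values for a residue vector; X counts as strongly
# hydrophilic so masked residues never fake a hydrophobic core.
.hydropathyOf <- function(chars, scale) {
  h <- unname(scale[chars])
  h[is.na(h)] <- -4.5
  h
}

# Find a hydrophobic region starting in [from, to]: the first start whose
# initial window of hMinLen residues has mean hydropathy >= hMinMean; the
# region is then extended while the trailing window of hMinLen residues
# stays at or above the threshold.
.findHydrophobicRun <- function(h, from, to, hMinLen, hMinMean) {
  n <- length(h)
  for (s in from:to) {
    e0 <- s + hMinLen - 1L
    if (e0 > n) break
    if (mean(h[s:e0]) >= hMinMean) {
      e <- e0
      while (e + 1L <= n && mean(h[(e - hMinLen + 2L):(e + 1L)]) >= hMinMean)
        e <- e + 1L
      return(c(s, e))
    }
  }
  NULL
}

#' Detect a twin-arginine (Tat) targeting signal
#'
#' The Tat signature used for thylakoid-lumen targeting: a double-arginine
#' (RR) pair in the N-terminal region, followed (within 25 residues) by a
#' hydrophobic stretch; a downstream Ala-Xaa-Ala peptidase motif marks the
#' cleavage site of a lumenal protein, while its absence marks a
#' membrane-anchored one. Every RR pair within the window is tried in
#' order and the first satisfying the hydrophobic clause wins.
#'
#' @param record a [ProteinRecord-class] or sequence string.
#' @param nWindow N-terminal window scanned for the RR pair.
#' @param scale named hydropathy scale ([hydropathyScale()]).
#' @param hMinLen minimum hydrophobic-stretch length.
#' @param hMinMean minimum mean hydropathy of the stretch.
#' @param cleaveWindow residues after the hydrophobic stretch searched for
#'   Ala-Xaa-Ala (the search also covers the stretch's last 10 residues,
#'   since the motif sits at the terminus of the hydrophobic region and
#'   alanines are themselves mildly hydrophobic).
#' @param allowVariant also accept KR/RK pairs (off by default: the
#'   signature is two consecutive arginines).
#' @return A [TatSignal-class], or `NULL` when no signal is found.
#' @export
detectTatSignal <- function(record, nWindow = 80L,
                            scale = hydropathyScale(), hMinLen = 8L,
                            hMinMean = 1.5, cleaveWindow = 30L,
                            allowVariant = FALSE) {
  s <- seqChars(asSequence(record))
  n <- length(s)
  h <- .hydropathyOf(s, scale)
  lastStart <- min(nWindow, n - 1L)
  if (lastStart < 1L) return(NULL)
  isR <- s == "R"
  isB <- s %in% c("R", "K")
  pairOk <- if (allowVariant) {
    isB[1:lastStart] & isB[2:(lastStart + 1L)] &
      (isR[1:lastStart] | isR[2:(lastStart + 1L)])
  } else {
    isR[1:lastStart] & isR[2:(lastStart + 1L)]
  }
  for (rr in which(pairOk)) {
    from <- rr + 2L
    to <- min(rr + 1L + 25L, n)
    if (from > to) next
    run <- .findHydrophobicRun(h, from, to, hMinLen, hMinMean)
    if (is.null(run)) next
    pFrom <- max(run[1] + 1L, run[2] - 10L)
    pTo <- min(n - 2L, run[2] + cleaveWindow)
    site <- NA_integer_
    if (pFrom <= pTo) {
      for (p in pFrom:pTo) {
        if (s[p] == "A" && s[p + 2L] == "A") {
          site <- p + 2L
          break
        }
      }
    }
    return(new("TatSignal", rrPosition = rr, hRegion = as.integer(run),
               cleavageSite = site, anchored = is.na(site)))
  }
  NULL
}

#' Detect an N-terminal hydrophobic (ER-type) signal sequence
#'
#' A hydrophobic stretch starting within the first `window` residues,
#' without the twin-arginine requirement. Used together with a C-terminal
#' retention motif to call ER residents.
#'
#' @inheritParams detectTatSignal
#' @param window N-terminal region in which the stretch must begin.
#' @return Integer span `c(start, end)` of the stretch, or `NULL`.
#' @export
detectErSignal <- function(record, window = 30L, scale = hydropathyScale(),
                           hMinLen = 8L, hMinMean = 1.5) {
  s <- seqChars(asSequence(record))
  n <- length(s)
  if (n < hMinLen) return(NULL)
  h <- .hydropathyOf(s, scale)
  run <- .findHydrophobicRun(h, 1L, min(window, n), hMinLen, hMinMean)
  if (is.null(run)) NULL else as.integer(run)
}

#' Detect a C-terminal ER retention motif
#'
#' Returns the C-terminal tetrapeptide when it matches `[A-Z][SD]EL`
#' (covering DSEL/NSEL-type plant variants and the classic KDEL/HDEL),
#' else `NULL`.
#'
#' @param record a [ProteinRecord-class] or sequence string (length >= 4).
#' @return The matching tetrapeptide, or `NULL`.
#' @export
detectErRetention <- function(record) {
  s <- asSequence(record)
  if (nchar(s) < 4L) stop("sequence shorter than a retention tetrapeptide")
  tail4 <- substr(s, nchar(s) - 3L, nchar(s))
  if (grepl("^[A-Z][SD]EL$", tail4) || tail4 %in% c("KDEL", "HDEL"))
    tail4
  else
    NULL
}

#' Detect nuclear localization signals
#'
#' Monopartite rule: any window of `monoWindow` residues containing at
#' least `monoMinBasic` K/R. Bipartite rule: two basic doublets separated
#' by a spacer of `biSpacer[1]`..`biSpacer[2]` residues. Overlapping
#' detections are merged.
#'
#' @param record a [ProteinRecord-class] or sequence string.
#' @param monoWindow monopartite window length.
#' @param monoMinBasic minimum K/R count per window.
#' @param biSpacer length-2 integer range of bipartite spacer lengths.
#' @return data.frame(start, end) of merged NLS spans; zero rows if none.
#' @export
detectNls <- function(record, monoWindow = 6L, monoMinBasic = 4L,
                      biSpacer = c(9L, 12L)) {
  s <- seqChars(asSequence(record))
  n <- length(s)
  basic <- as.integer(s %in% c("K", "R"))
  starts <- integer(0)
  ends <- integer(0)
  if (n >= monoWindow) {
    cs <- c(0L, cumsum(basic))
    w <- 1L:(n - monoWindow + 1L)
    hit <- w[cs[w + monoWindow] - cs[w] >= monoMinBasic]
    starts <- c(starts, hit)
    ends <- c(ends, hit + monoWindow - 1L)
  }
  if (n >= 2L) {
    doublets <- which(basic[1:(n - 1L)] == 1L & basic[2:n] == 1L)
    for (i in doublets) {
      js <- doublets[doublets - (i + 2L) >= biSpacer[1] &
                       doublets - (i + 2L) <= biSpacer[2]]
      if (length(js)) {
        starts <- c(starts, rep(i, length(js)))
        ends <- c(ends, js + 1L)
      }
    }
  }
  mergeSpans(starts, ends)
}

#' Combine detected signals into a compartment call
#'
#' Precedence: a Tat signal with a cleavage site places the protein in the
#' chloroplast (thylakoid) lumen; a Tat signal without one marks a
#' membrane-anchored thylakoid protein; an N-terminal hydrophobic signal
#' plus a C-terminal retention motif calls ER; an NLS (absent Tat/ER)
#' calls nucleus; with no signal at all the protein is cytosolic.
#'
#' @param record a [ProteinRecord-class] or sequence string.
#' @param tat a [TatSignal-class] or `NULL` (from [detectTatSignal()]).
#' @param erSignal `NULL` or the span from [detectErSignal()].
#' @param erRetention `NULL` or the motif from [detectErRetention()].
#' @param nls data.frame of NLS spans from [detectNls()] (or `NULL`).
#' @return A [TargetingCall-class].
#' @export
predictLocalization <- function(record, tat = NULL, erSignal = NULL,
                                erRetention = NULL, nls = NULL) {
  ev <- data.frame(signal = character(0), start = integer(0),
                   end = integer(0), detail = character(0))
  addEv <- function(signal, start, end, detail) {
    ev <<- rbind(ev, data.frame(signal = signal, start = start, end = end,
                                detail = detail))
  }
  n <- nchar(asSequence(record))
  if (!is.null(tat)) {
    addEv("tat", tat@rrPosition, tat@hRegion[2],
          if (tat@anchored) "no cleavage site"
          else paste0("cleavage at ", tat@cleavageSite))
  }
  if (!is.null(erSignal))
    addEv("er_signal", erSignal[1], erSignal[2], "hydrophobic leader")
  if (!is.null(erRetention))
    addEv("er_retention", n - 3L, n, erRetention)
  if (!is.null(nls) && NROW(nls))
    for (i in seq_len(nrow(nls)))
      addEv("nls", nls$start[i], nls$end[i], "basic cluster")
  comp <- if (!is.null(tat)) {
    if (tat@anchored) "chloroplast_membrane_anchored" else "chloroplast_lumen"
  } else if (!is.null(erSignal) && !is.null(erRetention)) {
    "ER"
  } else if (!is.null(nls) && NROW(nls)) {
    "nucleus"
  } else {
    "cytosol"
  }
  new("TargetingCall", compartment = comp, evidence = ev)
}
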