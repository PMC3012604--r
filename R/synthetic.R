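# Seeded generator of immunophilin-like protein families with ground
# truth, and the recovery metrics comparing pipeline output to the truth.

# Residues used for neutral spacers/linkers: no R/K (would bias the
# Arg/Lys and NLS detectors), no A (would fake Ala-Xaa-Ala cleavage
# sites), nothing hydrophobic (would fake signal cores).
.NEUTRAL <- c("G", "S", "T", "N", "Q", "D", "E", "P")
.HYDROPHOBIC <- c("L", "V", "I", "F")

#' Build a [GeneratorConfig-class]
#'
#' Defaults emulate the observed family structure: a mixed FKBP/CYP
#' family, moderate divergence from the ancestral catalytic core with
#' key positions mutating at their own rate, the signal repertoire
#' (Tat with/without cleavage, ER, NLS) on part of the family, occasional
#' 2-3 domain copies and Arg/Lys-rich linkers.
#'
#' @param nProteins number of proteins.
#' @param fkbpProportion probability of drawing the FKBP core.
#' @param keyMutationRate per-site substitution rate at key positions.
#' @param backgroundMutationRate per-site substitution rate elsewhere.
#' @param signalProbs named probabilities (tat_cleaved, tat_anchored, er,
#'   nls, none) summing to 1.
#' @param multiDomainProb probability of 2-3 domain copies.
#' @param copyProbs probabilities of 2 vs 3 copies.
#' @param rkLinkerProb probability of an Arg/Lys-rich linker.
#' @param seed integer seed.
#' @return A [GeneratorConfig-class].
#' @export
generatorConfig <- function(nProteins = 200L, fkbpProportion = 0.6,
                            keyMutationRate = 0.1,
                            backgroundMutationRate = 0.1,
                            signalProbs = c(tat_cleaved = 0.2,
                                            tat_anchored = 0.1, er = 0.1,
                                            nls = 0.1, none = 0.5),
                            multiDomainProb = 0.25,
                            copyProbs = c("2" = 0.7, "3" = 0.3),
                            rkLinkerProb = 0.1, seed = 1L) {
  new("GeneratorConfig", nProteins = as.integer(nProteins),
      fkbpProportion = fkbpProportion, keyMutationRate = keyMutationRate,
      backgroundMutationRate = backgroundMutationRate,
      signalProbs = signalProbs, multiDomainProb = multiDomainProb,
      copyProbs = copyProbs, rkLinkerProb = rkLinkerProb,
      seed = as.integer(seed))
}

# Mutate a core sequence: independent per-site substitution, rate kappa
# at key positions and rho elsewhere, replacement uniform over the 19
# alternatives.
.mutateCore <- function(chars, keyPositions, kappa, rho) {
  n <- length(chars)
  rate <- rep(rho, n)
  rate[keyPositions] <- kappa
  hit <- which(stats::runif(n) < rate)
  for (i in hit) {
    alt <- setdiff(AA_STANDARD, chars[i])
    chars[i] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

#' Generate a synthetic immunophilin family with ground truth
#'
#' Each protein is built from an ancestral catalytic core (hFKBP12 or
#' hCypA, or a member of a supplied ancestor panel), mutated per site,
#' optionally duplicated into 2-3 copies joined by short neutral linkers,
#' and decorated with at most one N-terminal signal (Tat with or without
#' an Ala-Xaa-Ala cleavage site, or an ER leader with C-terminal
#' retention motif), an optional appended NLS cluster, and an optional
#' Arg/Lys-rich linker. Spacer and hydrophobic-run lengths are drawn from
#' ranges within the detector defaults, so implanted signals are
#' detectable by construction. All randomness flows from the config seed;
#' the same seed reproduces the records and truth byte-identically.
#'
#' @param config a [GeneratorConfig-class].
#' @param ancestors optional ancestor panel from [referencePanel()]; when
#'   given, cores are drawn uniformly from the panel and the truth records
#'   each protein's ancestor name.
#' @param refs a [ReferenceSet-class] providing the default cores.
#' @return List with `records` (a [ProteinSet-class]) and `truth`
#'   (data.frame, one row per record).
#' @export
generateFamily <- function(config, ancestors = NULL,
                           refs = loadReferences()) {
  validObject(config)
  set.seed(config@seed)
  kappa <- config@keyMutationRate
  rho <- config@backgroundMutationRate
  defaultAncestors <- list(
    list(name = "hFKBP12", family = "FKBP",
         seq = refs@fkbpReference@sequence,
         keyPos = refs@fkbpKeyPositions$position),
    list(name = "hCYPA", family = "CYP",
         seq = refs@cypReference@sequence,
         keyPos = refs@cypKeyPositions$position))
  rows <- vector("list", config@nProteins)
  ids <- sprintf("SYN%04d", seq_len(config@nProteins))
  seqs <- character(config@nProteins)
  for (i in seq_len(config@nProteins)) {
    if (is.null(ancestors)) {
      anc <- defaultAncestors[[
        if (stats::runif(1) < config@fkbpProportion) 1L else 2L]]
    } else {
      anc <- ancestors[[sample.int(length(ancestors), 1L)]]
    }
    coreChars <- seqChars(anc$seq)
    keyPos <- anc$keyPos
    nDom <- if (stats::runif(1) < config@multiDomainProb)
      sample(c(2L, 3L), 1L, prob = config@copyProbs) else 1L
    copies <- lapply(seq_len(nDom), function(k)
      .mutateCore(coreChars, keyPos, kappa, rho))
    signal <- sample(names(config@signalProbs), 1L,
                     prob = config@signalProbs)
    prefix <- character(0)
    rrPos <- NA_integer_
    hStart <- NA_integer_
    hEnd <- NA_integer_
    cleave <- NA_integer_
    erLeader <- NA_integer_
    if (signal %in% c("tat_cleaved", "tat_anchored")) {
      spacer <- sample(.NEUTRAL, sample(2:10, 1L), replace = TRUE)
      gap <- sample(.NEUTRAL, sample(1:5, 1L), replace = TRUE)
      hyd <- sample(.HYDROPHOBIC, sample(8:15, 1L), replace = TRUE)
      prefix <- c("M", spacer, "R", "R", gap, hyd)
      rrPos <- 1L + length(spacer) + 1L
      hStart <- rrPos + 2L + length(gap)
      hEnd <- hStart + length(hyd) - 1L
      if (signal == "tat_cleaved") {
        prefix <- c(prefix, "A", sample(c("H", "N", "Q", "S"), 1L), "A")
        cleave <- hEnd + 3L
      }
    } else if (signal == "er") {
      hyd <- sample(.HYDROPHOBIC, sample(10:15, 1L), replace = TRUE)
      prefix <- c("M", hyd)
      erLeader <- 1L + length(hyd)
      hStart <- 2L
      hEnd <- erLeader
    }
    parts <- list(prefix)
    domStarts <- integer(nDom)
    domEnds <- integer(nDom)
    pos <- length(prefix)
    domKeyRes <- character(nDom)
    for (k in seq_len(nDom)) {
      if (k > 1L) {
        link <- sample(.NEUTRAL, sample(3:8, 1L), replace = TRUE)
        parts <- c(parts, list(link))
        pos <- pos + length(link)
      }
      domStarts[k] <- pos + 1L
      parts <- c(parts, list(copies[[k]]))
      pos <- pos + length(copies[[k]])
      domEnds[k] <- pos
      domKeyRes[k] <- paste(copies[[k]][keyPos], collapse = "")
    }
    rkStart <- NA_integer_
    rkEnd <- NA_integer_
    if (stats::runif(1) < config@rkLinkerProb) {
      len <- sample(40:60, 1L)
      rk <- ifelse(stats::runif(len) < 0.75,
                   sample(c("R", "K"), len, replace = TRUE),
                   sample(.NEUTRAL, len, replace = TRUE))
      parts <- c(parts, list(rk))
      rkStart <- pos + 1L
      rkEnd <- pos + len
      pos <- pos + len
    }
    nlsStart <- NA_integer_
    nlsEnd <- NA_integer_
    if (signal == "nls") {
      cluster <- c("P", sample(c("K", "R"), 6L, replace = TRUE,
                               prob = c(0.7, 0.3)), "V")
      parts <- c(parts, list(cluster))
      nlsStart <- pos + 2L
      nlsEnd <- pos + 7L
      pos <- pos + length(cluster)
    }
    if (signal == "er") {
      ret <- seqChars(sample(c("DSEL", "NSEL", "KDEL", "HDEL"), 1L))
      parts <- c(parts, list(ret))
      pos <- pos + 4L
    }
    seqs[i] <- paste(unlist(parts), collapse = "")
    compartmentTruth <- switch(signal,
      tat_cleaved = "chloroplast_lumen",
      tat_anchored = "chloroplast_membrane_anchored",
      er = "ER", nls = "nucleus", none = "cytosol")
    rows[[i]] <- data.frame(
      id = ids[i], family = anc$family, ancestor = anc$name,
      n_domains = nDom,
      domain_starts = paste(domStarts, collapse = ","),
      domain_ends = paste(domEnds, collapse = ","),
      signal = signal, rr_position = rrPos, h_start = hStart,
      h_end = hEnd, cleavage_site = cleave, er_leader_end = erLeader,
      nls_start = nlsStart, nls_end = nlsEnd, rk_start = rkStart,
      rk_end = rkEnd, compartment = compartmentTruth,
      key_residues = paste(domKeyRes, collapse = ","),
      kappa = kappa, rho = rho)
  }
  list(records = ProteinSet(ids, seqs,
                            descriptions = paste("synthetic", ids)),
       truth = do.call(rbind, rows))
}

#' Synthetic panel of named ancestral reference proteins
#'
#' Derives `nPerFamily` named ancestors per family by mutating the human
#' core at `divergence` per site; used to exercise ortholog assignment
#' and naming without any real plant sequences. Panel members carry
#' synthetic names (REF_FKBP13 style), cytosolic location and
#' single-domain architecture.
#'
#' @param nPerFamily ancestors per family.
#' @param divergence per-site substitution rate from the human core.
#' @param seed integer seed.
#' @param refs a [ReferenceSet-class].
#' @return List of ancestor entries (name, family, suffix, seq, keyPos,
#'   compartment, composition).
#' @export
referencePanel <- function(nPerFamily = 6L, divergence = 0.3, seed = 1L,
                           refs = loadReferences()) {
  set.seed(seed)
  suffixes <- list(FKBP = c("12", "13", "19", "43", "62", "77"),
                   CYP = c("18", "20", "22", "40", "59", "71"))
  out <- list()
  for (family in c("FKBP", "CYP")) {
    core <- seqChars(referenceProtein(refs, family)@sequence)
    keyPos <- keyPositions(refs, family)$position
    for (k in seq_len(nPerFamily)) {
      sfx <- suffixes[[family]][((k - 1L) %% 6L) + 1L]
      if (k > 6L) sfx <- paste0(sfx, "-", (k - 1L) %/% 6L + 1L)
      mut <- .mutateCore(core, keyPos, divergence, divergence)
      out[[length(out) + 1L]] <- list(
        name = paste0("REF_", family, sfx), family = family, suffix = sfx,
        seq = paste(mut, collapse = ""), keyPos = keyPos,
        compartment = "cytosol", composition = family)
    }
  }
  out
}

#' Compare pipeline output against generator truth
#'
#' @param truth the truth data.frame from [generateFamily()].
#' @param result the [ClassifiedSet-class] from [classifyProteins()] run
#'   on the generated records.
#' @return Named list of metrics: `domainCountAccuracy`, `boundaryMae`
#'   (mean absolute endpoint error, residues, over proteins with the
#'   correct count), `tatSensitivity`, `tatFpr` (on signal-free
#'   sequences), `compartmentAccuracy`, `rkRecall`,
#'   `orthologAccuracy` (`NA` unless the truth has panel ancestors and
#'   names were assigned from them).
#' @export
scoreRecovery <- function(truth, result) {
  inv <- inventory(result)
  if (!setequal(truth$id, inv$id))
    stop("truth and result describe different record sets")
  inv <- inv[match(truth$id, inv$id), ]
  arch <- result@architectures[truth$id]
  calls <- result@calls[truth$id]

  nDet <- vapply(arch, function(a) NROW(a@hits), integer(1))
  countOk <- nDet == truth$n_domains
  maes <- c()
  for (i in which(countOk)) {
    ts <- as.integer(strsplit(truth$domain_starts[i], ",")[[1]])
    te <- as.integer(strsplit(truth$domain_ends[i], ",")[[1]])
    h <- arch[[i]]@hits
    maes <- c(maes, mean(c(abs(h$start - ts), abs(h$end - te))))
  }
  tatDetected <- vapply(calls, function(cl)
    any(cl@evidence$signal == "tat"), logical(1))
  isTat <- truth$signal %in% c("tat_cleaved", "tat_anchored")
  noSignal <- truth$signal == "none"
  rkDetected <- vapply(seq_len(nrow(truth)), function(i) {
    if (is.na(truth$rk_start[i])) return(NA)
    aux <- arch[[i]]@auxFeatures
    rk <- aux[aux$feature == "RK", , drop = FALSE]
    any(rk$start <= truth$rk_end[i] & rk$end >= truth$rk_start[i])
  }, logical(1))
  orthAcc <- NA_real_
  if (any(grepl("^REF_", truth$ancestor))) {
    expectedSuffix <- sub("^REF_(FKBP|CYP)", "", truth$ancestor)
    gotSuffix <- vapply(result@names[truth$id], function(nm)
      if (is.null(nm)) NA_character_ else nm@suffix, character(1))
    orthAcc <- mean(gotSuffix == expectedSuffix, na.rm = FALSE)
  }
  list(domainCountAccuracy = mean(countOk),
       boundaryMae = if (length(maes)) mean(maes) else NA_real_,
       tatSensitivity = if (any(isTat)) mean(tatDetected[isTat])
                        else NA_real_,
       tatFpr = if (any(noSignal)) mean(tatDetected[noSignal])
                else NA_real_,
       compartmentAccuracy = mean(inv$compartment == truth$compartment),
       rkRecall = if (any(!is.na(rkDetected)))
         mean(rkDetected, na.rm = TRUE) else NA_real_,
       orthologAccuracy = orthAcc)
}
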