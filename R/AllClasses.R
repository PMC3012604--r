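# S4 class definitions for the containers flowing through the pipeline.

#' ProteinRecord: one amino-acid sequence
#'
#' A single protein with identifier, free-text description, uppercase
#' sequence over the 20 standard residues plus X, and an organism tag
#' (e.g. "Os", "At", "Hs").
#'
#' @slot id non-empty identifier token.
#' @slot description free-text description.
#' @slot sequence uppercase amino-acid string.
#' @slot organism organism tag.
#' @export
setClass("ProteinRecord",
  representation(id = "character", description = "character",
                 sequence = "character", organism = "character"),
  prototype(description = "", organism = ""))

setValidity("ProteinRecord", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id) || grepl("\\s", object@id))
    return("'id' must be a single non-empty token without whitespace")
  if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
    return("'sequence' must be a single non-empty string")
  bad <- setdiff(unique(seqChars(object@sequence)), AA_ALPHABET)
  if (length(bad))
    return(paste0("illegal sequence character(s): ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Constructor for [ProteinRecord-class]
#'
#' @param id identifier token.
#' @param sequence amino-acid string (uppercased on input).
#' @param description free text.
#' @param organism organism tag.
#' @return A `ProteinRecord`.
#' @export
ProteinRecord <- function(id, sequence, description = "", organism = "") {
  new("ProteinRecord", id = as.character(id),
      sequence = toupper(as.character(sequence)),
      description = as.character(description),
      organism = as.character(organism))
}

#' ProteinSet: a collection of protein records
#'
#' Columnar container for protein records with unique identifiers; the
#' collection type produced by [readFasta()] and consumed by the pipeline.
#'
#' @slot ids identifier vector (unique).
#' @slot descriptions description vector.
#' @slot sequences sequence vector.
#' @slot organisms organism tags.
#' @export
setClass("ProteinSet",
  representation(ids = "character", descriptions = "character",
                 sequences = "character", organisms = "character"))

setValidity("ProteinSet", function(object) {
  n <- length(object@ids)
  if (length(object@descriptions) != n || length(object@sequences) != n ||
      length(object@organisms) != n)
    return("parallel slots must have equal length")
  if (anyDuplicated(object@ids))
    return(paste0("duplicated record id(s): ",
                  paste(unique(object@ids[duplicated(object@ids)]),
                        collapse = ", ")))
  for (i in seq_len(n)) {
    bad <- setdiff(unique(seqChars(object@sequences[i])), AA_ALPHABET)
    if (nchar(object@sequences[i]) < 1L)
      return(paste0("empty sequence for record '", object@ids[i], "'"))
    if (length(bad))
      return(paste0("illegal character(s) in record '", object@ids[i],
                    "': ", paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Constructor for [ProteinSet-class]
#'
#' @param ids identifiers.
#' @param sequences amino-acid strings.
#' @param descriptions descriptions (recycled default "").
#' @param organisms organism tags (recycled default "").
#' @return A `ProteinSet`.
#' @export
ProteinSet <- function(ids, sequences, descriptions = "", organisms = "") {
  n <- length(ids)
  new("ProteinSet", ids = as.character(ids),
      sequences = toupper(as.character(sequences)),
      descriptions = rep_len(as.character(descriptions), n),
      organisms = rep_len(as.character(organisms), n))
}

#' ScoringScheme: substitution matrix plus affine gap penalties
#'
#' @slot matrix symmetric substitution matrix with residue dimnames.
#' @slot gapOpen positive gap-opening penalty.
#' @slot gapExtend positive per-residue gap-extension penalty.
#' @slot name matrix name (e.g. "BLOSUM62").
#' @export
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpen = "numeric",
                 gapExtend = "numeric", name = "character"))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("matrix must have identical row and column names")
  if (!isSymmetric(unname(m)))
    return("matrix must be symmetric")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    return("gap penalties must be non-negative")
  TRUE
})

#' ReferenceSet: the two human reference proteins and their key positions
#'
#' Holds human FKBP12 and human cyclophilin A together with the fixed
#' key-residue positions (14 for the FKBP family, 7 for the CYP family)
#' whose conservation the pipeline scores. Validity enforces the canonical
#' position/residue lists, so a tampered fixture fails hard.
#'
#' @slot fkbpReference hFKBP12 as a [ProteinRecord-class].
#' @slot cypReference hCypA as a [ProteinRecord-class].
#' @slot fkbpKeyPositions data.frame(position, residue), 14 rows.
#' @slot cypKeyPositions data.frame(position, residue), 7 rows.
#' @export
setClass("ReferenceSet",
  representation(fkbpReference = "ProteinRecord",
                 cypReference = "ProteinRecord",
                 fkbpKeyPositions = "data.frame",
                 cypKeyPositions = "data.frame"))

.FKBP_KEY_POSITIONS <- c(27L, 37L, 38L, 43L, 47L, 55L, 56L, 57L, 60L,
                         82L, 83L, 88L, 92L, 100L)
.FKBP_KEY_RESIDUES <- c("Y", "F", "D", "R", "F", "E", "V", "I", "W",
                        "A", "Y", "H", "I", "F")
.CYP_KEY_POSITIONS <- c(54L, 55L, 60L, 111L, 113L, 121L, 126L)
.CYP_KEY_RESIDUES <- c("H", "R", "F", "Q", "F", "W", "H")

setValidity("ReferenceSet", function(object) {
  fk <- object@fkbpKeyPositions
  cy <- object@cypKeyPositions
  if (!identical(as.integer(fk$position), .FKBP_KEY_POSITIONS) ||
      !identical(as.character(fk$residue), .FKBP_KEY_RESIDUES))
    return("FKBP key positions/residues do not match the canonical list")
  if (!identical(as.integer(cy$position), .CYP_KEY_POSITIONS) ||
      !identical(as.character(cy$residue), .CYP_KEY_RESIDUES))
    return("CYP key positions/residues do not match the canonical list")
  fs <- seqChars(object@fkbpReference@sequence)
  cs <- seqChars(object@cypReference@sequence)
  if (max(fk$position) > length(fs) || max(cy$position) > length(cs))
    return("key position beyond reference sequence length")
  if (!identical(fs[fk$position], as.character(fk$residue)))
    return("hFKBP12 sequence does not carry the key residues at the key positions")
  if (!identical(cs[cy$position], as.character(cy$residue)))
    return("hCypA sequence does not carry the key residues at the key positions")
  TRUE
})

#' PairAlignment: result of a pairwise affine-gap alignment
#'
#' @slot alignedA gapped first sequence.
#' @slot alignedB gapped second sequence.
#' @slot score alignment score.
#' @slot mode "global" or "local".
#' @slot aSpan,bSpan 1-based inclusive coordinates of the aligned
#'   (sub)sequences on the ungapped inputs; `c(0L, 0L)` for an empty local
#'   alignment.
#' @export
setClass("PairAlignment",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", mode = "character",
                 aSpan = "integer", bSpan = "integer"))

setValidity("PairAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  if (nchar(object@alignedA) > 0L) {
    a <- seqChars(object@alignedA)
    b <- seqChars(object@alignedB)
    if (any(a == "-" & b == "-"))
      return("no column may have gaps in both rows")
  }
  if (!object@mode %in% c("global", "local"))
    return("mode must be 'global' or 'local'")
  TRUE
})

#' TatSignal: evidence for a twin-arginine (Tat) targeting signal
#'
#' @slot rrPosition 1-based position of the first Arg of the RR pair.
#' @slot hRegion span (start, end) of the hydrophobic stretch.
#' @slot cleavageSite position of the final Ala of the Ala-Xaa-Ala
#'   peptidase motif, or `NA` when absent.
#' @slot anchored `TRUE` when no cleavage site was found (membrane-anchored
#'   mature protein).
#' @export
setClass("TatSignal",
  representation(rrPosition = "integer", hRegion = "integer",
                 cleavageSite = "integer", anchored = "logical"))

setValidity("TatSignal", function(object) {
  if (object@rrPosition >= object@hRegion[1])
    return("RR pair must precede the hydrophobic region")
  if (object@hRegion[1] > object@hRegion[2])
    return("invalid hydrophobic region span")
  if (!identical(object@anchored, is.na(object@cleavageSite)))
    return("anchored flag must mirror the absence of a cleavage site")
  TRUE
})

#' TargetingCall: predicted compartment with the supporting evidence
#'
#' @slot compartment one of cytosol, chloroplast_lumen,
#'   chloroplast_membrane_anchored, ER, nucleus, unassigned.
#' @slot evidence data.frame(signal, start, end, detail) of detected signals.
#' @export
setClass("TargetingCall",
  representation(compartment = "character", evidence = "data.frame"))

.COMPARTMENTS <- c("cytosol", "chloroplast_lumen",
                   "chloroplast_membrane_anchored", "ER", "nucleus",
                   "unassigned")

setValidity("TargetingCall", function(object) {
  if (!object@compartment %in% .COMPARTMENTS)
    return(paste0("unknown compartment '", object@compartment, "'"))
  TRUE
})

#' DomainArchitecture: PPIase-domain hits plus auxiliary features
#'
#' @slot proteinId record identifier.
#' @slot hits data.frame(family, start, end, rawScore, normalizedScore) of
#'   non-overlapping PPIase-domain hits sorted by start.
#' @slot auxFeatures data.frame(feature, start, end) of auxiliary domains
#'   (TPR, CCD, CaM, RRM, Arg/Lys-rich, ... supplied or detected).
#' @slot sdMd "SD" (single catalytic domain, no extras) or "MD".
#' @slot composition composition string in N-to-C order, e.g.
#'   "FKBP×3+TPR+CaM".
#' @export
setClass("DomainArchitecture",
  representation(proteinId = "character", hits = "data.frame",
                 auxFeatures = "data.frame", sdMd = "character",
                 composition = "character"))

setValidity("DomainArchitecture", function(object) {
  h <- object@hits
  if (nrow(h) > 1L) {
    o <- order(h$start)
    if (any(h$start[o][-1] <= h$end[o][-nrow(h)]))
      return("domain hits must be pairwise non-overlapping")
  }
  expectSd <- nrow(h) == 1L && nrow(object@auxFeatures) == 0L
  if (!identical(object@sdMd, if (expectSd) "SD" else "MD"))
    return("sdMd must be SD iff exactly one PPIase hit and no aux features")
  TRUE
})

#' KeyResidueProfile: residues at the fixed reference key positions
#'
#' One character per key position; '-' marks a position absent (gapped) in
#' the protein. Profiles parsed from the shipped conservation tables may
#' contain any uppercase letter (the printed tables are transcribed
#' verbatim).
#'
#' @slot proteinId record identifier.
#' @slot family "FKBP" or "CYP".
#' @slot residues residue string, one character per position.
#' @slot positions the matching 1-based reference positions.
#' @export
setClass("KeyResidueProfile",
  representation(proteinId = "character", family = "character",
                 residues = "character", positions = "integer"))

setValidity("KeyResidueProfile", function(object) {
  if (!object@family %in% c("FKBP", "CYP"))
    return("family must be FKBP or CYP")
  n <- length(object@positions)
  if (object@family == "FKBP" && n != 14L) return("FKBP profiles have 14 positions")
  if (object@family == "CYP" && n != 7L) return("CYP profiles have 7 positions")
  if (nchar(object@residues) != n)
    return("residue string length must equal the number of positions")
  if (grepl("[^A-Z-]", object@residues))
    return("residues must be uppercase letters or '-'")
  TRUE
})

#' ConservationResult: conserved-position count and rounded percentage
#'
#' @slot conservedCount number of key positions retaining the reference
#'   residue.
#' @slot total number of key positions.
#' @slot percent integer percentage, rounded half away from zero.
#' @export
setClass("ConservationResult",
  representation(conservedCount = "integer", total = "integer",
                 percent = "integer"))

setValidity("ConservationResult", function(object) {
  if (object@total <= 0L) return("total must be positive")
  if (object@conservedCount < 0L || object@conservedCount > object@total)
    return("conservedCount must lie in [0, total]")
  if (object@percent !=
      roundHalfUp(100 * object@conservedCount / object@total))
    return("percent must equal the rounded ratio")
  TRUE
})

#' OrthologAssignment: result of the ortholog gates for one candidate
#'
#' A reference is accepted as ortholog only when identity exceeds the
#' threshold and both the subcellular location and the domain architecture
#' match.
#'
#' @slot candidateId candidate identifier.
#' @slot orthologId accepted reference id, or `NA`.
#' @slot orthologSuffix the reference's name suffix (e.g. "20-1"), or `NA`.
#' @slot identityPercent global percent identity to the accepted reference
#'   (best reference when none accepted).
#' @slot similarityPercent global percent similarity, same convention.
#' @slot locationMatch,architectureMatch gate outcomes for that reference.
#' @export
setClass("OrthologAssignment",
  representation(candidateId = "character", orthologId = "character",
                 orthologSuffix = "character", identityPercent = "numeric",
                 similarityPercent = "numeric", locationMatch = "logical",
                 architectureMatch = "logical"))

#' ImmunophilinName: structured immunophilin gene name
#'
#' prefix (organism) + family token (FKBP/CYP/TIG) + suffix (ortholog
#' suffix or rounded kDa) + optional paralog letter.
#'
#' @slot prefix organism prefix, e.g. "Os".
#' @slot familyToken "FKBP", "CYP" or "TIG".
#' @slot suffix suffix string ("" for TIG).
#' @slot paralogLetter "" or a lowercase letter.
#' @export
setClass("ImmunophilinName",
  representation(prefix = "character", familyToken = "character",
                 suffix = "character", paralogLetter = "character"),
  prototype(paralogLetter = ""))

setValidity("ImmunophilinName", function(object) {
  if (!object@familyToken %in% c("FKBP", "CYP", "TIG", "IMM"))
    return("familyToken must be FKBP, CYP, TIG or IMM")
  if (!grepl("^[a-z]*$", object@paralogLetter))
    return("paralogLetter must be '' or lowercase letters")
  TRUE
})

#' GeneratorConfig: parameters of the synthetic immunophilin generator
#'
#' @slot nProteins number of proteins to generate.
#' @slot fkbpProportion probability that a protein is FKBP-derived.
#' @slot keyMutationRate per-site substitution rate at key positions.
#' @slot backgroundMutationRate per-site substitution rate elsewhere.
#' @slot signalProbs named probabilities for tat_cleaved, tat_anchored, er,
#'   nls, none (must sum to 1).
#' @slot multiDomainProb probability of carrying 2-3 domain copies.
#' @slot copyProbs probabilities of 2 and 3 copies given multi-domain.
#' @slot rkLinkerProb probability of an implanted Arg/Lys-rich linker.
#' @slot seed integer seed driving all randomness.
#' @export
setClass("GeneratorConfig",
  representation(nProteins = "integer", fkbpProportion = "numeric",
                 keyMutationRate = "numeric",
                 backgroundMutationRate = "numeric",
                 signalProbs = "numeric", multiDomainProb = "numeric",
                 copyProbs = "numeric", rkLinkerProb = "numeric",
                 seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  pr <- c(object@fkbpProportion, object@keyMutationRate,
          object@backgroundMutationRate, object@multiDomainProb,
          object@rkLinkerProb, object@signalProbs, object@copyProbs)
  if (any(pr < 0) || any(pr > 1))
    return("all probabilities/rates must lie in [0, 1]")
  need <- c("tat_cleaved", "tat_anchored", "er", "nls", "none")
  if (!identical(sort(names(object@signalProbs)), sort(need)))
    return("signalProbs must be named tat_cleaved, tat_anchored, er, nls, none")
  if (abs(sum(object@signalProbs) - 1) > 1e-8)
    return("signalProbs must sum to 1")
  if (!identical(sort(names(object@copyProbs)), c("2", "3")))
    return("copyProbs must be named '2' and '3'")
  if (abs(sum(object@copyProbs) - 1) > 1e-8)
    return("copyProbs must sum to 1")
  if (object@nProteins < 1L) return("nProteins must be >= 1")
  TRUE
})

#' ClassifiedSet: full output of the classification pipeline
#'
#' @slot inventory one row per input record (id, name, family, SD/MD class,
#'   composition, compartment, conservation, mature mass, ortholog, status).
#' @slot architectures,calls,profiles,assignments,names per-record objects,
#'   keyed by record id.
#' @slot trees per-family `phylo` trees (families with >= 3 members).
#' @slot msas per-family multiple alignments backing the trees.
#' @slot errors per-record failure messages (empty when all succeeded).
#' @slot config the configuration list used.
#' @export
setClass("ClassifiedSet",
  representation(inventory = "data.frame", architectures = "list",
                 calls = "list", profiles = "list", assignments = "list",
                 names = "list", trees = "list", msas = "list",
                 errors = "character", config = "list"))
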