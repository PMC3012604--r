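# Packaged reference fixtures: the two human reference proteins, their
# key-residue positions, the hydropathy scale and the residue masses.

#' Load the packaged reference set
#'
#' Returns human FKBP12 and human cyclophilin A together with the fixed
#' key positions whose conservation the pipeline scores: 14 positions on
#' hFKBP12 (FK506 binding / PPIase activity) and 7 positions on hCypA
#' (cyclosporin A binding / PPIase activity). Validity checking fails hard
#' if a fixture was tampered with (residue-at-position mismatch).
#'
#' @return A [ReferenceSet-class].
#' @examples
#' refs <- loadReferences()
#' keyResidueString(refs, "FKBP")  # "YFDRFEVIWAYHIF"
#' @export
loadReferences <- function() {
  if (!is.null(.immfamCache[["references"]]))
    return(.immfamCache[["references"]])
  fk <- readFasta(system.file("extdata", "hFKBP12.fasta",
                              package = "immfam"), organism = "Hs")[[1L]]
  cy <- readFasta(system.file("extdata", "hCYPA.fasta",
                              package = "immfam"), organism = "Hs")[[1L]]
  fkp <- utils::read.delim(system.file("extdata", "fkbp_key_positions.tsv",
                                       package = "immfam"),
                           colClasses = c("integer", "character"))
  cyp <- utils::read.delim(system.file("extdata", "cyp_key_positions.tsv",
                                       package = "immfam"),
                           colClasses = c("integer", "character"))
  refs <- new("ReferenceSet", fkbpReference = fk, cypReference = cy,
              fkbpKeyPositions = fkp, cypKeyPositions = cyp)
  .immfamCache[["references"]] <- refs
  refs
}

#' Reference protein for a family
#'
#' @param refs a [ReferenceSet-class].
#' @param family "FKBP" or "CYP".
#' @return A [ProteinRecord-class].
#' @export
referenceProtein <- function(refs, family = c("FKBP", "CYP")) {
  family <- match.arg(family)
  if (family == "FKBP") refs@fkbpReference else refs@cypReference
}

#' Key positions table for a family
#'
#' @param refs a [ReferenceSet-class].
#' @param family "FKBP" or "CYP".
#' @return data.frame(position, residue).
#' @export
keyPositions <- function(refs, family = c("FKBP", "CYP")) {
  family <- match.arg(family)
  if (family == "FKBP") refs@fkbpKeyPositions else refs@cypKeyPositions
}

#' Reference key residues as a single string
#'
#' @param refs a [ReferenceSet-class].
#' @param family "FKBP" or "CYP".
#' @return "YFDRFEVIWAYHIF" for FKBP, "HRFQFWH" for CYP.
#' @export
keyResidueString <- function(refs, family = c("FKBP", "CYP")) {
  paste(keyPositions(refs, family)$residue, collapse = "")
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 standard residues; positive is
#'   hydrophobic.
#' @export
hydropathyScale <- function() {
  if (is.null(.immfamCache[["kd"]])) {
    d <- utils::read.delim(system.file("extdata", "kd_hydropathy.tsv",
                                       package = "immfam"))
    .immfamCache[["kd"]] <- stats::setNames(d$hydropathy, d$residue)
  }
  .immfamCache[["kd"]]
}

#' Average residue masses (Da)
#'
#' Monoisotopic-free average masses of the 20 amino-acid residues (the
#' residue, i.e. minus water); add one water for a whole chain.
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
residueMasses <- function() {
  if (is.null(.immfamCache[["masses"]])) {
    d <- utils::read.delim(system.file("extdata", "aa_masses.tsv",
                                       package = "immfam"))
    .immfamCache[["masses"]] <- stats::setNames(d$average_mass, d$residue)
  }
  .immfamCache[["masses"]]
}
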