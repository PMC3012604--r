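# Shared helpers for the test suite. Fixtures are built in code.

SCHEME <- defaultScoringScheme()
REFS <- loadReferences()

randomSeq <- function(n, alphabet = immfam:::AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

randomProteinSet <- function(nRecords, minLen = 5L, maxLen = 60L) {
  ids <- sprintf("rec%03d", seq_len(nRecords))
  seqs <- vapply(ids, function(i)
    randomSeq(sample(minLen:maxLen, 1L)), character(1))
  ProteinSet(ids, seqs,
             descriptions = paste("random record", seq_len(nRecords)))
}

# Fetch a parsed row of a packaged family table by its rice (or, failing
# that, Arabidopsis) identifier.
tableRow <- function(table, id) {
  hit <- Filter(function(r) r$osId == id || r$atId == id, table$rows)
  if (!length(hit)) stop("row not found: ", id)
  hit[[1]]
}

TABLE1 <- parseDittoTable(immfam:::dittoTablePath("FKBP"), REFS, "FKBP")
TABLE2 <- parseDittoTable(immfam:::dittoTablePath("CYP"), REFS, "CYP")
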