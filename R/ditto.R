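# Parser/renderer for the ditto-notation conservation tables, and the
# audit that recomputes their printed values.
#
# Cell dialect (tab-separated, one row per protein pair):
#   "     the reference residue (for every organism present in the row)
#   X     residue X for every organism present
#   X/Y   organism-1 (rice) residue X, organism-2 (Arabidopsis) residue Y
#   X/"   organism-1 X, organism-2 the reference residue
#   -     position absent (gapped)
# Rows with an empty first column carry an organism-2 profile only. The
# special last row COLUMN_CONSERVED holds the printed per-position
# conservation percentages as os/at pairs.

.resolveDittoPart <- function(part, refResidue) {
  if (part == "\"") refResidue
  else part  # includes "-" and plain letters
}

.parseDittoCell <- function(token, refResidue, hasOs, hasAt) {
  if (grepl("/", token, fixed = TRUE)) {
    parts <- strsplit(token, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("illegal cell token '", token, "'")
    list(os = .resolveDittoPart(parts[1], refResidue),
         at = .resolveDittoPart(parts[2], refResidue))
  } else {
    v <- .resolveDittoPart(token, refResidue)
    list(os = if (hasOs) v else NA_character_,
         at = if (hasAt) v else NA_character_)
  }
}

.parsePrintedPair <- function(s) {
  if (!nzchar(s)) return(c(os = NA_real_, at = NA_real_))
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "-")
  num <- function(x) if (x %in% c("-", "")) NA_real_ else as.numeric(x)
  c(os = num(parts[1]), at = num(parts[2]))
}

#' Parse a ditto-notation conservation table
#'
#' @param x path to a table file, or a character vector of its lines.
#' @param refs a [ReferenceSet-class].
#' @param family "FKBP" or "CYP".
#' @return An object of class `DittoTable`: a list with `family`,
#'   `positions`, `header`, `rows` (each with ids, the expanded
#'   [KeyResidueProfile-class] per organism, the verbatim cell tokens and
#'   the printed conserved/similarity values) and `columnPrinted` (the
#'   printed bottom-row percentages).
#' @export
parseDittoTable <- function(x, refs = loadReferences(),
                            family = c("FKBP", "CYP")) {
  family <- match.arg(family)
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  ref <- keyPositions(refs, family)
  nPos <- nrow(ref)
  nCol <- 2L + nPos + 2L
  fields <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    length(f) <- nCol  # pad dropped trailing empties
    f[is.na(f)] <- ""
    f
  })
  header <- lines[1]
  rows <- list()
  columnPrinted <- NULL
  for (k in seq_along(fields)[-1]) {
    f <- fields[[k]]
    if (length(strsplit(lines[k], "\t", fixed = TRUE)[[1]]) > nCol)
      stop("row ", k, ": wrong column count")
    osId <- f[1]
    atId <- f[2]
    cells <- f[3:(2L + nPos)]
    if (osId == "COLUMN_CONSERVED") {
      columnPrinted <- t(vapply(cells, .parsePrintedPair, numeric(2)))
      rownames(columnPrinted) <- as.character(ref$position)
      next
    }
    hasOs <- nzchar(osId)
    hasAt <- nzchar(atId)
    if (!hasOs && !hasAt) stop("row ", k, ": no organism id")
    bad <- cells[!grepl("^([A-Z\"-]|[A-Z\"-]/[A-Z\"-])$", cells)]
    if (length(bad))
      stop("row ", k, ": illegal cell token '", bad[1], "'")
    parsed <- lapply(seq_len(nPos), function(i)
      .parseDittoCell(cells[i], as.character(ref$residue[i]), hasOs, hasAt))
    osRes <- vapply(parsed, `[[`, character(1), "os")
    atRes <- vapply(parsed, `[[`, character(1), "at")
    mkProfile <- function(id, res) {
      if (anyNA(res)) return(NULL)
      new("KeyResidueProfile", proteinId = id, family = family,
          residues = paste(res, collapse = ""),
          positions = as.integer(ref$position))
    }
    printed <- .parsePrintedPair(f[2L + nPos + 1L])
    rows[[length(rows) + 1L]] <- list(
      osId = osId, atId = atId, cells = cells,
      os = if (hasOs) mkProfile(osId, osRes) else NULL,
      at = if (hasAt) mkProfile(atId, atRes) else NULL,
      printedConservedRaw = f[2L + nPos + 1L],
      printedConservedOs = printed[["os"]],
      printedConservedAt = printed[["at"]],
      printedSimilarity = if (nzchar(f[2L + nPos + 2L]))
        as.numeric(f[2L + nPos + 2L]) else NA_real_)
  }
  structure(list(family = family, positions = as.integer(ref$position),
                 header = header, rows = rows,
                 columnPrinted = columnPrinted),
            class = "DittoTable")
}

.encodeDittoPart <- function(res, refResidue) {
  if (is.na(res)) "-"
  else if (res == refResidue) "\""
  else res
}

#' Render a ditto-notation conservation table
#'
#' Inverse of [parseDittoTable()]. With `values = "printed"` the parsed
#' table round-trips byte-identically; with `values = "recomputed"` the
#' conserved/similarity columns (and the bottom row) are recomputed from
#' the expanded residues under the stated rules.
#'
#' @param parsed a `DittoTable` from [parseDittoTable()], or a list with
#'   the same structure.
#' @param refs a [ReferenceSet-class].
#' @param values "printed" or "recomputed".
#' @return Character vector of table lines.
#' @export
renderDittoTable <- function(parsed, refs = loadReferences(),
                             values = c("printed", "recomputed")) {
  values <- match.arg(values)
  ref <- keyPositions(refs, parsed$family)
  nPos <- nrow(ref)
  out <- parsed$header
  consOf <- function(profile) {
    if (is.null(profile)) return(NA_real_)
    conservedPercent(profile, refs)@percent
  }
  for (row in parsed$rows) {
    hasOs <- nzchar(row$osId)
    hasAt <- nzchar(row$atId)
    if (values == "printed" && !is.null(row$cells)) {
      # the printed tables occasionally spell a residue out even where it
      # equals the reference; keep the verbatim tokens for byte-identical
      # round trips
      cells <- row$cells
    } else cells <- vapply(seq_len(nPos), function(i) {
      rr <- as.character(ref$residue[i])
      osP <- if (!is.null(row$os))
        .encodeDittoPart(substr(row$os@residues, i, i), rr) else NA
      atP <- if (!is.null(row$at))
        .encodeDittoPart(substr(row$at@residues, i, i), rr) else NA
      if (hasOs && hasAt) {
        if (identical(osP, atP)) osP else paste0(osP, "/", atP)
      } else if (hasOs) osP else atP
    }, character(1))
    if (values == "printed") {
      consCell <- row$printedConservedRaw
      simCell <- if (is.na(row$printedSimilarity)) ""
                 else format(row$printedSimilarity)
    } else {
      fmt <- function(v) if (is.na(v)) "-" else format(v)
      consCell <- paste0(fmt(consOf(row$os)), "/", fmt(consOf(row$at)))
      simCell <- if (!is.null(row$os) && !is.null(row$at))
        format(pairSimilarityPercent(row$os, row$at, mode = "identity"))
      else ""
    }
    out <- c(out, paste(c(row$osId, row$atId, cells, consCell, simCell),
                        collapse = "\t"))
  }
  if (!is.null(parsed$columnPrinted)) {
    if (values == "printed") {
      fmtPair <- function(v) {
        f <- function(x) if (is.na(x)) "-" else format(x)
        paste0(f(v[1]), "/", f(v[2]))
      }
      cells <- apply(parsed$columnPrinted, 1L, fmtPair)
    } else {
      osProfiles <- Filter(Negate(is.null), lapply(parsed$rows, `[[`, "os"))
      atProfiles <- Filter(Negate(is.null), lapply(parsed$rows, `[[`, "at"))
      cells <- vapply(seq_len(nPos), function(i)
        paste0(columnConservation(osProfiles, i, refs), "/",
               columnConservation(atProfiles, i, refs)), character(1))
    }
    out <- c(out, paste(c("COLUMN_CONSERVED", "", cells, "", ""),
                        collapse = "\t"))
  }
  out
}

# Path of a packaged family table fixture.
dittoTablePath <- function(family = c("FKBP", "CYP")) {
  family <- match.arg(family)
  system.file("extdata",
              if (family == "FKBP") "table1_fkbp.tsv" else "table2_cyp.tsv",
              package = "immfam")
}

#' Recompute the printed family conservation tables and audit them
#'
#' Parses the packaged rice/Arabidopsis key-residue table for one family,
#' recomputes every Conserved and (identity-mode) Similarity value and the
#' per-position bottom row from the printed residue cells, and reports
#' per-row and per-column agreement with the printed numbers. Mismatching
#' entries are flagged, never forced: a handful of printed values are
#' internally inconsistent with their own printed residues, and the audit
#' surfaces exactly those.
#'
#' The bottom-row denominators count rows that carry a profile for the
#' respective organism (so organism-2-only rows do not enter the rice
#' column and vice versa).
#'
#' @param family "FKBP" or "CYP".
#' @param refs a [ReferenceSet-class].
#' @return An object of class `PaperTableAudit`: list with `rows` and
#'   `columns` data.frames and the `family`.
#' @export
recomputePaperTables <- function(family = c("FKBP", "CYP"),
                                 refs = loadReferences()) {
  family <- match.arg(family)
  parsed <- parseDittoTable(dittoTablePath(family), refs, family)
  cons <- function(p) if (is.null(p)) NA_integer_
                      else conservedPercent(p, refs)@percent
  rows <- do.call(rbind, lapply(parsed$rows, function(row) {
    recOs <- cons(row$os)
    recAt <- cons(row$at)
    recSim <- if (!is.null(row$os) && !is.null(row$at))
      pairSimilarityPercent(row$os, row$at, mode = "identity")
    else NA_integer_
    cmp <- function(printed, recomputed) {
      if (is.na(printed) || is.na(recomputed)) NA else printed == recomputed
    }
    data.frame(osId = row$osId, atId = row$atId,
               printedOs = row$printedConservedOs, recomputedOs = recOs,
               osMatch = cmp(row$printedConservedOs, recOs),
               printedAt = row$printedConservedAt, recomputedAt = recAt,
               atMatch = cmp(row$printedConservedAt, recAt),
               printedSimilarity = row$printedSimilarity,
               recomputedSimilarity = recSim,
               similarityMatch = cmp(row$printedSimilarity, recSim))
  }))
  rows$flagged <- with(rows, (!is.na(osMatch) & !osMatch) |
                         (!is.na(atMatch) & !atMatch) |
                         (!is.na(similarityMatch) & !similarityMatch))
  osProfiles <- Filter(Negate(is.null), lapply(parsed$rows, `[[`, "os"))
  atProfiles <- Filter(Negate(is.null), lapply(parsed$rows, `[[`, "at"))
  nPos <- length(parsed$positions)
  columns <- data.frame(
    position = parsed$positions,
    printedOs = parsed$columnPrinted[, 1],
    recomputedOs = vapply(seq_len(nPos), function(i)
      columnConservation(osProfiles, i, refs), integer(1)),
    printedAt = parsed$columnPrinted[, 2],
    recomputedAt = vapply(seq_len(nPos), function(i)
      columnConservation(atProfiles, i, refs), integer(1)))
  columns$osMatch <- columns$printedOs == columns$recomputedOs
  columns$atMatch <- columns$printedAt == columns$recomputedAt
  columns$flagged <- (!is.na(columns$osMatch) & !columns$osMatch) |
    (!is.na(columns$atMatch) & !columns$atMatch)
  structure(list(family = family, rows = rows, columns = columns),
            class = "PaperTableAudit")
}

#' @export
print.PaperTableAudit <- function(x, ...) {
  cat("Conservation-table audit [", x$family, "]: ",
      sum(!x$rows$flagged), "/", nrow(x$rows), " rows consistent, ",
      sum(x$rows$flagged), " flagged\n", sep = "")
  if (any(x$rows$flagged)) {
    f <- x$rows[x$rows$flagged, ]
    for (i in seq_len(nrow(f)))
      cat("  row ", f$osId[i], ifelse(nzchar(f$atId[i]),
                                      paste0(" / ", f$atId[i]), ""),
          ": printed ", f$printedOs[i], "/", f$printedAt[i],
          " vs recomputed ", f$recomputedOs[i], "/", f$recomputedAt[i],
          "\n", sep = "")
  }
  if (any(x$columns$flagged))
    cat("  flagged bottom-row positions:",
        paste(x$columns$position[x$columns$flagged], collapse = ", "), "\n")
  invisible(x)
}
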