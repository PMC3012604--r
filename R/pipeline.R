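# End-to-end classification pipeline and its configuration.

#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline with its default. Values can
#' be overridden via a YAML file ([readImmfamConfig()]) or by editing the
#' returned list.
#'
#' @return Nested named list of parameters.
#' @export
immfamConfig <- function() {
  list(
    scheme = list(gapOpen = 10, gapExtend = 0.5),
    domain = list(minNormalized = 0.3, maxCopies = 4L),
    rk = list(window = 20L, minFraction = 0.4, minLength = 30L),
    tat = list(nWindow = 80L, hMinLen = 8L, hMinMean = 1.5,
               cleaveWindow = 30L, allowVariant = FALSE),
    er = list(window = 30L),
    nls = list(monoWindow = 6L, monoMinBasic = 4L, biSpacer = c(9L, 12L)),
    orthology = list(idThreshold = 50),
    naming = list(prefix = "Os", massMode = "mature")
  )
}

#' Read a YAML configuration file
#'
#' Keys present in the file override the defaults of [immfamConfig()];
#' everything else keeps its default.
#'
#' @param path path to a YAML file.
#' @return Nested named list of parameters.
#' @export
readImmfamConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(immfamConfig(), user)
  cfg
}

# Classify one record: domains, signals, localization, conservation.
.classifyOne <- function(rec, refs, scheme, cfg, aux) {
  hits <- scanPpiaseDomains(rec, refs, scheme,
                            minNormalized = cfg$domain$minNormalized,
                            maxCopies = cfg$domain$maxCopies)
  rk <- detectRkRich(rec, window = cfg$rk$window,
                     minFraction = cfg$rk$minFraction,
                     minLength = cfg$rk$minLength)
  auxAll <- data.frame(feature = character(0), start = integer(0),
                       end = integer(0))
  if (NROW(aux))
    auxAll <- rbind(auxAll, aux[, c("feature", "start", "end")])
  if (NROW(rk))
    auxAll <- rbind(auxAll, data.frame(feature = "RK", start = rk$start,
                                       end = rk$end))
  arch <- classifyArchitecture(hits, auxAll, proteinId = rec@id)
  tat <- detectTatSignal(rec, nWindow = cfg$tat$nWindow,
                         hMinLen = cfg$tat$hMinLen,
                         hMinMean = cfg$tat$hMinMean,
                         cleaveWindow = cfg$tat$cleaveWindow,
                         allowVariant = cfg$tat$allowVariant)
  erSig <- detectErSignal(rec, window = cfg$er$window,
                          hMinLen = cfg$tat$hMinLen,
                          hMinMean = cfg$tat$hMinMean)
  erRet <- if (nchar(rec@sequence) >= 4L) detectErRetention(rec) else NULL
  nls <- detectNls(rec, monoWindow = cfg$nls$monoWindow,
                   monoMinBasic = cfg$nls$monoMinBasic,
                   biSpacer = cfg$nls$biSpacer)
  call <- predictLocalization(rec, tat = tat, erSignal = erSig,
                              erRetention = erRet, nls = nls)
  family <- NA_character_
  profile <- NULL
  consRes <- NULL
  if (NROW(hits)) {
    rep <- selectRepresentativeDomain(hits)
    family <- rep$family
    domSeq <- substr(rec@sequence, rep$start, rep$end)
    profile <- extractKeyResidues(domSeq, referenceProtein(refs, family),
                                  keyPositions(refs, family), scheme,
                                  family = family, proteinId = rec@id)
    consRes <- conservedPercent(profile, refs)
  }
  cleavage <- NULL
  if (!is.null(tat) && !tat@anchored) {
    cleavage <- tat@cleavageSite
  } else if (identical(call@compartment, "ER") && !is.null(erSig)) {
    cleavage <- erSig[2]
  }
  mass <- matureMass(rec, cleavage)
  list(record = rec, hits = hits, arch = arch, call = call,
       profile = profile, conservation = consRes, family = family,
       massDa = mass$da, massKda = mass$kda)
}

#' Classify a set of candidate immunophilin proteins
#'
#' Runs the full pipeline on every record: PPIase-domain scan and
#' architecture classification, targeting-signal detection and
#' compartment call, key-residue extraction on the representative (most
#' conserved) domain and conservation scoring, optional ortholog
#' assignment against named references, naming, and per-family
#' neighbor-joining trees (families with at least three members).
#' Per-record failures are caught, reported in the `errors` slot and as a
#' failed `status` row in the inventory — never silently dropped. The
#' pipeline is fully deterministic.
#'
#' @param x a [ProteinSet-class] or path to a FASTA file (non-empty).
#' @param references optional named references for ortholog assignment: a
#'   [ProteinSet-class] (or FASTA path) whose entries are classified with
#'   the same pipeline, or a pre-built list as accepted by
#'   [assignOrtholog()].
#' @param refMeta optional data.frame(id, suffix) overriding the suffix
#'   parsed from reference ids (anything after the FKBP/CYP token).
#' @param auxFeatures optional data.frame from [readAuxFeatures()] (or a
#'   path) with externally supplied auxiliary domains.
#' @param config configuration list ([immfamConfig()]).
#' @param tigIds record ids flagged as trigger-factor-like; they are
#'   named `<prefix>TIG` regardless of their domain family.
#' @param refs a [ReferenceSet-class].
#' @return A [ClassifiedSet-class].
#' @export
classifyProteins <- function(x, references = NULL, refMeta = NULL,
                             auxFeatures = NULL, config = immfamConfig(),
                             tigIds = character(), refs = loadReferences()) {
  set <- if (is(x, "ProteinSet")) x else readFasta(x)
  if (!length(set)) stop("empty input: no records to classify")
  scheme <- defaultScoringScheme(config$scheme$gapOpen,
                                 config$scheme$gapExtend)
  if (is.character(auxFeatures)) auxFeatures <- readAuxFeatures(auxFeatures)

  refEntries <- NULL
  if (!is.null(references)) {
    if (is.list(references) && !is(references, "ProteinSet")) {
      refEntries <- references
    } else {
      refSet <- if (is(references, "ProteinSet")) references
                else readFasta(references)
      refEntries <- lapply(seq_len(length(refSet)), function(i) {
        rec <- refSet[[i]]
        cl <- .classifyOne(rec, refs, scheme, config,
                           aux = data.frame())
        suffix <- if (!is.null(refMeta) && rec@id %in% refMeta$id) {
          refMeta$suffix[match(rec@id, refMeta$id)]
        } else {
          sub("^.*(FKBP|CYP|TIG)[_-]?", "", rec@id)
        }
        list(record = rec, compartment = cl$call@compartment,
             composition = cl$arch@composition, suffix = suffix)
      })
    }
  }

  n <- length(set)
  perRecord <- vector("list", n)
  errors <- character(0)
  for (i in seq_len(n)) {
    rec <- set[[i]]
    aux <- data.frame()
    if (!is.null(auxFeatures) && NROW(auxFeatures))
      aux <- auxFeatures[auxFeatures$protein_id == rec@id, , drop = FALSE]
    perRecord[i] <- list(tryCatch(
      .classifyOne(rec, refs, scheme, config, aux),
      error = function(e) {
        errors <<- c(errors,
                     stats::setNames(conditionMessage(e), rec@id))
        NULL
      }))
  }
  ids <- proteinIds(set)
  ok <- !vapply(perRecord, is.null, logical(1))

  assignments <- stats::setNames(vector("list", n), ids)
  if (!is.null(refEntries)) {
    for (i in which(ok)) {
      cl <- perRecord[[i]]
      assignments[[i]] <- assignOrtholog(
        list(record = cl$record, compartment = cl$call@compartment,
             composition = cl$arch@composition),
        refEntries, idThreshold = config$orthology$idThreshold,
        scheme = scheme)
    }
  }

  candidates <- lapply(which(ok), function(i) {
    cl <- perRecord[[i]]
    fam <- if (ids[i] %in% tigIds) "TIG"
           else if (is.na(cl$family)) "IMM" else cl$family
    list(id = ids[i], family = fam, assignment = assignments[[i]],
         massDa = cl$massDa, record = cl$record)
  })
  nameList <- stats::setNames(vector("list", n), ids)
  if (length(candidates)) {
    named <- assignNames(candidates, organismPrefix = config$naming$prefix,
                         scheme = scheme)
    nameList[names(named)] <- named
  }

  invRows <- lapply(seq_len(n), function(i) {
    if (!ok[i]) {
      return(data.frame(id = ids[i], name = NA_character_,
                        family = NA_character_, sd_md = NA_character_,
                        composition = NA_character_,
                        compartment = NA_character_,
                        conserved_count = NA_integer_,
                        conserved_total = NA_integer_,
                        conserved_percent = NA_integer_,
                        mature_kda = NA_integer_,
                        ortholog = NA_character_,
                        identity_percent = NA_real_,
                        status = paste0("failed: ",
                                        errors[[match(ids[i],
                                                      names(errors))]])))
    }
    cl <- perRecord[[i]]
    asn <- assignments[[i]]
    data.frame(
      id = ids[i],
      name = if (!is.null(nameList[[i]])) nameString(nameList[[i]])
             else NA_character_,
      family = cl$family, sd_md = cl$arch@sdMd,
      composition = cl$arch@composition,
      compartment = cl$call@compartment,
      conserved_count = if (!is.null(cl$conservation))
        cl$conservation@conservedCount else NA_integer_,
      conserved_total = if (!is.null(cl$conservation))
        cl$conservation@total else NA_integer_,
      conserved_percent = if (!is.null(cl$conservation))
        cl$conservation@percent else NA_integer_,
      mature_kda = cl$massKda,
      ortholog = if (!is.null(asn)) asn@orthologId else NA_character_,
      identity_percent = if (!is.null(asn)) asn@identityPercent
                         else NA_real_,
      status = "ok")
  })
  inv <- do.call(rbind, invRows)

  trees <- list()
  msas <- list()
  for (family in c("FKBP", "CYP")) {
    members <- ids[ok][vapply(perRecord[ok], function(cl)
      identical(cl$family, family), logical(1))]
    if (length(members) >= 3L) {
      msa <- progressiveMsa(sequences(set)[members], scheme)
      msas[[family]] <- msa
      D <- tryCatch(pDistanceMatrix(msa), error = function(e)
        # a diverse family can leave a pair with no shared gap-free MSA
        # columns; fall back to pairwise-alignment distances
        pairwisePDistances(sequences(set)[members], scheme))
      trees[[family]] <- neighborJoining(D)
    }
  }

  new("ClassifiedSet",
      inventory = inv,
      architectures = stats::setNames(lapply(perRecord, function(cl)
        if (is.null(cl)) NULL else cl$arch), ids),
      calls = stats::setNames(lapply(perRecord, function(cl)
        if (is.null(cl)) NULL else cl$call), ids),
      profiles = stats::setNames(lapply(perRecord, function(cl)
        if (is.null(cl)) NULL else cl$profile), ids),
      assignments = assignments, names = nameList, trees = trees,
      msas = msas, errors = errors, config = config)
}

#' Write the pipeline reports to a directory
#'
#' Emits the inventory table (TSV), one ditto-notation conservation table
#' per family present (recomputed values), and one Newick tree per family
#' with at least three members.
#'
#' @param result a [ClassifiedSet-class].
#' @param dir output directory (created if missing).
#' @param refs a [ReferenceSet-class].
#' @return Invisibly, the paths written.
#' @export
writeReports <- function(result, dir, refs = loadReferences()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  invPath <- file.path(dir, "inventory.tsv")
  utils::write.table(inventory(result), invPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, invPath)
  for (family in c("FKBP", "CYP")) {
    profs <- Filter(function(p) !is.null(p) && p@family == family,
                    result@profiles)
    if (!length(profs)) next
    ref <- keyPositions(refs, family)
    header <- paste(c("os_id", "at_id", paste0("p", ref$position),
                      "conserved", "similarity"), collapse = "\t")
    rows <- lapply(profs, function(p)
      list(osId = p@proteinId, atId = "", os = p, at = NULL,
           printedConservedRaw = "", printedConservedOs = NA_real_,
           printedConservedAt = NA_real_, printedSimilarity = NA_real_))
    parsed <- structure(list(family = family,
                             positions = as.integer(ref$position),
                             header = header, rows = unname(rows),
                             columnPrinted = NULL),
                        class = "DittoTable")
    p <- file.path(dir, paste0("conservation_", family, ".tsv"))
    writeLines(renderDittoTable(parsed, refs, values = "recomputed"), p)
    paths <- c(paths, p)
  }
  for (family in names(result@trees)) {
    p <- file.path(dir, paste0("tree_", family, ".nwk"))
    writeNewickTree(result@trees[[family]], file = p)
    paths <- c(paths, p)
  }
  cfgPath <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(result@config, cfgPath)
  paths <- c(paths, cfgPath)
  invisible(paths)
}
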