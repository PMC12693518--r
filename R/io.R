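## Format readers and writers. TSV outputs carry a commented header naming
## units and conventions (1-based coordinates, neutral masses in Da,
## proportions on [0, 1]).

#' @keywords internal
.tsvHeader <- function(con, lines) {
  writeLines(paste0("# ", lines), con)
}

#' Write / read a probe definition as JSON
#'
#' The JSON carries the residue sequence as an array of codes (multi-letter
#' lesion codes included), 1-based lesion and label positions, and the enzyme
#' context.
#'
#' @param design a \code{\linkS4class{ProbeDesign}}.
#' @param path output / input file.
#' @return \code{readProbeJSON} returns a \code{\linkS4class{ProbeDesign}}.
#' @export
writeProbeJSON <- function(design, path) {
  stopifnot(is(design, "ProbeDesign"))
  obj <- list(
    format = "bermass-probe-1",
    coordinates = "1-based",
    sequence = probeSequence(design),
    topology = probeTopology(design),
    lesion_index = lesionIndex(design),
    lesion_kind = design@lesionKind,
    opposite_base = design@oppositeBase,
    label_indices = labelIndices(design),
    label_side = design@labelSide,
    analysis_enzymes = design@analysisEnzymes,
    diagnostic_enzyme = design@diagnosticEnzyme
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname writeProbeJSON
#' @export
readProbeJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- o$diagnostic_enzyme
  if (is.null(de)) de <- NA_character_
  ProbeDesign(as.character(o$sequence), topology = o$topology,
              lesionIndex = o$lesion_index, lesionKind = o$lesion_kind,
              oppositeBase = o$opposite_base,
              labelIndices = as.integer(o$label_indices),
              labelSide = o$label_side,
              analysisEnzymes = as.character(unlist(o$analysis_enzymes)),
              diagnosticEnzyme = de)
}

#' Write a probe top strand as FASTA
#'
#' One-letter codes only: abasic residues (AP/rAP/F) are exported as
#' \code{N}; the lesion kind is authoritative in the JSON definition.
#'
#' @param design a \code{\linkS4class{ProbeDesign}}.
#' @param path output file.
#' @param name FASTA record name.
#' @export
writeProbeFASTA <- function(design, path, name = "probe_top_strand") {
  seqv <- probeSequence(design)
  seqv[seqv %in% c("AP", "rAP", "F")] <- "N"
  x <- Biostrings::BStringSet(paste(seqv, collapse = ""))
  names(x) <- sprintf("%s %s lesion=%d label_side=%s", name,
                      probeTopology(design), lesionIndex(design),
                      design@labelSide)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write a spectrum as two-column TSV
#'
#' Columns \code{mz} and \code{intensity}; lines starting with \code{#} are
#' comments.
#'
#' @param path input / output file.
#' @param spectrum a \code{\linkS4class{Spectrum}}.
#' @return \code{readSpectrumTSV} returns a \code{\linkS4class{Spectrum}}.
#' @export
readSpectrumTSV <- function(path) {
  d <- read.delim(path, comment.char = "#", header = TRUE)
  if (!all(c("mz", "intensity") %in% names(d)))
    stop("spectrum TSV needs columns 'mz' and 'intensity'", call. = FALSE)
  Spectrum(d$mz, d$intensity, metadata = list(source = path))
}

#' @rdname readSpectrumTSV
#' @export
writeSpectrumTSV <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  .tsvHeader(con, c("bermass spectrum", "mz: m/z", "intensity: arbitrary units"))
  write.table(data.frame(mz = spectrum@mz, intensity = spectrum@intensity),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from TSV or mzML
#'
#' mzML files (first MS1 scan) are read through the optional mzR package.
#'
#' @param path input file; format chosen by extension.
#' @return a \code{\linkS4class{Spectrum}}.
#' @export
readSpectrum <- function(path) {
  ext <- tolower(file_ext(path))
  if (ext == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package", call. = FALSE)
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, 1L)
    return(Spectrum(pk[, 1], pk[, 2], metadata = list(source = path)))
  }
  readSpectrumTSV(path)
}

#' Write a mass ladder as TSV
#'
#' Entry table followed by the in-window charge-state table.
#'
#' @param ladder a \code{\linkS4class{MassLadder}}.
#' @param path output file.
#' @export
writeLadderTSV <- function(ladder, path) {
  stopifnot(is(ladder, "MassLadder"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  .tsvHeader(con, c("bermass mass ladder",
                    "neutral masses in Da; m/z for negative mode, M = (m/z + 1.008) * z",
                    sprintf("window: %g-%g m/z; charge range: %d-%d",
                            ladder@window[1], ladder@window[2],
                            ladder@chargeRange[1], ladder@chargeRange[2])))
  e <- ladderEntries(ladder)
  pk <- ladderPeaks(ladder)
  merged <- merge(e, pk, by = "label", all.x = TRUE, sort = FALSE)
  merged <- merged[order(merged$massMono, merged$z), ]
  write.table(merged, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Write assignments as TSV
#' @param assignments data.frame from \code{\link{assignPeaks}}.
#' @param path output file.
#' @export
writeAssignmentsTSV <- function(assignments, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  .tsvHeader(con, c("bermass peak assignments",
                    "errorDa: (deconvolved neutral mass - ladder mass) in Da"))
  write.table(assignments, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a composition estimate
#'
#' @param estimate a \code{\linkS4class{CompositionEstimate}}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
writeComposition <- function(estimate, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is(estimate, "CompositionEstimate"))
  if (format == "json") {
    jsonlite::write_json(list(
      classes = estimate@labels, heights = estimate@heights,
      proportions = estimate@proportions,
      unrepaired_fraction = estimate@unrepairedFraction),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  .tsvHeader(con, c("bermass composition estimate",
                    "proportions over repair classes on [0,1]; unrepaired excluded from the denominator",
                    sprintf("unrepaired_fraction: %.6g",
                            estimate@unrepairedFraction)))
  write.table(data.frame(class = estimate@labels, height = estimate@heights,
                         proportion = estimate@proportions),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a replicate composition table
#'
#' TSV layout: columns \code{sample}, \code{group}, then one column per
#' class.
#'
#' @param table a \code{\linkS4class{CompositionTable}}.
#' @param path input / output file.
#' @return \code{readCompositionTable} returns a
#'   \code{\linkS4class{CompositionTable}}.
#' @export
writeCompositionTable <- function(table, path) {
  stopifnot(is(table, "CompositionTable"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  .tsvHeader(con, c("bermass replicate composition table",
                    "proportions on [0,1], one row per replicate"))
  d <- data.frame(sample = table@replicate, group = as.character(table@group),
                  proportions(table), check.names = FALSE)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCompositionTable
#' @export
readCompositionTable <- function(path) {
  d <- read.delim(path, comment.char = "#", header = TRUE,
                  check.names = FALSE)
  if (!all(c("sample", "group") %in% names(d)))
    stop("composition table needs 'sample' and 'group' columns",
         call. = FALSE)
  cls <- setdiff(names(d), c("sample", "group"))
  CompositionTable(as.matrix(d[, cls, drop = FALSE]), group = d$group,
                   replicate = d$sample)
}

#' Write a run manifest
#'
#' Records command, configuration snapshot, seed, input/output paths, package
#' version and timestamp so a run can be reproduced.
#'
#' @param path output JSON file.
#' @param command subcommand or function name.
#' @param config configuration list.
#' @param seed integer seed.
#' @param inputs,outputs character vectors of paths.
#' @export
writeRunManifest <- function(path, command, config = list(), seed = NA,
                             inputs = character(), outputs = character()) {
  jsonlite::write_json(list(
    tool = "bermass", version = as.character(packageVersion("bermass")),
    command = command, seed = seed, config = config,
    inputs = inputs, outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
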