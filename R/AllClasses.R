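## Central S4 data containers. Coordinates throughout the package are 1-based
## and intervals are closed, following R/Bioconductor convention; every text
## output states this in its header.

RESIDUE_CODES <- c("A", "C", "G", "T", "U", "AP", "rAP", "F")
LESION_CODES <- c("U", "AP", "rAP", "F")

#' Mass-labeled BER probe design
#'
#' Represents the top strand of a mass-labeled probe substrate: the residue
#' sequence (IUPAC bases plus lesion codes), its topology, the lesion position
#' and kind, the heavy-label positions (fully
#' \eqn{^{13}C,^{15}N}-substituted dAMP/dGMP), and the enzymes used to release
#' and authenticate the analysis fragment.
#'
#' @slot sequence character vector of residue codes, 5' to 3' on the lesion
#'   (top) strand; one of \code{A, C, G, T, U, AP, rAP, F} per position
#'   (\code{AP} abasic site, \code{rAP} its reduced ring-opened form, \code{F}
#'   tetrahydrofuran abasic analog).
#' @slot topology \code{"circular"} or \code{"linear"}.
#' @slot lesionIndex 1-based position of the lesion on the top strand.
#' @slot lesionKind one of \code{U, AP, rAP, F}.
#' @slot oppositeBase base paired with the lesion on the bottom strand
#'   (\code{A}, \code{C} or \code{G}).
#' @slot heavy logical vector parallel to \code{sequence}; \code{TRUE} marks a
#'   heavy residue. Heavy is only permitted for A and G.
#' @slot labelSide \code{"downstream_G"} (patch-size probe) or
#'   \code{"upstream_A"} (5'-excision probe).
#' @slot analysisEnzymes names of the two enzymes releasing the analysis
#'   fragment (may be empty for linear oligo substrates analyzed whole).
#' @slot diagnosticEnzyme name of the enzyme whose recognition site overlaps
#'   the lesion (NA when the design declares none).
#'
#' @seealso \code{\link{makeProbe}}, \code{\link{validateDesign}},
#'   \code{\link{digestProbe}}
#' @export
setClass("ProbeDesign",
  representation(
    sequence = "character",
    topology = "character",
    lesionIndex = "integer",
    lesionKind = "character",
    oppositeBase = "character",
    heavy = "logical",
    labelSide = "character",
    analysisEnzymes = "character",
    diagnosticEnzyme = "character"
  )
)

setValidity("ProbeDesign", function(object) {
  msg <- character()
  n <- length(object@sequence)
  if (n == 0L) msg <- c(msg, "sequence must be non-empty")
  bad <- setdiff(unique(object@sequence), RESIDUE_CODES)
  if (length(bad))
    msg <- c(msg, paste0("unknown residue code(s): ", paste(bad, collapse = ", ")))
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  li <- object@lesionIndex
  if (length(li) != 1L || is.na(li) || li < 1L || li > n)
    msg <- c(msg, "lesionIndex out of range")
  if (!object@lesionKind %in% LESION_CODES)
    msg <- c(msg, "lesionKind must be one of U, AP, rAP, F")
  if (!object@oppositeBase %in% c("A", "C", "G"))
    msg <- c(msg, "oppositeBase must be A, C or G")
  if (length(object@heavy) != n)
    msg <- c(msg, "heavy must be parallel to sequence")
  hv <- which(object@heavy)
  if (length(li) == 1L && !is.na(li) && li >= 1L && li <= n) {
    if (object@sequence[li] != object@lesionKind)
      msg <- c(msg, "sequence at lesionIndex must equal lesionKind")
    if (li %in% hv)
      msg <- c(msg, "lesion position cannot be heavy-labeled")
  }
  if (length(hv) && !all(object@sequence[hv] %in% c("A", "G")))
    msg <- c(msg, "heavy labels are only permitted on A and G residues")
  if (!object@labelSide %in% c("downstream_G", "upstream_A"))
    msg <- c(msg, "labelSide must be 'downstream_G' or 'upstream_A'")
  if (length(hv)) {
    want <- if (object@labelSide == "downstream_G") "G" else "A"
    if (!all(object@sequence[hv] == want))
      msg <- c(msg, sprintf("labelSide %s requires all heavy residues to be %s",
                            object@labelSide, want))
  }
  if (!length(object@analysisEnzymes) %in% c(0L, 2L))
    msg <- c(msg, "analysisEnzymes must name exactly two enzymes (or none)")
  if (length(object@diagnosticEnzyme) != 1L)
    msg <- c(msg, "diagnosticEnzyme must be a single name or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a ProbeDesign
#'
#' @param sequence character vector of residue codes (or a single string of
#'   one-letter codes when no multi-letter lesion code is needed).
#' @param topology \code{"circular"} or \code{"linear"}.
#' @param lesionIndex 1-based lesion position.
#' @param lesionKind lesion residue code (\code{U}, \code{AP}, \code{rAP},
#'   \code{F}); defaults to the residue found at \code{lesionIndex}.
#' @param oppositeBase base opposite the lesion (default \code{"A"}).
#' @param labelIndices 1-based positions carrying heavy residues.
#' @param labelSide \code{"downstream_G"} or \code{"upstream_A"}.
#' @param analysisEnzymes character vector of length 2 (or empty).
#' @param diagnosticEnzyme single enzyme name or \code{NA}.
#' @return A \code{\linkS4class{ProbeDesign}} object.
#' @examples
#' pd <- ProbeDesign("ACGCATAUGGGCT", topology = "linear", lesionIndex = 8,
#'                   labelIndices = c(9, 10, 11), labelSide = "downstream_G")
#' lesionIndex(pd)
#' @export
ProbeDesign <- function(sequence, topology = c("circular", "linear"),
                        lesionIndex, lesionKind = NULL, oppositeBase = "A",
                        labelIndices = integer(), labelSide = "downstream_G",
                        analysisEnzymes = character(),
                        diagnosticEnzyme = NA_character_) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1]]
  topology <- match.arg(topology)
  lesionIndex <- as.integer(lesionIndex)
  if (is.null(lesionKind)) lesionKind <- sequence[lesionIndex]
  heavy <- rep(FALSE, length(sequence))
  heavy[as.integer(labelIndices)] <- TRUE
  new("ProbeDesign", sequence = sequence, topology = topology,
      lesionIndex = lesionIndex, lesionKind = lesionKind,
      oppositeBase = oppositeBase, heavy = heavy, labelSide = labelSide,
      analysisEnzymes = as.character(analysisEnzymes),
      diagnosticEnzyme = as.character(diagnosticEnzyme))
}

#' Theoretical mass ladder of repair outcomes
#'
#' Holds one entry per distinguishable repair outcome class (plus the
#' unrepaired substrate), with neutral masses and the charge-state m/z values
#' that fall inside the instrument window.
#'
#' @slot entries data.frame with columns \code{label}, \code{state}
#'   (\code{"repaired"}/\code{"unrepaired"}), \code{j} (5'-excision length),
#'   \code{k} (patch length; NA where marginalized), \code{heavyRemoved},
#'   \code{massMono}, \code{massAvg} (Da).
#' @slot peaks data.frame with columns \code{label}, \code{z}, \code{mz};
#'   only m/z values inside \code{window}.
#' @slot window numeric length-2 m/z acquisition window.
#' @slot chargeRange integer length-2 (negative-mode charge magnitudes).
#' @slot matchOn which mass drives m/z positions and matching:
#'   \code{"average"} or \code{"monoisotopic"}.
#' @seealso \code{\link{buildLadder}}
#' @export
setClass("MassLadder",
  representation(entries = "data.frame", peaks = "data.frame",
                 window = "numeric", chargeRange = "integer",
                 matchOn = "character")
)

setValidity("MassLadder", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("label", "state", "j", "k", "heavyRemoved", "massMono", "massAvg")
  if (!all(need %in% names(e))) msg <- c(msg, "entries missing required columns")
  if (anyDuplicated(e$label)) msg <- c(msg, "class labels must be unique")
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be an increasing length-2 numeric")
  if (nrow(object@peaks) &&
      (any(object@peaks$mz < object@window[1] - 1e-9) ||
       any(object@peaks$mz > object@window[2] + 1e-9)))
    msg <- c(msg, "all ladder m/z values must lie inside the window")
  if (!object@matchOn %in% c("average", "monoisotopic"))
    msg <- c(msg, "matchOn must be 'average' or 'monoisotopic'")
  if (length(msg)) msg else TRUE
})

#' Raw m/z-intensity trace
#'
#' @slot mz strictly ascending m/z grid.
#' @slot intensity nonnegative intensities, same length as \code{mz}.
#' @slot metadata list (source, window, averaged-scan count, simulation truth
#'   when synthetic).
#' @seealso \code{\link{simulateSpectrum}}, \code{\link{readSpectrumTSV}}
#' @export
setClass("Spectrum",
  representation(mz = "numeric", intensity = "numeric", metadata = "list")
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz) && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly ascending")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#' @param mz ascending m/z values.
#' @param intensity nonnegative intensities.
#' @param metadata optional list of provenance fields.
#' @return A \code{\linkS4class{Spectrum}}.
#' @export
Spectrum <- function(mz, intensity, metadata = list()) {
  new("Spectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      metadata = metadata)
}

#' Centroided peak list
#'
#' @slot peaks data.frame with columns \code{mz} (centroid), \code{height}
#'   (apex height after parabolic interpolation), \code{snr} (height over the
#'   MAD noise floor) and \code{area} (trapezoidal area over the local peak
#'   support; reported but unused by default quantification).
#' @seealso \code{\link{pickPeaks}}
#' @export
setClass("PeakList", representation(peaks = "data.frame"))

setValidity("PeakList", function(object) {
  p <- object@peaks
  msg <- character()
  if (!all(c("mz", "height", "snr", "area") %in% names(p)))
    msg <- c(msg, "peaks must have columns mz, height, snr, area")
  if (nrow(p)) {
    if (is.unsorted(p$mz, strictly = TRUE))
      msg <- c(msg, "peak centroids must be strictly ascending")
    if (any(p$height <= 0)) msg <- c(msg, "peak heights must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Per-class composition estimate
#'
#' The assay readout: summed apex heights and proportions per repair class.
#' Proportions are taken over repair classes only; the unrepaired substrate is
#' excluded from the denominator and reported as a separate fraction of total
#' assigned signal.
#'
#' @slot labels repair class labels, ladder order.
#' @slot heights summed apex heights per class (all charge states).
#' @slot proportions per-class proportions, summing to 1.
#' @slot unrepairedFraction fraction of total assigned height carried by the
#'   unrepaired substrate.
#' @slot assignments data.frame of the peak assignments behind the estimate.
#' @seealso \code{\link{quantifyComposition}}
#' @export
setClass("CompositionEstimate",
  representation(labels = "character", heights = "numeric",
                 proportions = "numeric", unrepairedFraction = "numeric",
                 assignments = "data.frame")
)

setValidity("CompositionEstimate", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (length(object@heights) != n || length(object@proportions) != n)
    msg <- c(msg, "labels, heights and proportions must be parallel")
  if (any(object@proportions < 0))
    msg <- c(msg, "proportions must be nonnegative")
  if (n && abs(sum(object@proportions) - 1) > 1e-9)
    msg <- c(msg, "proportions must sum to 1")
  if (length(object@unrepairedFraction) != 1L ||
      object@unrepairedFraction < 0 || object@unrepairedFraction > 1)
    msg <- c(msg, "unrepairedFraction must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Replicate composition table
#'
#' @slot proportions n samples x D classes matrix of proportions (rows on the
#'   simplex after \code{\link{closeComposition}}).
#' @slot group factor with one level per experimental group.
#' @slot replicate character replicate identifiers.
#' @seealso \code{\link{simulateReplicates}}, \code{\link{fitDirichlet}}
#' @export
setClass("CompositionTable",
  representation(proportions = "matrix", group = "factor",
                 replicate = "character")
)

setValidity("CompositionTable", function(object) {
  msg <- character()
  n <- nrow(object@proportions)
  if (is.null(colnames(object@proportions)))
    msg <- c(msg, "proportions must have class labels as column names")
  if (length(object@group) != n)
    msg <- c(msg, "group must have one entry per row")
  if (length(object@replicate) != n)
    msg <- c(msg, "replicate must have one entry per row")
  if (any(object@proportions < 0))
    msg <- c(msg, "proportions must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a CompositionTable
#' @param proportions numeric matrix (samples x classes) with column names.
#' @param group factor or character of group membership, one per row.
#' @param replicate optional replicate ids (default \code{"r1"}, ...).
#' @return A \code{\linkS4class{CompositionTable}}.
#' @export
CompositionTable <- function(proportions, group,
                             replicate = paste0("r", seq_len(nrow(proportions)))) {
  new("CompositionTable", proportions = as.matrix(proportions),
      group = as.factor(group), replicate = as.character(replicate))
}

## ---- accessors -------------------------------------------------------------

#' @describeIn ProbeDesign residue codes of the top strand
#' @param object,x a \code{ProbeDesign}
#' @export
setGeneric("probeSequence", function(object) standardGeneric("probeSequence"))
#' @export
setMethod("probeSequence", "ProbeDesign", function(object) object@sequence)

#' @describeIn ProbeDesign 1-based lesion position
#' @export
setGeneric("lesionIndex", function(object) standardGeneric("lesionIndex"))
#' @export
setMethod("lesionIndex", "ProbeDesign", function(object) object@lesionIndex)

#' @describeIn ProbeDesign 1-based heavy-label positions
#' @export
setGeneric("labelIndices", function(object) standardGeneric("labelIndices"))
#' @export
setMethod("labelIndices", "ProbeDesign", function(object) which(object@heavy))

#' @describeIn ProbeDesign probe topology
#' @export
setGeneric("probeTopology", function(object) standardGeneric("probeTopology"))
#' @export
setMethod("probeTopology", "ProbeDesign", function(object) object@topology)

#' @describeIn MassLadder entry table (one row per class)
#' @param object a \code{MassLadder}
#' @export
setGeneric("ladderEntries", function(object) standardGeneric("ladderEntries"))
#' @export
setMethod("ladderEntries", "MassLadder", function(object) object@entries)

#' @describeIn MassLadder in-window charge-state m/z table
#' @export
setGeneric("ladderPeaks", function(object) standardGeneric("ladderPeaks"))
#' @export
setMethod("ladderPeaks", "MassLadder", function(object) object@peaks)

#' @describeIn PeakList centroid table
#' @param object a \code{PeakList}
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))
#' @export
setMethod("peakTable", "PeakList", function(object) object@peaks)

#' @describeIn CompositionEstimate named per-class proportions
#' @param object a \code{CompositionEstimate} or \code{CompositionTable}
#' @export
setGeneric("proportions", function(object) standardGeneric("proportions"))
#' @export
setMethod("proportions", "CompositionEstimate", function(object)
  setNames(object@proportions, object@labels))
#' @export
setMethod("proportions", "CompositionTable", function(object) object@proportions)

#' @describeIn CompositionEstimate unrepaired-substrate fraction
#' @export
setGeneric("unrepairedFraction",
           function(object) standardGeneric("unrepairedFraction"))
#' @export
setMethod("unrepairedFraction", "CompositionEstimate",
          function(object) object@unrepairedFraction)

#' @describeIn CompositionTable group factor
#' @param object a \code{CompositionTable}
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))
#' @export
setMethod("sampleGroups", "CompositionTable", function(object) object@group)

## ---- show methods ----------------------------------------------------------

setMethod("show", "ProbeDesign", function(object) {
  cat(sprintf("ProbeDesign: %d-nt %s top strand\n", length(object@sequence),
              object@topology))
  cat(sprintf("  lesion %s:%s at position %d; %d heavy %s label(s) (%s)\n",
              object@lesionKind, object@oppositeBase, object@lesionIndex,
              sum(object@heavy),
              if (object@labelSide == "downstream_G") "dGMP" else "dAMP",
              object@labelSide))
  if (length(object@analysisEnzymes))
    cat("  analysis enzymes:", paste(object@analysisEnzymes, collapse = " + "),
        "\n")
  if (!is.na(object@diagnosticEnzyme))
    cat("  diagnostic enzyme:", object@diagnosticEnzyme, "\n")
})

setMethod("show", "MassLadder", function(object) {
  cat(sprintf("MassLadder: %d classes, window %g-%g m/z, z %d-%d (%s mass)\n",
              nrow(object@entries), object@window[1], object@window[2],
              object@chargeRange[1], object@chargeRange[2], object@matchOn))
  print(object@entries, row.names = FALSE)
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.1f-%.1f m/z\n", length(object@mz),
              min(object@mz), max(object@mz)))
  if (!is.null(object@metadata$scans))
    cat("  averaged scans:", object@metadata$scans, "\n")
})

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList: %d peaks\n", nrow(object@peaks)))
  if (nrow(object@peaks)) print(utils::head(object@peaks, 10), row.names = FALSE)
})

setMethod("show", "CompositionEstimate", function(object) {
  cat("CompositionEstimate (proportions over repair classes):\n")
  print(round(setNames(object@proportions, object@labels), 4))
  cat(sprintf("  unrepaired fraction: %.4f\n", object@unrepairedFraction))
})

setMethod("show", "CompositionTable", function(object) {
  cat(sprintf("CompositionTable: %d samples x %d classes, groups: %s\n",
              nrow(object@proportions), ncol(object@proportions),
              paste(levels(object@group), collapse = ", ")))
})
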