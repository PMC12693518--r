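## Probe model: lesion-aware recognition-site scanning, in silico digestion,
## the UDG/APE1/endonuclease diagnostic logic, and design validation.
##
## Scanning rules: U is read as T (restriction enzymes cleave U-containing
## DNA); the abasic codes AP, rAP and F match no IUPAC letter, so a site
## overlapping them is blocked. These two rules reproduce the assay's
## diagnostic behavior (uracil removal abolishes cleavage at a site that
## contains the lesion; repair restores it).

#' @keywords internal
.residuesOf <- function(x) {
  if (is(x, "ProbeDesign")) probeSequence(x)
  else if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1]]
  else as.character(x)
}

#' @keywords internal
.wrap1 <- function(i, L) ((i - 1L) %% L) + 1L

## Vectorized pattern scan over all candidate starts, honoring U==T and
## lesion blocking; circular sequences wrap. Returns 1-based start positions.
#' @keywords internal
.scanPattern <- function(seqv, pat, circular) {
  m <- length(pat)
  L <- length(seqv)
  if (L < m && !circular) return(integer())
  ext <- seqv
  ext[ext == "U"] <- "T"
  ext[!ext %in% c("A", "C", "G", "T")] <- "X"   # abasic blocks any site
  if (circular) ext <- c(ext, ext[seq_len(min(m - 1L, L))])
  starts <- if (circular) seq_len(L) else seq_len(L - m + 1L)
  ok <- rep(TRUE, length(starts))
  for (i in seq_len(m)) {
    allowed <- .IUPAC[[pat[i]]]
    ok <- ok & ext[starts + i - 1L] %in% allowed
    if (!any(ok)) return(integer())
  }
  starts[ok]
}

#' Find recognition sites of an enzyme
#'
#' Scans the top strand for the enzyme's IUPAC-degenerate recognition string
#' in both orientations. U is treated as T; sites overlapping an abasic
#' residue (AP/rAP/F) are not reported. Circular scans include
#' origin-spanning matches (coordinates wrap).
#'
#' @param x a \code{\linkS4class{ProbeDesign}}, a character vector of residue
#'   codes, or a single sequence string.
#' @param enzyme enzyme name (looked up in \code{table}) or a list row from
#'   \code{\link{loadEnzymeTable}}.
#' @param topology \code{"circular"} or \code{"linear"}; taken from \code{x}
#'   when it is a ProbeDesign.
#' @param table enzyme table (default shipped table).
#' @return data.frame with columns \code{start} (1-based top-strand
#'   coordinate of the site's first position), \code{strand} (\code{"+"} if
#'   the recognition string reads on the top strand, \code{"-"} otherwise),
#'   \code{cutTop}, \code{cutBottom} (top-strand coordinate of the residue
#'   immediately 5' of each strand's cut; NA for the uncut strand of a
#'   nicking enzyme), sorted by \code{start}.
#' @examples
#' findSites("GGCATATGCC", "NdeI", topology = "linear")
#' @export
findSites <- function(x, enzyme, topology = NULL, table = loadEnzymeTable()) {
  seqv <- .residuesOf(x)
  if (!length(seqv)) stop("empty sequence (input error)", call. = FALSE)
  if (is(x, "ProbeDesign")) topology <- probeTopology(x)
  if (is.null(topology)) topology <- "linear"
  circular <- topology == "circular"
  if (is.character(enzyme)) enzyme <- .getEnzyme(enzyme, table)
  pat <- strsplit(enzyme$recognition, "", fixed = TRUE)[[1]]
  m <- length(pat)
  L <- length(seqv)
  patRC <- strsplit(.revcompIUPAC(enzyme$recognition), "", fixed = TRUE)[[1]]
  plus <- .scanPattern(seqv, pat, circular)
  minus <- setdiff(.scanPattern(seqv, patRC, circular), plus)
  # (palindromic sites reported once, on the plus strand)
  ot <- enzyme$cut_offset_top
  ob <- enzyme$cut_offset_bottom
  cut1 <- function(s, off) {
    if (is.na(off)) rep(NA_integer_, length(s))
    else if (circular) .wrap1(s + off - 1L, L) else s + off - 1L
  }
  res <- rbind(
    if (length(plus)) data.frame(start = plus, strand = "+",
                                 cutTop = cut1(plus, ot),
                                 cutBottom = cut1(plus, ob)),
    if (length(minus)) data.frame(start = minus, strand = "-",
                                  cutTop = cut1(minus, m - ob),
                                  cutBottom = cut1(minus, m - ot))
  )
  if (is.null(res))
    res <- data.frame(start = integer(), strand = character(),
                      cutTop = integer(), cutBottom = integer())
  res[order(res$start), , drop = FALSE]
}

#' In silico restriction digest
#'
#' Cuts the probe with one or more double-strand cutters and returns the
#' resulting fragment intervals per strand. Restriction cuts leave
#' 5'-phosphate / 3'-hydroxyl chemistry; the original ends of a linear
#' molecule are taken as 5'-hydroxyl / 3'-hydroxyl (synthetic oligo ends).
#' Fragment lengths sum exactly to the input length on each strand.
#'
#' @param design a \code{\linkS4class{ProbeDesign}}.
#' @param enzymes character vector of enzyme names.
#' @param strand \code{"top"} (default; the lesion strand analyzed by MS) or
#'   \code{"both"}.
#' @param table enzyme table.
#' @return data.frame with columns \code{start}, \code{end} (1-based closed,
#'   top-strand coordinates; \code{start > end} denotes an origin-wrapping
#'   fragment on a circular molecule), \code{length}, \code{strand},
#'   \code{fivePrime}, \code{threePrime}. A circular molecule with zero cuts
#'   is returned as one full-length "uncut" circular row.
#' @examples
#' ## a circular single-cut plasmid linearizes into one full-length fragment
#' @export
digestProbe <- function(design, enzymes, strand = c("top", "both"),
                        table = loadEnzymeTable()) {
  strand <- match.arg(strand)
  stopifnot(is(design, "ProbeDesign"))
  L <- length(probeSequence(design))
  circular <- probeTopology(design) == "circular"
  cutsTop <- integer(); cutsBottom <- integer()
  for (nm in enzymes) {
    e <- .getEnzyme(nm, table)
    if (e$nicking != "none")
      stop("nicking enzyme ", nm, " is not supported by digestProbe ",
           "(unsupported operation)", call. = FALSE)
    s <- findSites(design, e)
    cutsTop <- c(cutsTop, s$cutTop)
    cutsBottom <- c(cutsBottom, s$cutBottom)
  }
  frag1 <- function(cuts, strandName) {
    cuts <- sort(unique(cuts))
    if (!length(cuts)) {
      if (circular)
        return(data.frame(start = 1L, end = L, length = L, strand = strandName,
                          fivePrime = "circular", threePrime = "circular"))
      return(data.frame(start = 1L, end = L, length = L, strand = strandName,
                        fivePrime = "hydroxyl", threePrime = "hydroxyl"))
    }
    if (circular) {
      k <- length(cuts)
      start <- .wrap1(cuts + 1L, L)
      end <- c(cuts[-1L], cuts[1L])
      len <- (end - start) %% L + 1L
      data.frame(start = start, end = end, length = len, strand = strandName,
                 fivePrime = "phosphate", threePrime = "hydroxyl")
    } else {
      bounds <- c(0L, cuts[cuts < L], L)
      start <- bounds[-length(bounds)] + 1L
      end <- bounds[-1L]
      data.frame(start = start, end = end, length = end - start + 1L,
                 strand = strandName,
                 fivePrime = c("hydroxyl", rep("phosphate", length(start) - 1L)),
                 threePrime = c(rep("hydroxyl", length(start))))
    }
  }
  out <- frag1(cutsTop, "top")
  if (strand == "both") out <- rbind(out, frag1(cutsBottom, "bottom"))
  rownames(out) <- NULL
  out
}

#' @keywords internal
.fragmentPositions <- function(start, length, L) .wrap1(start + seq_len(length) - 1L, L)

#' Extract the analysis fragment of a probe
#'
#' Digests with the design's analysis enzymes and returns the top-strand
#' fragment containing the lesion, i.e. the segment whose neutral mass the
#' assay measures. For a linear design with no analysis enzymes the whole
#' strand is returned.
#'
#' @param design a \code{\linkS4class{ProbeDesign}}.
#' @param table enzyme table.
#' @return list with \code{interval} (one row of \code{\link{digestProbe}}
#'   output), \code{positions} (top-strand coordinates of the fragment
#'   residues, 5' to 3'), \code{residues}, \code{heavy}, \code{lesionOffset}
#'   (1-based position of the lesion within the fragment) and \code{fivePrime}
#'   end chemistry.
#' @export
analysisFragment <- function(design, table = loadEnzymeTable()) {
  L <- length(probeSequence(design))
  if (!length(design@analysisEnzymes)) {
    pos <- seq_len(L)
    interval <- data.frame(start = 1L, end = L, length = L, strand = "top",
                           fivePrime = "hydroxyl", threePrime = "hydroxyl")
  } else {
    fr <- digestProbe(design, design@analysisEnzymes, strand = "top",
                      table = table)
    li <- lesionIndex(design)
    hit <- NA_integer_
    for (i in seq_len(nrow(fr))) {
      pos_i <- .fragmentPositions(fr$start[i], fr$length[i], L)
      if (li %in% pos_i) { hit <- i; pos <- pos_i; break }
    }
    if (is.na(hit))
      stop("no digest fragment contains the lesion", call. = FALSE)
    interval <- fr[hit, , drop = FALSE]
  }
  list(interval = interval, positions = pos,
       residues = probeSequence(design)[pos], heavy = design@heavy[pos],
       lesionOffset = match(lesionIndex(design), pos),
       fivePrime = interval$fivePrime)
}

#' @keywords internal
.lesionResult <- function(design) {
  ## repaired base restores Watson-Crick pairing with the opposite base
  c(A = "T", G = "C", C = "G")[[design@oppositeBase]]
}

#' Simulate the diagnostic digest
#'
#' Applies an ordered series of treatments to the probe and reports, for each
#' endonuclease in the series, whether its site overlapping the current
#' lesion state is cleavable. UDG converts every U to an AP site; APE1
#' incises 5' of each AP/rAP/F residue (leaving a nick). A recognition site
#' containing an abasic residue, or with a nick between two of its residues,
#' is uncleavable; the repaired state (lesion replaced by the normal base) is
#' cleavable.
#'
#' @param design a \code{\linkS4class{ProbeDesign}}.
#' @param treatments character vector drawn from \code{"UDG"}, \code{"APE1"}
#'   and enzyme names, applied in order.
#' @param state \code{"unrepaired"} (default) or \code{"repaired"} (lesion
#'   replaced by the repaired base before treatments).
#' @param table enzyme table.
#' @return data.frame with one row per endonuclease treatment: \code{token},
#'   \code{verdict} (\code{"cut"}/\code{"uncut"}), \code{nSites} (cleavable
#'   sites at that step).
#' @examples
#' ## a U-containing site is cut directly but not after UDG (U -> AP)
#' @export
simulateDiagnostic <- function(design, treatments,
                               state = c("unrepaired", "repaired"),
                               table = loadEnzymeTable()) {
  state <- match.arg(state)
  stopifnot(is(design, "ProbeDesign"))
  seqv <- probeSequence(design)
  L <- length(seqv)
  circular <- probeTopology(design) == "circular"
  if (state == "repaired") seqv[lesionIndex(design)] <- .lesionResult(design)
  nicks <- integer()  # nick after top-strand position p
  out <- list()
  for (tok in treatments) {
    if (identical(tok, "UDG")) {
      seqv[seqv == "U"] <- "AP"
    } else if (identical(tok, "APE1")) {
      ab <- which(seqv %in% c("AP", "rAP", "F"))
      nicks <- sort(unique(c(nicks, .wrap1(ab - 1L, L))))
    } else if (tok %in% table$name) {
      sites <- findSites(seqv, tok,
                         topology = if (circular) "circular" else "linear",
                         table = table)
      ok <- logical(nrow(sites))
      m <- nchar(.getEnzyme(tok, table)$recognition)
      if (nrow(sites)) for (i in seq_len(nrow(sites))) {
        span <- .wrap1(sites$start[i] + seq_len(m - 1L) - 1L, L)
        ok[i] <- !any(nicks %in% span)  # nick strictly inside the site blocks
      }
      out[[length(out) + 1L]] <- data.frame(
        token = tok, verdict = if (any(ok)) "cut" else "uncut",
        nSites = sum(ok))
    } else {
      stop("unknown treatment token: ", tok, " (configuration error)",
           call. = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(token = character(), verdict = character(),
                      nSites = integer()))
  do.call(rbind, out)
}

#' Validate a probe design
#'
#' Runs the named design checks and reports each individually; failures are
#' report rows, not errors.
#' \enumerate{
#'   \item exactly one Nt.BspQI and one Nb.BbvCI site (circular designs; the
#'     oligo-swap construction requires unique nicking sites),
#'   \item the lesion lies inside a recognition site of the diagnostic
#'     enzyme (scanning with U read as T),
#'   \item each analysis enzyme cuts exactly once, and the released fragment
#'     contains the lesion,
#'   \item all heavy-label positions lie inside the analysis fragment,
#'   \item the label scheme yields a collision-free mass ladder
#'     (\code{\link{collisionCheck}} at \code{minSeparation} Da).
#' }
#'
#' @param design a \code{\linkS4class{ProbeDesign}}.
#' @param minSeparation neutral-mass separation (Da) required between ladder
#'   classes (default 5).
#' @param table enzyme table.
#' @return data.frame with columns \code{check}, \code{pass}, \code{note}.
#' @examples
#' pd <- makeProbe(simulationConfig(seed = 1))
#' validateDesign(pd)
#' @export
validateDesign <- function(design, minSeparation = 5,
                           table = loadEnzymeTable()) {
  checks <- list()
  add <- function(check, pass, note = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 note = note)
  }
  circular <- probeTopology(design) == "circular"

  ## (1) unique nicking sites
  if (circular) {
    nt <- nrow(findSites(design, "Nt.BspQI", table = table))
    nb <- nrow(findSites(design, "Nb.BbvCI", table = table))
    add("unique_nicking_sites", nt == 1L && nb == 1L,
        sprintf("Nt.BspQI: %d site(s), Nb.BbvCI: %d site(s)", nt, nb))
  } else {
    add("unique_nicking_sites", TRUE, "not applicable (linear design)")
  }

  ## (2) lesion inside diagnostic-enzyme site
  if (is.na(design@diagnosticEnzyme)) {
    add("lesion_in_diagnostic_site", TRUE,
        "not applicable (no diagnostic enzyme declared)")
  } else {
    s <- findSites(design, design@diagnosticEnzyme, table = table)
    m <- nchar(.getEnzyme(design@diagnosticEnzyme, table)$recognition)
    L <- length(probeSequence(design))
    inside <- FALSE
    if (nrow(s)) for (i in seq_len(nrow(s)))
      if (lesionIndex(design) %in% .wrap1(s$start[i] + seq_len(m) - 1L, L))
        inside <- TRUE
    add("lesion_in_diagnostic_site", inside,
        sprintf("%s sites: %d", design@diagnosticEnzyme, nrow(s)))
  }

  ## (3) analysis enzymes single-cut, fragment contains lesion
  if (!length(design@analysisEnzymes)) {
    add("analysis_enzymes_single_cut", TRUE,
        "not applicable (whole strand analyzed)")
    frag <- analysisFragment(design, table = table)
  } else {
    counts <- vapply(design@analysisEnzymes, function(nm)
      nrow(findSites(design, nm, table = table)), integer(1))
    frag <- tryCatch(analysisFragment(design, table = table),
                     error = function(e) NULL)
    ok <- all(counts == 1L) && !is.null(frag)
    add("analysis_enzymes_single_cut", ok,
        paste(sprintf("%s: %d cut(s)", design@analysisEnzymes, counts),
              collapse = "; "))
  }

  ## (4) labels inside the analysis fragment
  if (is.null(frag)) {
    add("labels_in_analysis_fragment", FALSE, "no analysis fragment")
    add("collision_free_ladder", FALSE, "no analysis fragment")
  } else {
    ok4 <- all(labelIndices(design) %in% frag$positions)
    add("labels_in_analysis_fragment", ok4,
        sprintf("%d/%d labels inside the %d-nt fragment",
                sum(labelIndices(design) %in% frag$positions),
                length(labelIndices(design)), frag$interval$length))

    ## (5) collision-free ladder
    res <- tryCatch({
      lad <- buildLadder(enumerateOutcomes(design), design)
      coll <- collisionCheck(lad, minSeparation = minSeparation)
      list(ok = nrow(coll) == 0L,
           note = sprintf("%d ambiguous pair(s) at %.1f Da separation",
                          nrow(coll), minSeparation))
    }, error = function(e) list(ok = FALSE, note = conditionMessage(e)))
    add("collision_free_ladder", res$ok, res$note)
  }

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
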