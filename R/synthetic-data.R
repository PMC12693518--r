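## Synthetic data: compliant probe sequences, simulated ESI negative-mode
## spectra of product mixtures, and replicate composition tables. Everything
## is deterministic per seed; each simulated object carries its configuration
## in metadata so a run can be reproduced exactly.

#' @keywords internal
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  force(expr)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' assay's standard conditions: a circular plasmid probe, a ~6 kDa analysis
#' fragment observed at charge states 4-8 (discrete Gaussian envelope
#' centered at z = 6, chosen so the fragment's peaks fall inside the
#' 900-1800 m/z acquisition window), envelope-collapsed Gaussian peaks of
#' 0.02 m/z sigma, and three replicates per condition.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param labelSide \code{"downstream_G"} (patch-size probe, 6 heavy dGMPs
#'   immediately 3' of the lesion) or \code{"upstream_A"} (5'-excision probe,
#'   4 heavy dAMPs immediately 5' of the lesion).
#' @param lesionKind \code{"U"} (default), \code{"AP"}, \code{"rAP"} or
#'   \code{"F"}.
#' @param oppositeBase base opposite the lesion (default \code{"A"}).
#' @param mode \code{"plasmid"} (circular, default) or \code{"linear"}
#'   (52-mer duplex with the lesion at position 26).
#' @param plasmidLength total plasmid length in nt (default 2000).
#' @param truth named ground-truth repair composition (class label ->
#'   proportion); default \code{scenarioComposition("hss_ua")} for
#'   downstream-G probes and \code{scenarioComposition("hss_excision_ua")}
#'   for upstream-A probes.
#' @param unrepairedFraction fraction of total signal carried by the intact
#'   unrepaired substrate (default 0.1).
#' @param chargeRange,chargeCenter,chargeSpread discrete Gaussian charge
#'   envelope over \code{chargeRange} (default 4-8, centered at 6, sd 1).
#' @param window m/z acquisition window (default 900-1800).
#' @param peakSigma Gaussian peak width (sigma) in m/z; default 0.02
#'   (FWHM ~0.05, i.e. resolving power ~2e4 at m/z 1000, typical for a
#'   QTOF; wide enough to collapse the isotope envelope at this sampling,
#'   narrow enough to resolve the ~0.15 m/z gap between the unrepaired
#'   substrate and the 2-nt product at z = 6).
#' @param gridStep m/z grid spacing (default 0.005).
#' @param peakHeight height scale of the strongest possible peak (default
#'   1000, arbitrary intensity units).
#' @param baseline constant baseline intensity (default 1).
#' @param noiseSd additive Gaussian noise sd (default 2).
#' @param nReplicates replicate spectra per condition (default 3).
#' @param precision Dirichlet precision of replicate-to-replicate composition
#'   scatter (default 200; sd of a 50\% component about 3.5 points).
#' @return list of class \code{"simConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             labelSide = c("downstream_G", "upstream_A"),
                             lesionKind = "U", oppositeBase = "A",
                             mode = c("plasmid", "linear"),
                             plasmidLength = 2000L, truth = NULL,
                             unrepairedFraction = 0.1,
                             chargeRange = c(4L, 8L), chargeCenter = 6,
                             chargeSpread = 1, window = c(900, 1800),
                             peakSigma = 0.02, gridStep = 0.005,
                             peakHeight = 1000, baseline = 1, noiseSd = 2,
                             nReplicates = 3L, precision = 200) {
  labelSide <- match.arg(labelSide)
  mode <- match.arg(mode)
  if (is.null(truth))
    truth <- scenarioComposition(
      if (labelSide == "downstream_G") "hss_ua" else "hss_excision_ua")
  if (any(truth < 0) || abs(sum(truth) - 1) > 1e-9)
    stop("truth must be a composition on the simplex", call. = FALSE)
  if (unrepairedFraction < 0 || unrepairedFraction >= 1)
    stop("unrepairedFraction must lie in [0, 1)", call. = FALSE)
  stopifnot(peakSigma > 0, gridStep > 0, peakHeight > 0, noiseSd >= 0,
            precision > 0, chargeSpread > 0)
  structure(list(seed = as.integer(seed), labelSide = labelSide,
                 lesionKind = lesionKind, oppositeBase = oppositeBase,
                 mode = mode, plasmidLength = as.integer(plasmidLength),
                 truth = truth, unrepairedFraction = unrepairedFraction,
                 chargeRange = as.integer(chargeRange),
                 chargeCenter = chargeCenter, chargeSpread = chargeSpread,
                 window = window, peakSigma = peakSigma, gridStep = gridStep,
                 peakHeight = peakHeight, baseline = baseline,
                 noiseSd = noiseSd, nReplicates = as.integer(nReplicates),
                 precision = precision),
            class = "simConfig")
}

#' Built-in ground-truth compositions
#'
#' Named repair-product compositions emulating the experimental groups the
#' assay was developed on (frog egg extract with and without added DNA
#' polymerase beta, pre-incised substrates, human whole-cell extract at
#' increased concentration, and the 5'-excision distribution). Used as
#' simulation ground truths for end-to-end validation.
#'
#' @param name one of \code{"hss_ua"} (unsupplemented egg extract, U:A
#'   substrate: 20\% 1-nt / 80\% 2-nt), \code{"hss_polb50"} (extract + 50 nM
#'   Pol beta: 75\% 1-nt / 25\% 2-nt), \code{"relaxed_udg_ape1"} (relaxed
#'   plasmid pre-treated with UDG + AP endonuclease: 60\% 1-nt / 40\% 2-nt),
#'   \code{"wce_6x"} (human whole-cell extract at six-fold concentration:
#'   35\% 1-nt, 25\% 2-nt, remainder across longer patches), or
#'   \code{"hss_excision_ua"} (5'-excision classes on the upstream-A probe:
#'   15\% none, 40\% 1-nt, 40\% 2-nt, 5\% longer).
#' @return named numeric composition over repair class labels.
#' @examples
#' scenarioComposition("hss_ua")
#' @export
scenarioComposition <- function(name = c("hss_ua", "hss_polb50",
                                         "relaxed_udg_ape1", "wce_6x",
                                         "hss_excision_ua")) {
  name <- match.arg(name)
  switch(name,
    hss_ua = c("1-nt" = 0.20, "2-nt" = 0.80),
    hss_polb50 = c("1-nt" = 0.75, "2-nt" = 0.25),
    relaxed_udg_ape1 = c("1-nt" = 0.60, "2-nt" = 0.40),
    wce_6x = c("1-nt" = 0.35, "2-nt" = 0.25, "3-nt" = 0.15, "4-nt" = 0.05,
               "5-nt" = 0.04, "6-nt" = 0.04, "\u22657-nt" = 0.12),
    hss_excision_ua = c("0-nt" = 0.15, "1-nt" = 0.40, "2-nt" = 0.40,
                        "3-nt" = 0.04, "\u22654-nt" = 0.01))
}

#' @keywords internal
.randSeq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' @keywords internal
.siteCount <- function(seqv, enzymes, topology) {
  vapply(enzymes, function(nm)
    nrow(findSites(seqv, nm, topology = topology)), integer(1))
}

#' Generate a compliant probe design
#'
#' Builds a probe satisfying the assay's design constraints, deterministic
#' per seed. Plasmid mode embeds a single Nt.BspQI and Nb.BbvCI site (the
#' oligo-swap construction), a cassette around the lesion and random filler;
#' extra occurrences of the constrained sites in the filler are mutated away
#' (bounded retries). The patch-size probe carries the lesion inside the
#' NdeI recognition site (T replaced by U) with 6 heavy dGMPs immediately
#' downstream and is released by NdeI + HaeII; the 5'-excision probe carries
#' 4 heavy dAMPs immediately upstream of the lesion and is released by
#' HaeII + PstI (no diagnostic enzyme is declared for it: a run of four
#' adenines cannot coexist with the lesion inside CATATG). Linear mode emits
#' a 52-mer with the lesion at position 26.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param maxTries mutation iterations allowed when removing extra sites
#'   (default 500).
#' @return a validated \code{\linkS4class{ProbeDesign}}.
#' @examples
#' pd <- makeProbe(simulationConfig(seed = 7))
#' all(validateDesign(pd)$pass)
#' @export
makeProbe <- function(config = simulationConfig(), maxTries = 500L) {
  stopifnot(inherits(config, "simConfig"))
  .withSeed(config$seed + 104729L, {
    if (config$mode == "linear") return(.makeLinearProbe(config))
    .makePlasmidProbe(config, maxTries)
  })
}

#' @keywords internal
.makeLinearProbe <- function(config) {
  n <- 52L; li <- 26L
  seqv <- .randSeq(n)
  seqv[li] <- config$lesionKind
  if (config$labelSide == "downstream_G") {
    lab <- (li + 1L):(li + 6L); seqv[lab] <- "G"
  } else {
    lab <- (li - 4L):(li - 1L); seqv[lab] <- "A"
  }
  ProbeDesign(seqv, topology = "linear", lesionIndex = li,
              lesionKind = config$lesionKind,
              oppositeBase = config$oppositeBase, labelIndices = lab,
              labelSide = config$labelSide,
              analysisEnzymes = character(),
              diagnosticEnzyme = NA_character_)
}

## Cassette blocks: fixed functional elements interleaved with mutable
## random spacers. Only fixed positions (enzyme sites, label runs, lesion)
## are protected from the site-removal mutations.
#' @keywords internal
.cassetteBlocks <- function(config) {
  lesion <- config$lesionKind
  fx <- function(...) list(fixed = TRUE, res = c(...))
  rd <- function(n) list(fixed = FALSE, res = .randSeq(n))
  if (config$labelSide == "downstream_G") {
    ## NdeI site with the lesion at its second T, 6 heavy Gs 3' of the
    ## lesion, HaeII closing the analysis fragment; PstI upstream for the
    ## bead-capture digest.
    blocks <- list(fx("G","C","T","C","T","T","C"),       # Nt.BspQI
                   rd(8),
                   fx("C","C","T","C","A","G","C"),       # Nb.BbvCI
                   rd(8),
                   fx("C","T","G","C","A","G"),           # PstI
                   rd(6),
                   fx("C","A","T","A",lesion,"G",         # NdeI, lesion = 2nd T
                      "G","G","G","G","G"),               # heavy G run
                   rd(5),                                 # in-fragment spacer
                   fx("A","G","C","G","C","T"))           # HaeII
    lesionOff <- 7L + 8L + 7L + 8L + 6L + 6L + 4L         # residues before lesion
    labelOff <- lesionOff + 1L + 0:5                      # G of site + 5 Gs
    analysisEnzymes <- c("NdeI", "HaeII")
    diagnostic <- "NdeI"
  } else {
    ## HaeII opening the fragment, 4 heavy As 5' of the lesion, PstI
    ## closing it.
    blocks <- list(fx("G","C","T","C","T","T","C"),       # Nt.BspQI
                   rd(8),
                   fx("C","C","T","C","A","G","C"),       # Nb.BbvCI
                   rd(8),
                   fx("A","G","C","G","C","T"),           # HaeII
                   rd(4),
                   fx("A","A","A","A",lesion),            # heavy A run + lesion
                   rd(5),
                   fx("C","T","G","C","A","G"))           # PstI
    lesionOff <- 7L + 8L + 7L + 8L + 6L + 4L + 4L         # residues before lesion
    labelOff <- lesionOff - (4:1)
    analysisEnzymes <- c("HaeII", "PstI")
    diagnostic <- NA_character_
  }
  res <- unlist(lapply(blocks, `[[`, "res"))
  fixed <- unlist(lapply(blocks, function(b) rep(b$fixed, length(b$res))))
  list(res = res, fixedPos = which(fixed), lesionOff = lesionOff,
       labelOff = labelOff, analysisEnzymes = analysisEnzymes,
       diagnostic = diagnostic)
}

#' @keywords internal
.makePlasmidProbe <- function(config, maxTries) {
  L <- config$plasmidLength
  cas <- .cassetteBlocks(config)
  analysisEnzymes <- cas$analysisEnzymes
  diagnostic <- cas$diagnostic
  nFill <- L - length(cas$res)
  if (nFill < 0L) stop("plasmidLength too small for the cassette",
                       call. = FALSE)
  seqv <- c(cas$res, .randSeq(nFill))
  li <- cas$lesionOff + 1L
  lab <- cas$labelOff + 1L

  ## mutate away extra constrained sites in the mutable positions; enzymes
  ## absent from the cassette (NdeI on the excision probe) are unconstrained
  protected <- cas$fixedPos
  constrained <- c("Nt.BspQI", "Nb.BbvCI", analysisEnzymes,
                   if (!is.na(diagnostic)) diagnostic)
  constrained <- unique(constrained)
  want <- setNames(rep(1L, length(constrained)), constrained)
  for (try in seq_len(maxTries)) {
    bad <- NULL
    for (nm in constrained) {
      s <- findSites(seqv, nm, topology = "circular")
      if (nrow(s) > want[[nm]]) {
        m <- nchar(.getEnzyme(nm)$recognition)
        for (r in seq_len(nrow(s))) {
          span <- .wrap1(s$start[r] + seq_len(m) - 1L, L)
          free <- setdiff(span, protected)
          ## mutate any filler position of a spurious site (sites wholly
          ## inside the fixed cassette cannot be spurious)
          if (length(free)) { bad <- free; break }
        }
        if (!is.null(bad)) break
      }
    }
    if (is.null(bad)) break
    pos <- if (length(bad) == 1L) bad else sample(bad, 1L)
    seqv[pos] <- sample(setdiff(c("A", "C", "G", "T"), seqv[pos]), 1L)
  }
  counts <- .siteCount(seqv, constrained, "circular")
  if (any(counts != 1L))
    stop("probe generation failed: could not obtain unique sites for ",
         paste(constrained[counts != 1L], collapse = ", "),
         call. = FALSE)
  ProbeDesign(seqv, topology = "circular", lesionIndex = li,
              lesionKind = config$lesionKind, oppositeBase = config$oppositeBase,
              labelIndices = lab, labelSide = config$labelSide,
              analysisEnzymes = analysisEnzymes,
              diagnosticEnzyme = diagnostic)
}

#' Simulate an ESI negative-mode spectrum
#'
#' Places, for every ladder class and every charge state inside the window,
#' an envelope-collapsed Gaussian peak at the class m/z with height
#' proportional to (ground-truth proportion) x (charge-envelope weight),
#' then adds a constant baseline and seeded Gaussian noise. Deterministic
#' per seed.
#'
#' @param ladder a \code{\linkS4class{MassLadder}}; defaults to the ladder of
#'   the default probe generated from \code{config}.
#' @param truth named ground-truth composition over the ladder's repair
#'   classes (missing classes get 0); defaults to \code{config$truth}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed spectrum seed (defaults to \code{config$seed}).
#' @return a \code{\linkS4class{Spectrum}} whose metadata records truth,
#'   seed and configuration.
#' @examples
#' sp <- simulateSpectrum(seed = 2)
#' @export
simulateSpectrum <- function(ladder = NULL, truth = NULL,
                             config = simulationConfig(), seed = config$seed) {
  stopifnot(inherits(config, "simConfig"))
  if (is.null(ladder)) {
    pd <- makeProbe(config)
    ladder <- buildLadder(enumerateOutcomes(pd), pd,
                          chargeRange = config$chargeRange,
                          window = config$window)
  }
  if (is.null(truth)) truth <- config$truth
  e <- ladderEntries(ladder)
  repLabels <- e$label[e$state == "repaired"]
  extra <- setdiff(names(truth), repLabels)
  if (length(extra))
    stop("truth labels not in the ladder: ", paste(extra, collapse = ", "),
         " (composition/ladder mismatch)", call. = FALSE)
  if (abs(sum(truth) - 1) > 1e-9 || any(truth < 0))
    stop("truth must be a composition on the simplex", call. = FALSE)
  p <- setNames(numeric(length(repLabels)), repLabels)
  p[names(truth)] <- truth
  f <- config$unrepairedFraction
  amp <- c(p * (1 - f), setNames(f, "unrepaired")) * config$peakHeight

  zs <- seq.int(config$chargeRange[1], config$chargeRange[2])
  w <- exp(-(zs - config$chargeCenter)^2 / (2 * config$chargeSpread^2))
  names(w) <- as.character(zs)

  grid <- seq(config$window[1], config$window[2], by = config$gridStep)
  y <- numeric(length(grid))
  pk <- ladderPeaks(ladder)
  for (i in seq_len(nrow(pk))) {
    a <- amp[[pk$label[i]]] * w[[as.character(pk$z[i])]]
    if (is.na(a) || a <= 0) next
    ctr <- pk$mz[i]
    span <- which(grid >= ctr - 6 * config$peakSigma &
                  grid <= ctr + 6 * config$peakSigma)
    y[span] <- y[span] +
      a * exp(-(grid[span] - ctr)^2 / (2 * config$peakSigma^2))
  }
  .withSeed(seed, {
    y <- y + config$baseline + rnorm(length(y), 0, config$noiseSd)
  })
  Spectrum(grid, pmax(y, 0),
           metadata = list(truth = p, unrepairedFraction = f, seed = seed,
                           config = unclass(config), source = "simulateSpectrum"))
}

#' Simulate a replicate composition table
#'
#' Draws replicate composition vectors from a Dirichlet distribution with
#' mean \code{meanComposition} and the given precision (concentration sum);
#' the empirical mean converges to the mean composition as n grows.
#'
#' @param meanComposition named mean composition on the simplex.
#' @param precision Dirichlet precision (> 0); larger = tighter replicates.
#' @param n number of replicates (>= 2).
#' @param seed integer seed.
#' @param group group label assigned to all rows (default \code{"g1"}).
#' @return a \code{\linkS4class{CompositionTable}}.
#' @examples
#' simulateReplicates(c(a = 0.3, b = 0.7), precision = 100, n = 3, seed = 1)
#' @export
simulateReplicates <- function(meanComposition, precision, n, seed,
                               group = "g1") {
  if (any(meanComposition < 0) || abs(sum(meanComposition) - 1) > 1e-9)
    stop("meanComposition must lie on the simplex (input error)",
         call. = FALSE)
  stopifnot(precision > 0, n >= 2)
  alpha <- precision * meanComposition
  .withSeed(seed, {
    m <- t(vapply(seq_len(n), function(i) {
      g <- rgamma(length(alpha), shape = alpha, rate = 1)
      g / sum(g)
    }, numeric(length(alpha))))
  })
  colnames(m) <- names(meanComposition)
  CompositionTable(m, group = rep(group, n))
}
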