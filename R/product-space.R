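## Product space: enumerate distinguishable repair outcomes and build the
## theoretical mass ladder. A repair outcome replaces the lesion (and k-1
## downstream nucleotides, the "patch") and j upstream nucleotides (the
## "5' excision") with normal-mass synthesis; each heavy residue inside the
## replaced window lowers the fragment mass by ~15.0187 Da. Outcomes with
## equal heavy-replacement counts are indistinguishable by mass and are
## merged, which yields the open-ended top bins (">=7-nt" patches,
## ">=4-nt" excision).

#' Enumerate distinguishable repair outcomes
#'
#' For a downstream-G (patch-size) probe, outcomes vary the patch length k at
#' j = 0; for an upstream-A (5'-excision) probe, outcomes vary j while k is
#' marginalized (downstream replacement swaps light residues for light ones
#' and cannot change the mass). Outcomes whose heavy-replacement count equals
#' that of a smaller class are merged into an open-ended class labeled with a
#' \code{>=} prefix.
#'
#' @param design a \code{\linkS4class{ProbeDesign}}.
#' @param jMax largest 5'-excision length enumerated (default 6).
#' @param kMax largest patch length enumerated (default 8).
#' @param table enzyme table.
#' @return data.frame with columns \code{label}, \code{state}
#'   (\code{"repaired"}), \code{j}, \code{k} (representative outcome; k is NA
#'   for excision probes where it is marginalized), \code{heavyRemoved} and
#'   \code{nMerged} (how many raw outcomes the class absorbs).
#' @examples
#' pd <- makeProbe(simulationConfig(seed = 1))
#' enumerateOutcomes(pd)$label
#' @export
enumerateOutcomes <- function(design, jMax = 6L, kMax = 8L,
                              table = loadEnzymeTable()) {
  stopifnot(is(design, "ProbeDesign"), jMax >= 1L, kMax >= 1L)
  frag <- analysisFragment(design, table = table)
  lo <- frag$lesionOffset
  n <- frag$interval$length
  hv <- frag$heavy
  if (design@labelSide == "downstream_G") {
    if (lo + kMax - 1L > n)
      stop("replaced window exceeds the analysis fragment (input error)",
           call. = FALSE)
    idx <- seq_len(kMax)
    removed <- vapply(idx, function(k) sum(hv[lo:(lo + k - 1L)]), numeric(1))
    jrep <- rep(0L, kMax); krep <- idx; unit <- "k"
  } else {
    if (lo - jMax < 1L)
      stop("replaced window exceeds the analysis fragment (input error)",
           call. = FALSE)
    idx <- 0L:jMax
    removed <- vapply(idx, function(j)
      if (j == 0L) 0 else sum(hv[(lo - j):(lo - 1L)]), numeric(1))
    jrep <- idx; krep <- rep(NA_integer_, length(idx)); unit <- "j"
  }
  grp <- match(removed, removed)        # index of first outcome w/ same count
  reps <- sort(unique(grp))
  out <- lapply(reps, function(g) {
    members <- which(grp == g)
    size <- idx[g]
    lab <- if (length(members) > 1L) sprintf("\u2265%d-nt", size)
           else sprintf("%d-nt", size)
    data.frame(label = lab, state = "repaired", j = jrep[g], k = krep[g],
               heavyRemoved = removed[g], nMerged = length(members))
  })
  out <- do.call(rbind, out)
  if (length(unique(out$heavyRemoved)) == 1L && nrow(out) == 1L &&
      length(idx) > 1L)
    warning("probe carries no informative labels: all repaired outcomes ",
            "collapse to a single class", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' @keywords internal
.outcomeMass <- function(frag, design, j, k, state) {
  res <- frag$residues
  hv <- frag$heavy
  lo <- frag$lesionOffset
  if (state == "repaired") {
    res[lo] <- .lesionResult(design)
    win <- lo
    if (!is.na(k) && k > 1L) win <- c(win, (lo + 1L):(lo + k - 1L))
    if (j > 0L) win <- c(win, (lo - j):(lo - 1L))
    hv[win] <- FALSE
  }
  fp <- if (frag$fivePrime %in% c("phosphate", "circular")) "phosphate"
        else "hydroxyl"
  neutralMass(fragmentComposition(res, hv, fivePrime = fp))
}

#' Build the theoretical mass ladder
#'
#' Computes, for every outcome class plus the intact unrepaired substrate,
#' the neutral mass of the analysis fragment with the outcome's replacements
#' applied, and lists every charge state whose m/z falls inside the
#' instrument window.
#'
#' @param outcomes data.frame from \code{\link{enumerateOutcomes}}.
#' @param design the \code{\linkS4class{ProbeDesign}} the outcomes refer to.
#' @param chargeRange integer length-2; negative-mode charge magnitudes
#'   considered (default 4 to 8).
#' @param window m/z acquisition window (default 900 to 1800, the
#'   time-of-flight range of the assay).
#' @param matchOn which mass scale positions the ladder peaks:
#'   \code{"average"} (default; envelope-collapsed peaks) or
#'   \code{"monoisotopic"} (isotope-resolved centroids).
#' @param kMax used to assert, for upstream-A probes, that the patch length
#'   never changes the computed mass.
#' @param table enzyme table.
#' @return a \code{\linkS4class{MassLadder}}; entries sorted by ascending
#'   monoisotopic mass, with the unrepaired entry flagged by
#'   \code{state == "unrepaired"}. If some entry has no charge state inside
#'   the window a warning is emitted (the ladder is still returned).
#' @examples
#' pd <- makeProbe(simulationConfig(seed = 1))
#' lad <- buildLadder(enumerateOutcomes(pd), pd)
#' ladderEntries(lad)
#' @export
buildLadder <- function(outcomes, design, chargeRange = c(4L, 8L),
                        window = c(900, 1800), matchOn = c("average",
                        "monoisotopic"), kMax = 8L,
                        table = loadEnzymeTable()) {
  matchOn <- match.arg(matchOn)
  if (!nrow(outcomes)) stop("outcomes must be non-empty", call. = FALSE)
  frag <- analysisFragment(design, table = table)
  rows <- lapply(seq_len(nrow(outcomes)), function(i) {
    m <- .outcomeMass(frag, design, outcomes$j[i], outcomes$k[i], "repaired")
    data.frame(label = outcomes$label[i], state = "repaired",
               j = outcomes$j[i], k = outcomes$k[i],
               heavyRemoved = outcomes$heavyRemoved[i],
               massMono = m[["monoisotopic"]], massAvg = m[["average"]])
  })
  mu <- .outcomeMass(frag, design, 0L, NA_integer_, "unrepaired")
  rows[[length(rows) + 1L]] <- data.frame(
    label = "unrepaired", state = "unrepaired", j = 0L, k = NA_integer_,
    heavyRemoved = 0, massMono = mu[["monoisotopic"]],
    massAvg = mu[["average"]])
  entries <- do.call(rbind, rows)
  entries <- entries[order(entries$massMono), , drop = FALSE]
  rownames(entries) <- NULL

  if (design@labelSide == "upstream_A") {
    ## patch length must be mass-silent for excision probes
    m1 <- .outcomeMass(frag, design, 0L, 1L, "repaired")
    mK <- .outcomeMass(frag, design, 0L, kMax, "repaired")
    stopifnot(abs(m1[["monoisotopic"]] - mK[["monoisotopic"]]) < 1e-9)
  }

  zs <- seq.int(chargeRange[1], chargeRange[2])
  mass <- if (matchOn == "average") entries$massAvg else entries$massMono
  peaks <- do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
    mz <- mzForCharge(mass[i], zs)
    keep <- mz >= window[1] & mz <= window[2]
    if (!any(keep)) return(NULL)
    data.frame(label = entries$label[i], z = zs[keep], mz = mz[keep])
  }))
  if (is.null(peaks))
    peaks <- data.frame(label = character(), z = integer(), mz = numeric())
  missing <- setdiff(entries$label, unique(peaks$label))
  if (length(missing))
    warning("no charge state inside the window for: ",
            paste(missing, collapse = ", "), call. = FALSE)
  new("MassLadder", entries = entries, peaks = peaks,
      window = as.numeric(window),
      chargeRange = as.integer(chargeRange), matchOn = matchOn)
}

#' Detect ambiguous (colliding) ladder classes
#'
#' Reports every pair of quantified repair classes whose neutral masses lie
#' closer than \code{minSeparation}, plus any pair of entries (including the
#' unrepaired substrate) whose charge-state peaks overlap within the matching
#' tolerance at a shared charge state. The unrepaired entry is exempt from
#' the separation rule because the chemistry pins it ~1 Da from the 2-nt
#' product (U-to-T is +14.016 Da, one heavy replacement is -15.019 Da); it
#' only needs to be resolvable at the matching tolerance, not by a full
#' ladder step.
#'
#' @param ladder a \code{\linkS4class{MassLadder}}.
#' @param minSeparation required neutral-mass separation in Da (> 0).
#' @param tolerance neutral-mass matching tolerance in Da (default 0.35, the
#'   assignment default).
#' @return data.frame with columns \code{label1}, \code{label2},
#'   \code{deltaM}; zero rows when the ladder is identifiable.
#' @export
collisionCheck <- function(ladder, minSeparation = 5, tolerance = 0.35) {
  stopifnot(minSeparation > 0)
  e <- ladderEntries(ladder)
  mass <- if (ladder@matchOn == "average") e$massAvg else e$massMono
  pk <- ladderPeaks(ladder)
  out <- list()
  if (nrow(e) >= 2L) for (i in seq_len(nrow(e) - 1L)) for (jj in (i + 1L):nrow(e)) {
    dm <- abs(mass[jj] - mass[i])
    sharedZ <- intersect(pk$z[pk$label == e$label[i]],
                         pk$z[pk$label == e$label[jj]])
    bothRepair <- e$state[i] == "repaired" && e$state[jj] == "repaired"
    if ((bothRepair && dm < minSeparation) ||
        (length(sharedZ) && dm < tolerance))
      out[[length(out) + 1L]] <- data.frame(label1 = e$label[i],
                                            label2 = e$label[jj], deltaM = dm)
  }
  if (!length(out))
    return(data.frame(label1 = character(), label2 = character(),
                      deltaM = numeric()))
  do.call(rbind, out)
}
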