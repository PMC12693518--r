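## Shared fixtures, memoized so that slow probe construction runs once per
## test session.

.fx <- new.env()

fixtureProbe <- function(side = "downstream_G", seed = 1L) {
  key <- paste(side, seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- makeProbe(simulationConfig(seed = seed, labelSide = side))
  .fx[[key]]
}

fixtureLadder <- function(side = "downstream_G", seed = 1L) {
  key <- paste("lad", side, seed)
  if (is.null(.fx[[key]])) {
    pd <- fixtureProbe(side, seed)
    .fx[[key]] <- buildLadder(enumerateOutcomes(pd), pd)
  }
  .fx[[key]]
}

## Pad a named truth composition to all repair classes of a ladder.
fullTruth <- function(truth, ladder) {
  e <- ladderEntries(ladder)
  labs <- e$label[e$state == "repaired"]
  p <- setNames(numeric(length(labs)), labs)
  p[names(truth)] <- truth
  p
}

## A tiny hand-built ladder for assignment/quantification edge cases.
toyLadder <- function(masses, labels = names(masses),
                      states = rep("repaired", length(masses)),
                      chargeRange = c(1L, 1L), window = c(100, 1e5)) {
  if (!length(masses)) labels <- character()
  entries <- data.frame(label = labels, state = states,
                        j = integer(length(masses)),
                        k = rep(NA_integer_, length(masses)),
                        heavyRemoved = numeric(length(masses)),
                        massMono = as.numeric(masses),
                        massAvg = as.numeric(masses))
  zs <- seq.int(chargeRange[1], chargeRange[2])
  peaks <- do.call(rbind, lapply(seq_along(masses), function(i) {
    mz <- mzForCharge(masses[i], zs)
    keep <- mz >= window[1] & mz <= window[2]
    data.frame(label = labels[i], z = zs[keep], mz = mz[keep])
  }))
  if (is.null(peaks))
    peaks <- data.frame(label = character(), z = integer(), mz = numeric())
  new("MassLadder", entries = entries, peaks = peaks,
      window = as.numeric(window), chargeRange = as.integer(chargeRange),
      matchOn = "average")
}

## PeakList from raw vectors.
toyPeaks <- function(mz, height) {
  o <- order(mz)
  new("PeakList", peaks = data.frame(mz = mz[o], height = height[o],
                                     snr = height[o], area = height[o]))
}
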