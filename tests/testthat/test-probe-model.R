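revcomp <- function(seqv) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  rev(unname(comp[seqv]))
}

test_that("recognition sites are found with IUPAC degeneracy and U==T", {
  s <- findSites("GGCATATGCC", "NdeI", topology = "linear")
  expect_equal(s$start, 3L)
  expect_equal(s$strand, "+")
  expect_equal(s$cutTop, 4L)     # CA^TATG
  expect_equal(s$cutBottom, 6L)

  ## HaeII = RGCGCY: purine required at position 1
  expect_equal(nrow(findSites("AGCGCT", "HaeII", topology = "linear")), 1L)
  expect_equal(nrow(findSites("TGCGCT", "HaeII", topology = "linear")), 0L)

  ## U is read as T
  expect_equal(findSites(c("G","G","C","A","T","A","U","G","C","C"), "NdeI",
                         topology = "linear")$start, 3L)
  ## an abasic residue blocks the site
  expect_equal(nrow(findSites(c("G","G","C","A","T","A","AP","G","C","C"),
                              "NdeI", topology = "linear")), 0L)

  expect_error(findSites("ACGT", "NoSuchEnzyme"), "unknown enzyme")
  expect_error(findSites(character(), "NdeI"), "empty sequence")
})

test_that("circular scanning reports origin-spanning sites once, matching a
          rotation oracle", {
  set.seed(21)
  for (rep in 1:5) {
    ## random circle with one NdeI site laid across the origin
    L <- 40L
    seqv <- sample(c("A", "C", "T"), L, replace = TRUE)  # no G: no chance sites
    site <- c("C", "A", "T", "A", "T", "G")
    cutAt <- sample(1:5, 1)                              # split point in site
    seqv[(L - cutAt + 1):L] <- site[1:cutAt]
    seqv[1:(6 - cutAt)] <- site[(cutAt + 1):6]
    got <- findSites(seqv, "NdeI", topology = "circular")

    ## oracle: brute-force linear scan over every rotation, mapped back
    oracle <- integer()
    for (r in 0:(L - 1)) {
      rot <- seqv[((seq_len(L) - 1 + r) %% L) + 1]
      hit <- findSites(rot, "NdeI", topology = "linear")$start
      oracle <- union(oracle, ((hit - 1 + r) %% L) + 1)
    }
    expect_equal(sort(got$start), sort(oracle))
    expect_equal(nrow(got), 1L)              # reported exactly once
    expect_equal(got$start, L - cutAt + 1L)  # wrapped coordinate
  }
})

test_that("site lists are mirror-consistent under reverse complement", {
  set.seed(31)
  for (enz in c("NdeI", "HaeII", "PstI", "Nt.BspQI")) {
    m <- nchar(bermass::loadEnzymeTable()$recognition[
      bermass::loadEnzymeTable()$name == enz])
    for (rep in 1:5) {
      L <- 60L
      seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      fwd <- findSites(seqv, enz, topology = "linear")$start
      rc <- findSites(revcomp(seqv), enz, topology = "linear")$start
      expect_equal(sort((L - (fwd + m - 1)) + 1L), sort(rc))
    }
  }
})

test_that("digestion conserves sequence length and cut chemistry", {
  pd <- fixtureProbe()
  L <- length(probeSequence(pd))

  fr <- digestProbe(pd, c("NdeI", "HaeII"), strand = "both")
  for (st in c("top", "bottom"))
    expect_equal(sum(fr$length[fr$strand == st]), L)
  expect_true(all(fr$fivePrime == "phosphate"))
  expect_true(all(fr$threePrime == "hydroxyl"))

  ## single cut on a circle linearizes to one full-length fragment
  fr1 <- digestProbe(pd, "PstI")
  expect_equal(nrow(fr1), 1L)
  expect_equal(fr1$length, L)

  ## three cutters
  fr3 <- digestProbe(pd, c("NdeI", "HaeII", "PstI"))
  expect_equal(nrow(fr3), 3L)
  expect_equal(sum(fr3$length), L)

  ## zero cutters on a circle: "uncut", not an error
  pdNoSite <- ProbeDesign(c("A","C","A","U","A","C","C","T"),
                          topology = "circular", lesionIndex = 4,
                          labelIndices = integer())
  un <- digestProbe(pdNoSite, "NdeI")
  expect_equal(un$fivePrime, "circular")
  expect_equal(un$length, 8L)

  expect_error(digestProbe(pd, "Nt.BspQI"), "nicking")
})

test_that("the analysis fragment carries lesion and labels at known offsets", {
  pd <- fixtureProbe()
  frag <- analysisFragment(pd)
  expect_true(lesionIndex(pd) %in% frag$positions)
  expect_true(all(labelIndices(pd) %in% frag$positions))
  expect_equal(frag$interval$length, 19L)
  expect_equal(frag$lesionOffset, 3L)   # NdeI leaves TA | U at the 5' end
  expect_equal(sum(frag$heavy), 6L)

  pdA <- fixtureProbe("upstream_A")
  fragA <- analysisFragment(pdA)
  expect_equal(fragA$interval$length, 20L)
  expect_equal(sum(fragA$heavy), 4L)
  expect_true(all(which(fragA$heavy) == fragA$lesionOffset - (4:1)))
})

test_that("diagnostic digest logic reproduces the uracil/abasic behavior", {
  pd <- fixtureProbe()   # U inside the NdeI site

  ## intact U probe is cleavable (U read as T)
  expect_equal(simulateDiagnostic(pd, "NdeI")$verdict, "cut")
  ## UDG converts U to AP: site blocked
  expect_equal(simulateDiagnostic(pd, c("UDG", "NdeI"))$verdict, "uncut")
  ## repaired molecule (lesion -> T) stays cleavable through UDG
  expect_equal(simulateDiagnostic(pd, c("UDG", "NdeI"),
                                  state = "repaired")$verdict, "cut")
  ## an APE1 nick inside the site also blocks
  expect_equal(simulateDiagnostic(pd, c("UDG", "APE1", "NdeI"))$verdict,
               "uncut")
  ## the distal PstI site is untouched by any of this
  expect_equal(simulateDiagnostic(pd, c("UDG", "APE1", "PstI"))$verdict, "cut")

  ## an rAP lesion blocks recognition directly
  seqv <- probeSequence(pd)
  seqv[lesionIndex(pd)] <- "rAP"
  pdR <- ProbeDesign(seqv, topology = "circular",
                     lesionIndex = lesionIndex(pd), lesionKind = "rAP",
                     labelIndices = labelIndices(pd),
                     labelSide = "downstream_G",
                     analysisEnzymes = c("NdeI", "HaeII"),
                     diagnosticEnzyme = "NdeI")
  expect_equal(simulateDiagnostic(pdR, "NdeI")$verdict, "uncut")

  expect_error(simulateDiagnostic(pd, "NotATreatment"), "unknown treatment")
})

test_that("design validation reports failed checks without raising", {
  pd <- fixtureProbe()
  rep0 <- validateDesign(pd)
  expect_true(all(rep0$pass))
  expect_setequal(rep0$check,
                  c("unique_nicking_sites", "lesion_in_diagnostic_site",
                    "analysis_enzymes_single_cut",
                    "labels_in_analysis_fragment", "collision_free_ladder"))

  ## second Nt.BspQI site in the filler fails check 1 (and nothing raises)
  seqv <- probeSequence(pd)
  seqv[1001:1007] <- c("G", "C", "T", "C", "T", "T", "C")
  pd2 <- ProbeDesign(seqv, topology = "circular",
                     lesionIndex = lesionIndex(pd),
                     labelIndices = labelIndices(pd),
                     labelSide = "downstream_G",
                     analysisEnzymes = c("NdeI", "HaeII"),
                     diagnosticEnzyme = "NdeI")
  rep2 <- validateDesign(pd2)
  expect_false(rep2$pass[rep2$check == "unique_nicking_sites"])

  ## lesion outside the diagnostic site fails check 2
  pd3 <- ProbeDesign(c("G","G","C","A","T","A","T","G","C","C","U","A"),
                     topology = "linear", lesionIndex = 11,
                     labelIndices = integer(), labelSide = "downstream_G",
                     diagnosticEnzyme = "NdeI")
  rep3 <- suppressWarnings(validateDesign(pd3))
  expect_false(rep3$pass[rep3$check == "lesion_in_diagnostic_site"])
})
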