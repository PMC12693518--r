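gauss <- function(grid, ctr, h, sigma = 0.02) h * exp(-(grid - ctr)^2 / (2 * sigma^2))

test_that("spectrum averaging is a pointwise mean with resampling", {
  grid <- seq(1000, 1010, by = 0.005)
  y <- gauss(grid, 1005, 100)
  s1 <- Spectrum(grid, y)

  av <- averageSpectra(list(s1, s1, s1))
  expect_equal(av@intensity, y)
  expect_equal(av@metadata$scans, 3L)

  s0 <- Spectrum(grid, numeric(length(grid)))
  av2 <- averageSpectra(list(s1, s0))
  expect_equal(av2@intensity, y / 2)

  ## different grids are interpolated onto the densest one
  coarse <- Spectrum(seq(1000, 1010, by = 0.05),
                     gauss(seq(1000, 1010, by = 0.05), 1005, 100))
  av3 <- averageSpectra(list(s1, coarse))
  expect_equal(length(av3@mz), length(grid))
  expect_equal(max(av3@intensity), 100, tolerance = 0.02)

  expect_error(averageSpectra(list()), "empty")
})

test_that("averaging n noisy replicates shrinks the noise like 1/sqrt(n)", {
  grid <- seq(1000, 1020, by = 0.01)
  set.seed(5)
  mkNoise <- function() Spectrum(grid, pmax(rnorm(length(grid), 50, 4), 0))
  one <- mkNoise()
  many <- averageSpectra(replicate(16, mkNoise(), simplify = FALSE))
  ratio <- sd(many@intensity) / sd(one@intensity)
  expect_equal(ratio, 1 / 4, tolerance = 0.15)
})

test_that("peak picking finds isolated Gaussians and rejects pure noise", {
  grid <- seq(1000, 1010, by = 0.005)

  ## single peak: centroid within 0.01 m/z of truth
  sp <- Spectrum(grid, gauss(grid, 1004.9973, 200) + 1)
  pk <- peakTable(pickPeaks(sp))
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$mz - 1004.9973), 0.01)
  expect_equal(pk$height, 200, tolerance = 0.02)

  ## two peaks separated by > 3 widths
  sp2 <- Spectrum(grid, gauss(grid, 1003, 150) + gauss(grid, 1006, 80) + 1)
  expect_equal(nrow(peakTable(pickPeaks(sp2))), 2L)

  ## pure noise at minSnr = 5: false positives in < 1% of spectra
  set.seed(123)
  nFP <- 0L
  for (i in 1:100) {
    noise <- Spectrum(seq(1000, 1025, by = 0.005),
                      pmax(rnorm(5001, 10, 2), 0))
    nFP <- nFP + (nrow(peakTable(pickPeaks(noise, minSnr = 5))) > 0L)
  }
  expect_lte(nFP, 1L)
})

test_that("nearby noise maxima on one physical peak are merged", {
  grid <- seq(1000, 1010, by = 0.005)
  set.seed(77)
  sp <- Spectrum(grid, pmax(gauss(grid, 1005, 60, sigma = 0.05) +
                              rnorm(length(grid), 0, 2), 0))
  ## minPeakDist is scaled to the (here: broad) peak width, ~3 sigma
  pk <- peakTable(pickPeaks(sp, minPeakDist = 0.15))
  expect_equal(sum(abs(pk$mz - 1005) < 0.2), 1L)
  expect_equal(pk$height[which.min(abs(pk$mz - 1005))], 60, tolerance = 0.1)
})

test_that("assignment deconvolves at every charge and flags ambiguity", {
  lad <- fixtureLadder()
  e <- ladderEntries(lad)
  m2 <- e$massAvg[e$label == "2-nt"]

  ## a peak placed exactly at the 2-nt class m/z for z = 6
  pk <- toyPeaks(mzForCharge(m2, 6), 100)
  asg <- assignPeaks(pk, lad)
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$label, "2-nt")
  expect_equal(asg$z, 6L)
  expect_lt(abs(asg$errorDa), 1e-9)
  expect_false(asg$ambiguous)

  ## a peak 10 Da (neutral) off every entry stays unassigned
  far <- toyPeaks(mzForCharge(m2 + 10, 6), 100)
  expect_equal(nrow(assignPeaks(far, lad, tolerance = 0.5)), 0L)

  ## two entries 0.3 Da apart at tolerance 0.5: both matches ambiguous
  toy <- toyLadder(c(a = 6000.0, b = 6000.3), chargeRange = c(6L, 6L))
  both <- assignPeaks(toyPeaks(mzForCharge(6000.15, 6), 50), toy,
                      tolerance = 0.5)
  expect_equal(nrow(both), 2L)
  expect_true(all(both$ambiguous))

  expect_error(assignPeaks(pk, toyLadder(numeric(0))), "empty ladder")
})

test_that("quantification follows the peak-height proportion rule", {
  toy <- toyLadder(c("1-nt" = 6000, "2-nt" = 6100, unrepaired = 6200),
                   states = c("repaired", "repaired", "unrepaired"),
                   chargeRange = c(5L, 6L))

  mkAsg <- function(label, z, height)
    data.frame(peak = seq_along(label), mz = 0, height = height, z = z,
               label = label, errorDa = 0, errorPpm = 0, ambiguous = FALSE)

  ## heights 80 / 20 -> proportions 0.8 / 0.2
  est <- quantifyComposition(mkAsg(c("1-nt", "2-nt"), 6L, c(80, 20)), toy)
  expect_equal(unname(proportions(est)), c(0.8, 0.2))
  expect_equal(unrepairedFraction(est), 0)

  ## heights summed across charge states: (30 + 10) vs 60 -> 0.4 / 0.6
  est2 <- quantifyComposition(
    mkAsg(c("1-nt", "1-nt", "2-nt"), c(5L, 6L, 6L), c(30, 10, 60)), toy)
  expect_equal(unname(proportions(est2)), c(0.4, 0.6))

  ## the unrepaired class never enters the repair denominator
  est3 <- quantifyComposition(
    mkAsg(c("1-nt", "2-nt", "unrepaired"), 6L, c(80, 20, 100)), toy)
  expect_equal(unname(proportions(est3)), c(0.8, 0.2))
  expect_equal(unrepairedFraction(est3), 0.5)

  ## ambiguous assignments are excluded
  a <- mkAsg(c("1-nt", "2-nt", "2-nt"), 6L, c(80, 20, 500))
  a$ambiguous[3] <- TRUE
  expect_equal(unname(proportions(quantifyComposition(a, toy))), c(0.8, 0.2))

  ## zero repair signal is an explicit error
  expect_error(
    quantifyComposition(mkAsg("unrepaired", 6L, 10), toy), "no repair")
})

test_that("composition estimates are invariant to peak order and intensity
          scale", {
  lad <- fixtureLadder()
  cfg <- simulationConfig(seed = 1)
  sp <- simulateSpectrum(lad, cfg$truth, cfg, seed = 8)
  pk <- pickPeaks(sp)

  base <- quantifyComposition(assignPeaks(pk, lad), lad)

  ## permuted peak order
  tb <- peakTable(pk)
  set.seed(2); shuf <- tb[sample(nrow(tb)), ]
  shuf <- shuf[order(shuf$mz), ]; rownames(shuf) <- NULL
  pk2 <- new("PeakList", peaks = shuf)
  est2 <- quantifyComposition(assignPeaks(pk2, lad), lad)
  expect_equal(proportions(est2), proportions(base))

  ## halved intensities
  spHalf <- Spectrum(sp@mz, sp@intensity / 2)
  estHalf <- analyzeSpectrum(spHalf, lad)
  expect_equal(proportions(estHalf), proportions(base), tolerance = 1e-6)
  expect_equal(unrepairedFraction(estHalf), unrepairedFraction(base),
               tolerance = 1e-6)
})

test_that("the full pipeline recovers simulated ground truth within 0.03", {
  lad <- fixtureLadder()
  cfg <- simulationConfig(seed = 1)
  truth <- fullTruth(cfg$truth, lad)
  errs <- vapply(1:20, function(s) {
    est <- analyzeSpectrum(simulateSpectrum(lad, cfg$truth, cfg, seed = s), lad)
    max(abs(proportions(est)[names(truth)] - truth))
  }, numeric(1))
  expect_lt(mean(errs), 0.03)
  ## and the unrepaired fraction tracks its simulated value
  est <- analyzeSpectrum(simulateSpectrum(lad, cfg$truth, cfg, seed = 3), lad)
  expect_equal(unrepairedFraction(est), 0.1, tolerance = 0.03)
})
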