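test_that("probe generation is deterministic and satisfies its constraints", {
  cfg <- simulationConfig(seed = 42)
  p1 <- makeProbe(cfg)
  p2 <- makeProbe(simulationConfig(seed = 42))
  expect_identical(probeSequence(p1), probeSequence(p2))
  expect_identical(labelIndices(p1), labelIndices(p2))

  p3 <- makeProbe(simulationConfig(seed = 43))
  expect_false(identical(probeSequence(p1), probeSequence(p3)))

  ## every generated plasmid probe passes the validator (wider sweep lives
  ## in the acceptance suite)
  for (s in c(5, 17, 23)) {
    for (side in c("downstream_G", "upstream_A")) {
      pd <- makeProbe(simulationConfig(seed = s, labelSide = side))
      v <- validateDesign(pd)
      expect_true(all(v$pass), info = paste(side, "seed", s))
    }
  }
})

test_that("linear mode emits a 52-mer with a centrally located lesion", {
  pd <- makeProbe(simulationConfig(seed = 9, mode = "linear"))
  expect_equal(length(probeSequence(pd)), 52L)
  expect_equal(lesionIndex(pd), 26L)
  expect_equal(probeTopology(pd), "linear")
  expect_equal(probeSequence(pd)[26], "U")
  expect_equal(labelIndices(pd), 27:32)

  pdA <- makeProbe(simulationConfig(seed = 9, mode = "linear",
                                    labelSide = "upstream_A"))
  expect_equal(labelIndices(pdA), 22:25)
})

test_that("noiseless single-class spectra have peaks only at that class's
          ladder positions", {
  lad <- fixtureLadder()
  cfg <- simulationConfig(seed = 1, noiseSd = 0, baseline = 0,
                          unrepairedFraction = 0)
  truth <- c("3-nt" = 1)
  sp <- simulateSpectrum(lad, truth, cfg, seed = 1)
  pk <- peakTable(pickPeaks(sp))
  want <- ladderPeaks(lad)
  want <- want$mz[want$label == "3-nt"]
  expect_equal(nrow(pk), length(want))
  expect_equal(sort(pk$mz), sort(want), tolerance = 1e-3)

  ## every simulated point stays inside the acquisition window
  expect_gte(min(sp@mz), 900)
  expect_lte(max(sp@mz), 1800)

  ## determinism
  sp2 <- simulateSpectrum(lad, truth, cfg, seed = 1)
  expect_identical(sp@intensity, sp2@intensity)

  ## a truth label unknown to the ladder is rejected
  expect_error(simulateSpectrum(lad, c("12-nt" = 1), cfg),
               "mismatch")
})

test_that("replicate tables are Dirichlet-distributed around the mean", {
  mean_comp <- c(a = 0.2, b = 0.5, c = 0.3)

  ## concentration limit: enormous precision pins rows to the mean
  tight <- proportions(simulateReplicates(mean_comp, precision = 1e8,
                                          n = 4, seed = 1))
  expect_lt(max(abs(sweep(tight, 2, mean_comp))), 1e-3)

  ## law of large numbers at n = 1e4
  big <- proportions(simulateReplicates(mean_comp, precision = 30,
                                        n = 1e4, seed = 2))
  expect_lt(max(abs(colMeans(big) - mean_comp)), 0.01)

  ## determinism
  t1 <- simulateReplicates(mean_comp, 50, 5, seed = 7)
  t2 <- simulateReplicates(mean_comp, 50, 5, seed = 7)
  expect_identical(proportions(t1), proportions(t2))

  expect_error(simulateReplicates(c(0.5, 0.2), 10, 3, seed = 1), "simplex")
  expect_error(simulateReplicates(mean_comp, -1, 3, seed = 1))
})

test_that("generator output flows through the whole pipeline unedited", {
  ## probe -> ladder -> spectrum -> analysis -> replicate table -> statistics
  cfgA <- simulationConfig(seed = 31, truth = scenarioComposition("hss_ua"))
  cfgB <- simulationConfig(seed = 31,
                           truth = scenarioComposition("hss_polb50"))
  pd <- makeProbe(cfgA)
  lad <- buildLadder(enumerateOutcomes(pd), pd)
  rows <- list(); grp <- character()
  for (cfg in list(cfgA, cfgB)) for (r in 1:3) {
    sp <- simulateSpectrum(lad, cfg$truth, cfg,
                           seed = 31000 + 10 * r + (cfg$truth[1] > 0.5))
    rows[[length(rows) + 1L]] <- proportions(analyzeSpectrum(sp, lad))
    grp <- c(grp, paste0("c", cfg$truth[1]))
  }
  m <- do.call(rbind, rows)
  ## restrict to the observed classes (the others are structural zeros that
  ## would overparameterize the fit at three replicates per group)
  m <- m[, c("1-nt", "2-nt")]
  m <- m / rowSums(m)
  tab <- closeComposition(CompositionTable(m, group = grp))
  lrt <- lrtGlobal(fitDirichlet(tab, "group"), fitDirichlet(tab, "intercept"))
  ## 20/80 vs 75/25 is a large, reliably detected shift
  expect_lt(lrt$p.value, 1e-4)
  bt <- betaComponentTests(tab)
  expect_true(all(bt$q[bt$class %in% c("1-nt", "2-nt")] < 0.05))
})
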