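test_that("equal seeds give bit-identical studies, different seeds differ", {
  a <- smallStudy(seed = 42)
  b <- smallStudy(seed = 42)
  expect_identical(intensities(a), intensities(b))
  expect_identical(sampleInfo(a), sampleInfo(b))
  c <- smallStudy(seed = 43)
  expect_false(identical(intensities(a), intensities(c)))
})

test_that("with all effects zero and vanishing noise every intensity is exp(mu)", {
  p <- 6
  eff <- effectSpec(p, mu = rep(2, p), tau = rep(0, p), sigma = 1e-9,
                    differentialPeaks = integer(0),
                    interactionPeaks = integer(0))
  study <- simulateStudy(studyDesign(nPerGroup = 3, nPeaks = p), eff)
  expect_equal(as.vector(intensities(study)),
               rep(exp(2), p * ncol(intensities(study))), tolerance = 1e-6)
})

test_that("planted down-regulation shows in late-stage tumor vs placebo means, across seeds", {
  for (seed in 1:20) {
    study <- simulateStudy(studyDesign(seed = seed),
                           effects = effectSpec(interactionPeaks = integer(0)))
    eff <- S4Vectors::metadata(study)$effects
    cd <- sampleInfo(study)
    lateTumor <- cd$timepoint == "late" & cd$condition == "tumor"
    latePlac <- cd$timepoint == "late" & cd$condition == "placebo"
    logI <- log(intensities(study))
    d <- rowMeans(logI[, lateTumor]) - rowMeans(logI[, latePlac])
    planted <- eff$differentialPeaks
    expect_true(all(sign(d[planted]) == sign(eff$delta[planted])),
                label = sprintf("planted signs recovered (seed %d)", seed))
  }
})

test_that("generator rejects invalid designs and effect parameters", {
  expect_error(studyDesign(nPerGroup = 1), class = "vocpanel_config_error")
  expect_error(effectSpec(10, sigma = 0), class = "vocpanel_config_error")
  expect_error(effectSpec(10, sigma = -1), class = "vocpanel_config_error")
  expect_error(simulateStudy(studyDesign(nPeaks = 10), effectSpec(9)),
               class = "vocpanel_config_error")
  # interaction effects must cancel across models
  g <- matrix(1, 10, 2)
  expect_error(effectSpec(10, gamma = g), class = "vocpanel_config_error")
})

test_that("ground-truth sets are recorded and lie within the peak list", {
  study <- smallStudy(seed = 5, nPeaks = 34)
  expect_true(all(plantedDifferential(study) %in% peakIds(study)))
  expect_true(all(plantedInteraction(study) %in% peakIds(study)))
  expect_length(intersect(plantedDifferential(study),
                          plantedInteraction(study)), 0)
})

test_that("tumor volume follows the caliper formula with coefficient 3.14", {
  expect_identical(tumorVolume(0, 0), 0)
  expect_equal(tumorVolume(6, 1), 3.14)
  expect_equal(tumorVolume(10, 5), 3.14 * 10 * 25 / 6)  # 130.8333...
  expect_equal(tumorVolume(10, 5), 130.83333, tolerance = 1e-6)
  expect_error(tumorVolume(-1, 2), class = "vocpanel_config_error")
})

test_that("growth cubics evaluate the printed polynomials", {
  expect_equal(growthCurve("LKR", 0), -18)
  expect_equal(growthCurve("LLC", 0), -4)
  expect_equal(growthCurve("LKR", 10), 0.092 * 1000 - 2.8 * 100 + 380 - 18)
  expect_equal(growthCurve("LKR", 10), 174)
  expect_error(growthCurve("XYZ", 1), class = "vocpanel_config_error")
})

test_that("synthetic chromatograms have the stated analytic properties", {
  grid <- seq(0, 10, by = 0.01)
  one <- simulateTic(10, 5, 0.2, grid)
  expect_equal(max(one$intensity), 10)
  expect_equal(one$rt[which.max(one$intensity)], 5)

  flat <- simulateTic(numeric(0), numeric(0), numeric(0), grid, baseline = 5)
  expect_true(all(flat$intensity == 5))

  two <- simulateTic(c(4, 7), c(3, 7), c(0.2, 0.3), grid, baseline = 0.5)
  trapz <- sum(diff(two$rt) * (head(two$intensity, -1) + tail(two$intensity, -1)) / 2)
  closed <- 0.5 * 10 + sum(c(4, 7) * c(0.2, 0.3) * sqrt(2 * pi))
  expect_equal(trapz, closed, tolerance = 1e-4)

  expect_error(simulateTic(1, 1, 1, numeric(0)), class = "vocpanel_data_error")
  n1 <- simulateTic(5, 5, 0.2, grid, noiseSd = 0.1, seed = 9)
  n2 <- simulateTic(5, 5, 0.2, grid, noiseSd = 0.1, seed = 9)
  expect_identical(n1, n2)
})
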