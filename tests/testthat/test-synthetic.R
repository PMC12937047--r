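test_that("with all noise off, the dual ratio is exactly affine in spike with
           x-intercept at minus the in-assay endogenous level", {
  m <- bvhMatrix(); d <- bvhDesign()
  tab <- simulateAssay(m, d, zeroErrorModel(), seed = 1)
  rt <- responseTable(tab)
  fit <- suppressWarnings(fitStandardAddition(rt$spike_level, rt$response))
  c0 <- endogenousInAssay(m, d)
  expect_equal(fit@x0, c0, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  # strict affinity: residuals of the exact line vanish
  expect_equal(rt$response,
               fit@slope * rt$spike_level + fit@intercept, tolerance = 1e-9)
})

test_that("the ionization matrix factor cancels from the endogenous estimate", {
  d <- bvhDesign()
  m1 <- bvhMatrix()
  m2 <- MatrixSpec("BVH-x2", 800, 12, matrixFactor = 2 * m1@matrixFactor,
                   extractionRecovery = m1@extractionRecovery)
  f <- function(m) {
    rt <- responseTable(simulateAssay(m, d, zeroErrorModel()))
    suppressWarnings(fitStandardAddition(rt$spike_level, rt$response))@x0
  }
  expect_equal(f(m1), f(m2), tolerance = 1e-9)
})

test_that("a default-noise run recovers the true endogenous concentration", {
  m <- bvhMatrix(); d <- bvhDesign()
  rt <- responseTable(simulateAssay(m, d, ErrorModel(), seed = 1))
  fit <- fitStandardAddition(rt$spike_level, rt$response)
  conc <- endogenousConcentration(fit, dilutionFactor(m, d))
  expect_lt(abs(conc[["conc"]] - m@trueConc) / m@trueConc, 0.05)
})

test_that("area tables have the full channel block per sample", {
  tab <- simulateAssay(bvhMatrix(), bvhDesign(), ErrorModel(), seed = 3)
  counts <- table(tab$sample_id, tab$channel)
  expect_true(all(counts == 1))
  expect_true(all(tab$area >= 0))
  expect_equal(nrow(tab), 4 * 3 * 3)  # levels x replicates x channels
})

test_that("validation aliquots make the recovery and matrix-effect estimators
           consistent for their generative parameters", {
  d <- bvhDesign()
  est <- function(m) {
    rt <- responseTable(makeValidationSet(m, d, zeroErrorModel()))
    A <- mean(rt$analyte[rt$design_role == "A"])
    B <- mean(rt$analyte[rt$design_role == "B"])
    C <- mean(rt$analyte[rt$design_role == "C"])
    D <- mean(rt$analyte[rt$design_role == "D"])
    c(rec = recoveryPercent(A, B, C), me = matrixEffectPercent(A, C, D))
  }
  ideal <- est(MatrixSpec("ideal", 800, 12, 1, 1))
  expect_equal(unname(ideal), c(100, 100), tolerance = 1e-9)
  suppressed <- est(MatrixSpec("sup", 800, 12, matrixFactor = 0.53))
  expect_equal(suppressed[["me"]], 53, tolerance = 1e-9)
  lossy <- est(MatrixSpec("loss", 800, 12, extractionRecovery = 0.93))
  expect_equal(lossy[["rec"]], 93, tolerance = 1e-9)
})

test_that("the saturating activity-yield map spans the robustness range", {
  E <- digestionYield(c(1000, 2000, 5000))
  expect_equal(E, c(0.6, 0.8, 1.0), tolerance = 1e-12)
  expect_gt((max(E) - min(E)) / E[2], 0.2)  # >= 20 percent spread
  expect_true(all(diff(digestionYield(seq(100, 8000, by = 100))) > 0))
})

test_that("sharing the digestion factor with IS1 is what makes the ratio
           robust", {
  m <- bvhMatrix(); d <- bvhDesign()
  tab <- makeRobustnessSet(m, d, zeroErrorModel())
  cv <- robustnessCv(tab)
  expect_gt(cv[["cv_unnormalized"]], 20)  # raw areas track the yield spread
  expect_equal(cv[["cv_normalized"]], 0)  # exact cancellation
  cvNoisy <- robustnessCv(makeRobustnessSet(m, d, ErrorModel(), seed = 7))
  expect_lt(cvNoisy[["cv_normalized"]], cvNoisy[["cv_unnormalized"]])
})

test_that("a single-activity design degenerates to detector-level noise", {
  m <- bvhMatrix(); d <- bvhDesign()
  e <- ErrorModel(enzymeEfficiencyCv = 0)  # isolate detector + channel noise
  tab <- makeRobustnessSet(m, d, e, activities = 2000, replicates = 200,
                           seed = 11)
  cv <- robustnessCv(tab)
  expected <- 100 * sqrt(e@runDetectorCv^2 + e@channelNoiseCv^2)
  expect_equal(cv[["cv_unnormalized"]], expected, tolerance = 0.25)
  expect_equal(cv[["cv_normalized"]], 100 * sqrt(2) * e@channelNoiseCv,
               tolerance = 0.25)
})

test_that("freeze-thaw cycling scales the endogenous level geometrically", {
  m <- bvhMatrix(); d <- bvhDesign(); z <- zeroErrorModel()
  x0 <- function(tab) {
    rt <- responseTable(tab)
    suppressWarnings(fitStandardAddition(rt$spike_level, rt$response))@x0
  }
  ref <- x0(simulateAssay(m, d, z))
  none <- x0(makeFreezeThawSet(m, d, z, cycles = 0, perCycleLoss = 0.075))
  expect_equal(none, ref, tolerance = 1e-9)
  lossless <- x0(makeFreezeThawSet(m, d, z, cycles = 2, perCycleLoss = 0))
  expect_equal(stabilityPercentChange(ref, lossless), 0, tolerance = 1e-9)
  two <- x0(makeFreezeThawSet(m, d, z, cycles = 2, perCycleLoss = 0.075))
  expect_equal(stabilityPercentChange(ref, two), 100 * (1 - 0.925^2),
               tolerance = 1e-9)  # 14.44 percent
})

test_that("rendered chromatograms re-integrate to the generating areas and
           are reproducible", {
  tab <- simulateAssay(bvhMatrix(), bvhDesign(), ErrorModel(), seed = 5)[1:3, ]
  e <- ErrorModel()
  tr <- renderChromatograms(tab, e, seed = 9)
  pk <- measurePeaks(tr, e)
  merged <- merge(tab, pk, by = c("sample_id", "channel"))
  expect_equal(merged$area.y / merged$area.x, rep(1, nrow(merged)),
               tolerance = 0.01)
  # zero area renders to a flat noise-only trace
  flat <- tab[1, ]; flat$area <- 0
  trFlat <- renderChromatograms(flat, e, seed = 9)
  expect_lt(max(abs(trFlat$intensity)), e@baselineNoiseAmplitude * 1.0001)
  # bit-identical under the same seed
  expect_identical(renderChromatograms(tab, e, seed = 9), tr)
})

test_that("generators are reproducible given a seed", {
  args <- list(bvhMatrix(), bvhDesign(), ErrorModel())
  expect_identical(do.call(simulateAssay, c(args, seed = 21)),
                   do.call(simulateAssay, c(args, seed = 21)))
  expect_identical(do.call(makeValidationSet, c(args, seed = 22)),
                   do.call(makeValidationSet, c(args, seed = 22)))
  expect_false(identical(do.call(simulateAssay, c(args, seed = 21)),
                         do.call(simulateAssay, c(args, seed = 23))))
})
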