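test_that("the dual-normalized response has its defining symmetries", {
  expect_equal(responseRatio(100, 50, 10), 0.2)
  expect_equal(responseRatio(0, 50, 10), 0)
  for (k in c(0.5, 3, 100))
    expect_equal(responseRatio(k * 100, k * 50, 10), 0.2)
  expect_equal(responseRatio(100, 50, 20), 0.1)  # inverse in IS2
  expect_error(responseRatio(10, 0, 5), "IS1")
  expect_error(responseRatio(10, 5, 0), "IS2")
})

test_that("standard-addition OLS recovers exact affine data", {
  fit <- suppressWarnings(   # stats::summary.lm warns on an exact fit
    fitStandardAddition(c(0, 4, 12, 20), c(0.8, 1.2, 2.0, 2.8)))
  expect_equal(fit@slope, 0.1, tolerance = 1e-12)
  expect_equal(fit@intercept, 0.8, tolerance = 1e-12)
  expect_equal(fit@x0, 8, tolerance = 1e-12)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_error(fitStandardAddition(c(0, 4, 12), c(1, 1, 1)),
               "non-responsive")
  expect_error(fitStandardAddition(c(0, 4), c(1, 2)), "design error")
  expect_error(fitStandardAddition(c(4, 12, 20), c(1, 2, 3)), "design error")
})

test_that("x0 is invariant under rescaling of the response axis", {
  set.seed(5)
  x <- rep(c(0, 4, 12, 20), 3)
  y <- (0.07 * x + 0.6) * (1 + rnorm(length(x), 0, 0.02))
  f1 <- fitStandardAddition(x, y)
  f2 <- fitStandardAddition(x, 1000 * y)
  expect_equal(f1@x0, f2@x0, tolerance = 1e-9)
  expect_equal(f1@x0Se, f2@x0Se, tolerance = 1e-9)
  expect_equal(f1@rSquared, f2@rSquared, tolerance = 1e-12)
})

test_that("delta-method x0 intervals cover the truth", {
  set.seed(42)
  x <- rep(c(0, 4, 12, 20), each = 6)
  truth <- 8
  covered <- vapply(seq_len(1000), function(i) {
    y <- 0.1 * (x + truth) + rnorm(length(x), 0, 0.02 * mean(0.1 * (x + truth)))
    fit <- fitStandardAddition(x, y)
    abs(fit@x0 - truth) <= 3 * fit@x0Se
  }, logical(1))
  expect_gte(mean(covered), 0.99)
})

test_that("endogenous concentration scales with the dilution chain", {
  fit <- suppressWarnings(fitStandardAddition(c(0, 4, 12, 20),
                                              0.1 * (c(0, 4, 12, 20) + 8.33)))
  conc <- endogenousConcentration(fit, 96)
  expect_equal(conc[["conc"]], 8.33 * 96, tolerance = 1e-9)
  expect_equal(endogenousConcentration(fit, 1)[["conc"]], fit@x0)
  # default BVH-like chain: 12-fold predilution, 20 uL into 162 uL
  expect_equal(dilutionFactor(bvhMatrix(), bvhDesign()), 12 * 162 / 20)
})

test_that("LOD and LOQ scale the measured concentration by 3/SNR and 10/SNR", {
  s <- estimateLodLoq(0.9, 18.3)
  expect_equal(s@lod, 0.9 * 3 / 18.3, tolerance = 1e-12)
  expect_equal(s@loq, 0.9 * 10 / 18.3, tolerance = 1e-12)
  expect_equal(estimateLodLoq(5, 3)@lod, 5)
  for (case in list(c(0.9, 18.3), c(8.2, 167), c(100, 3)))
    expect_equal(estimateLodLoq(case[1], case[2])@loq /
                 estimateLodLoq(case[1], case[2])@lod, 10 / 3,
                 tolerance = 1e-12)
  expect_error(estimateLodLoq(1, 0), "positive")
})

test_that("accuracy, precision, recovery, matrix effect and stability follow
           their defining formulas", {
  expect_equal(accuracyPercent(28, 8, 20), 100)
  expect_equal(accuracyPercent(26, 8, 20), 90)
  expect_error(accuracyPercent(26, 8, 0), "positive")

  expect_equal(precisionRsd(c(10, 10, 10)), 0)
  expect_equal(precisionRsd(c(9, 10, 11)), 10)
  expect_equal(precisionRsd(5 * c(9, 10, 11)), 10)  # scale invariance
  expect_error(precisionRsd(c(1, 2)), "design error")
  expect_error(precisionRsd(c(-1, 0, 1)), "zero mean")

  expect_equal(recoveryPercent(100, 195, 200), 95)
  expect_equal(recoveryPercent(100, 200, 200), 100)
  expect_error(recoveryPercent(100, 150, 100), "undefined")

  expect_equal(matrixEffectPercent(100, 200, 200), 50)
  expect_equal(matrixEffectPercent(0, 200, 200), 100)
  expect_error(matrixEffectPercent(1, 2, 0), "positive")

  expect_equal(stabilityPercentChange(100, 85.23), 14.77)
  expect_equal(stabilityPercentChange(100, 86.44), 13.56)
  expect_equal(stabilityPercentChange(100, 100), 0)
  expect_error(stabilityPercentChange(0, 1), "positive")
})

test_that("robustness CVs vanish for identical areas", {
  tab <- do.call(rbind, lapply(1:3, function(i)
    data.frame(sample_id = paste0("s", i), design_role = "robustness",
               spike_level = 0, replicate = i, activity = 2000,
               channel = c("analyte", "IS1", "IS2"), area = c(100, 50, 20),
               height = 1, local_noise = 1)))
  expect_equal(unname(robustnessCv(tab)), c(0, 0))
  expect_error(robustnessCv(tab[1:3, ]), "at least 2")
})
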