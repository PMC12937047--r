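test_that("oligomer formulas assemble by monosaccharide bookkeeping", {
  expect_equal(formulaString(buildFormula(OligomerSpec(2, "delta_unsaturated"))),
               "C28H42N2O22")
  expect_equal(formulaString(buildFormula(OligomerSpec(2, "saturated"))),
               "C28H44N2O23")
  # acid-hydrolysis deacetylated dimer: C14H23NO12 - C2H2O
  expect_equal(formulaString(buildFormula(
    OligomerSpec(1, "saturated", nDeacetylated = 1))), "C12H21NO11")
  expect_equal(formulaString(buildFormula(OligomerSpec(1, "saturated"))),
               "C14H23NO12")
  expect_equal(elementCount(buildFormula(OligomerSpec(2, "delta_unsaturated"))),
               28L)
  expect_error(OligomerSpec(2, "saturated", nDeacetylated = 3),
               "nDeacetylated")
  expect_error(OligomerSpec(2, "saturated", provenance = "RSK"), "unsaturated")
})

test_that("monoisotopic masses agree with a per-element hand sum", {
  f <- parseFormula("C28H42N2O22")
  expect_equal(monoisotopicMass(f), oracleMass(28, 42, 2, 22),
               tolerance = 1e-10)
  expect_equal(monoisotopicMass(f), 758.2229, tolerance = 1e-4)
  expect_equal(monoisotopicMass(MolecularFormula()), 0)
  # strict 13C additivity: k mass defects, no rounding drift
  for (k in c(1, 14, 28))
    expect_equal(monoisotopicMass(f, k) - monoisotopicMass(f),
                 k * (13.0033548 - 12), tolerance = 1e-12)
  expect_error(monoisotopicMass(f, 29), "n13C")
})

test_that("nominal deprotonated m/z reproduces the MRM precursor table", {
  unsat <- buildFormula(OligomerSpec(2, "delta_unsaturated"))
  sat <- buildFormula(OligomerSpec(2, "saturated"))
  expect_equal(ionMz(unsat, mode = "nominal"), 757)
  expect_equal(ionMz(unsat, n13C = 28, mode = "nominal"), 785)
  expect_equal(ionMz(sat, n13C = 14, mode = "nominal"), 789)
  # hydrolase vs lyase product: one water, +18 nominal
  expect_equal(round(monoisotopicMass(sat) - monoisotopicMass(unsat), 4),
               18.0106)
})

test_that("exact m/z matches the six printed high-resolution values within 3 mDa", {
  unsat <- buildFormula(OligomerSpec(2, "delta_unsaturated"))
  deacDimer <- buildFormula(OligomerSpec(1, "saturated", nDeacetylated = 1))
  dimer <- buildFormula(OligomerSpec(1, "saturated"))
  glca <- parseFormula("C6H10O7")
  observed <- list(
    list(ionMz(unsat), 757.2169),
    list(ionMz(unsat, n13C = 28), 785.3071),
    list(ionMz(deacDimer, n13C = 12), 366.1447),
    list(ionMz(dimer, n13C = 14), 410.1614),
    list(ionMz(dimer, n13C = 13), 409.1594),
    list(ionMz(glca, n13C = 6), 199.055))
  for (pair in observed)
    expect_lt(abs(pair[[1]] - pair[[2]]), 3e-3)
  # and against the independent hand sum
  expect_equal(ionMz(deacDimer, n13C = 12),
               oracleMz(12, 21, 1, 11, n13C = 12), tolerance = 1e-10)
})

test_that("m/z respects charge-state and isotopologue grid structure", {
  f <- buildFormula(OligomerSpec(2, "delta_unsaturated"))
  expect_gt(ionMz(f, charge = 1), ionMz(f, charge = 2))
  # unit-mass grid: nominal m/z of k-13C species = unlabeled + k (z = 1)
  base <- ionMz(f, mode = "nominal")
  for (k in 0:28)
    expect_equal(ionMz(f, n13C = k, mode = "nominal"), base + k)
  expect_error(ionMz(f, charge = 0), "charge")
  expect_error(ionMz(MolecularFormula(C = 1), charge = 1), "protons")
})

test_that("saturated/unsaturated mass gap is one water for any length", {
  for (n in c(1, 2, 3, 5)) {
    d <- monoisotopicMass(buildFormula(OligomerSpec(n, "saturated"))) -
      monoisotopicMass(buildFormula(OligomerSpec(n, "delta_unsaturated")))
    expect_equal(d, oracleMass(H = 2, O = 1), tolerance = 1e-10)
  }
})

test_that("formula string parsing round-trips", {
  for (s in c("C28H42N2O22", "C6H10O7", "C14H21NO11", "C20H29NO17"))
    expect_equal(formulaString(parseFormula(s)), s)
  expect_error(parseFormula("C6H12S"), "parse")
})
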