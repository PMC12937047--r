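tetramer <- OligomerSpec(2, "delta_unsaturated")

test_that("a fully labeled scheme collapses the envelope to all-13C", {
  env <- envelopeTable(labelEnvelope(tetramer, LabelingScheme(1, 0, 0)))
  expect_equal(nrow(env), 1L)
  expect_equal(env$n13C, 28L)
  expect_equal(env$probability, 1)
  expect_equal(env$rel_abundance, 100)
})

test_that("a 1:1 feed has support on the 6a + 2b unit grid", {
  env <- envelopeTable(labelEnvelope(tetramer,
                                     LabelingScheme(0.5, 0.3, 0),
                                     truncation = 0))
  grid <- sort(unique(as.vector(outer(6 * (0:4), 2 * (0:2), `+`))))
  expect_setequal(env$n13C, grid)
})

test_that("envelope probabilities form a proper distribution and base-peak
           scaling is idempotent", {
  for (sch in list(LabelingScheme(1, 0.13, 0.007),
                   LabelingScheme(0.5, 0.5, 0.0067),
                   LabelingScheme(0.8, 0.2, 0.02))) {
    env <- envelopeTable(labelEnvelope(tetramer, sch, truncation = 0))
    expect_equal(sum(env$probability), 1, tolerance = 1e-9)
    expect_equal(max(env$rel_abundance), 100)
    rescaled <- 100 * env$rel_abundance / max(env$rel_abundance)
    expect_equal(rescaled, env$rel_abundance)
    expect_false(is.unsorted(env$n13C))
  }
  expect_error(labelEnvelope(tetramer, LabelingScheme(1, 0, 0), truncation = 1),
               "truncation")
})

test_that("analytic envelope matches a Monte-Carlo simulation of the unit
           labeling model", {
  set.seed(401)
  for (par in list(c(1, 0.129, 0.0067), c(0.5, 0.5, 0.01))) {
    sch <- LabelingScheme(par[1], par[2], par[3])
    p <- denseEnvelope(labelEnvelope(tetramer, sch, truncation = 0), 28)
    phat <- oracleEnvelopeMC(par[1], par[2], par[3], n = 1e5)
    expect_lt(tvDistance(p, phat), 0.02)
  }
})

test_that("fragment 12C partitioning is hypergeometric", {
  # one 12C in the 14-carbon dimer: 6/14 in the GlcA fragment, 8/14 lost
  part <- fragmentLabelDistribution(14, 1, 6)
  expect_equal(unname(part@distribution),
               unname(c(oracleFragmentSplit(14, 1, 6))), tolerance = 1e-12)
  expect_equal(part@distribution[["1"]], 6 / 14)
  expect_equal(part@distribution[["0"]], 8 / 14)
  # no 12C to place
  expect_equal(fragmentLabelDistribution(28, 0, 20)@distribution, c("0" = 1))
  # 2 of 4 carbons retained, 2 parent 12C: brute-force over C(4,2) placements
  expect_equal(unname(fragmentLabelDistribution(4, 2, 2)@distribution),
               unname(c(oracleFragmentSplit(4, 2, 2))), tolerance = 1e-12)
  expect_error(fragmentLabelDistribution(4, 5, 2), "parentN12C")
  expect_error(fragmentLabelDistribution(4, 2, 5), "fragmentCarbons")
})

test_that("fragment partition mean obeys the hypergeometric identity", {
  cases <- expand.grid(parent = c(14, 28), n12 = c(1, 2, 5), frag = c(6, 8))
  for (i in seq_len(nrow(cases))) {
    p <- cases$parent[i]; n12 <- cases$n12[i]; fr <- cases$frag[i]
    expect_equal(partitionMean(fragmentLabelDistribution(p, n12, fr)),
                 n12 * fr / p, tolerance = 1e-12)
  }
})

test_that("an unlabeled acetyl splits 1:1 between fragments keeping one of
           two acetyls", {
  # acetyl-level partition: 2 acetyl groups, 1 unlabeled, fragment keeps 1;
  # this is the origin of the +/-2 Da product-ion doublets
  part <- fragmentLabelDistribution(2, 1, 1)
  expect_equal(unname(part@distribution), c(0.5, 0.5))
})

test_that("closed-form parameter inversion round-trips through the forward
           model", {
  sch <- fitLabelingParameters(30.1, 18.9, nCarbons = 28, nAcetylGroups = 2)
  expect_equal(sch@fUnit, 1)
  expect_equal(sch@epsilon, 0.0067, tolerance = 0.01)
  env <- envelopeTable(labelEnvelope(tetramer, sch))
  expect_equal(env$rel_abundance[env$n13C == 26], 30.1, tolerance = 1e-6)
  expect_equal(env$rel_abundance[env$n13C == 27], 18.9, tolerance = 1e-6)
  # base peak is still the all-13C species
  expect_equal(env$n13C[which.max(env$probability)], 28L)
})

test_that("parameter inversion agrees with a two-parameter grid search", {
  target <- c(30.1, 18.9)
  qStep <- 0.002; eStep <- 2e-4
  grid <- expand.grid(q = seq(0.02, 0.3, by = qStep),
                      eps = seq(5e-4, 0.02, by = eStep))
  sse <- mapply(function(q, eps) {
    env <- envelopeTable(labelEnvelope(tetramer, LabelingScheme(1, q, eps)))
    r26 <- env$rel_abundance[env$n13C == 26]
    r27 <- env$rel_abundance[env$n13C == 27]
    (r26 - target[1])^2 + (r27 - target[2])^2
  }, grid$q, grid$eps)
  best <- grid[which.min(sse), ]
  sch <- fitLabelingParameters(target[1], target[2], 28, 2)
  # closed form must land within one grid cell of the brute-force optimum
  expect_lt(abs(sch@qAcetyl - best$q), qStep)
  expect_lt(abs(sch@epsilon - best$eps), eStep)
})

test_that("degenerate and invalid satellite abundances are handled", {
  sch <- fitLabelingParameters(0, 0, 28, 2)
  expect_equal(sch@epsilon, 0)
  expect_equal(sch@qAcetyl, 0)
  # a huge single-impurity satellite forces the two-flip term past r2
  expect_error(fitLabelingParameters(0.5, 80, 28, 2), "fit failure")
  expect_error(fitLabelingParameters(-1, 5, 28, 2), "percentages")
})
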