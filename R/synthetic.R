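## Seeded synthetic-data generator.
##
## Generative model per sample s (areas, before chromatogram rendering):
##   E_s = digestionYield(activity) * lognormal(enzymeEfficiencyCv)
##   D_s = lognormal(runDetectorCv)            detector/injection drift
##   eta = lognormal(channelNoiseCv)           per channel
##   analyte ~ R * (C_endog + spike) * E_s * X * M * D_s * eta
##   IS1     ~ R * C_IS1            * E_s * X * M * D_s * eta
##   IS2     ~ R * C_IS2                     * M * D_s * eta
## IS1 is polymeric labeled HA added before workup, so it shares digestion
## (E), extraction (X), ionization (M) and drift (D) with the analyte; IS2 is
## a pre-hydrolyzed tetramer added to the reconstituted extract, so it shares
## only M and D. All lognormal factors have unit mean, so expectations are the
## noise-free algebra and the dual ratio's expectation is affine in spike.

.lnormFactor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)  # unit-mean lognormal
}

#' Create a matrix specification
#'
#' @param name Matrix name.
#' @param trueConc True endogenous HA concentration in the original matrix
#'   (ug/mL).
#' @param predilution Fold predilution in water.
#' @param matrixFactor Ionization matrix factor (1 = none).
#' @param extractionRecovery Workup recovery fraction in (0, 1].
#' @param digestionYieldRef Tetramer yield at the reference enzyme activity.
#' @return A [MatrixSpec-class].
#' @export
MatrixSpec <- function(name, trueConc, predilution, matrixFactor = 1,
                       extractionRecovery = 1, digestionYieldRef = 0.8) {
  new("MatrixSpec", name = name, trueConc = trueConc,
      predilution = predilution, matrixFactor = matrixFactor,
      extractionRecovery = extractionRecovery,
      digestionYieldRef = digestionYieldRef)
}

#' Bovine-vitreous-humor-like default matrix
#'
#' Endogenous 800 ug/mL, 12-fold predilution, strong ionization suppression
#' (factor 0.5323) and near-complete extraction recovery (0.9913).
#'
#' @return A [MatrixSpec-class].
#' @export
bvhMatrix <- function() {
  MatrixSpec("BVH-like", trueConc = 800, predilution = 12,
             matrixFactor = 0.5323, extractionRecovery = 0.9913)
}

#' Human-synovial-fluid-like default matrix
#'
#' Endogenous 1100 ug/mL, 10-fold predilution, mild ionization enhancement
#' (factor 1.1315), extraction recovery 0.9298.
#'
#' @return A [MatrixSpec-class].
#' @export
hsfMatrix <- function() {
  MatrixSpec("HSF-like", trueConc = 1100, predilution = 10,
             matrixFactor = 1.1315, extractionRecovery = 0.9298)
}

#' Create an assay design
#'
#' @param spikeLevels In-assay spike ladder (ug/mL), ascending, starting at 0.
#' @param is1Conc,is2Conc In-assay internal standard concentrations (ug/mL HA
#'   equivalents).
#' @param replicates Replicate curves.
#' @param enzymeActivity Hyaluronidase activity (U/mL).
#' @param dilutionChain List of `c(aliquot, total)` volume pairs after the
#'   predilution (default: 20 uL prediluted matrix into a 162 uL assay).
#' @return An [AssayDesign-class].
#' @export
AssayDesign <- function(spikeLevels, is1Conc = 50 * 40 / 162, is2Conc = 12,
                        replicates = 3, enzymeActivity = 2000,
                        dilutionChain = list(c(20, 162))) {
  new("AssayDesign", spikeLevels = as.numeric(spikeLevels),
      is1Conc = is1Conc, is2Conc = is2Conc,
      replicates = as.integer(replicates), enzymeActivity = enzymeActivity,
      dilutionChain = dilutionChain)
}

#' Default standard-addition designs
#'
#' Spike ladders 0/4/12/20 ug/mL (BVH-like) and 0/8/24/40 ug/mL (HSF-like),
#' IS1 at 50 ug/mL dosed as 40 uL into the 162 uL assay, three replicates,
#' reference enzyme activity 2000 U/mL.
#'
#' @return An [AssayDesign-class].
#' @export
bvhDesign <- function() AssayDesign(c(0, 4, 12, 20))

#' @rdname bvhDesign
#' @export
hsfDesign <- function() AssayDesign(c(0, 8, 24, 40))

#' Create an error model
#'
#' Defaults describe a well-behaved triple-quadrupole run: 1 percent
#' per-channel area CV, 1.5 percent per-sample drift, 5 percent digestion
#' variability, and a baseline noise amplitude that puts the neat
#' signal-to-noise of the endogenous level in the few-hundreds.
#'
#' @param runDetectorCv,channelNoiseCv,enzymeEfficiencyCv Fractional CVs.
#' @param baselineNoiseAmplitude Half peak-to-peak baseline noise (intensity).
#' @param peakWidthSigma Gaussian peak sigma (minutes).
#' @param retentionTimes Named numeric (minutes) for channels `analyte`,
#'   `IS1`, `IS2`. The isotopologues coelute; the saturated IS2 runs slightly
#'   later.
#' @param responseFactor Detector response (area per ug/mL).
#' @return An [ErrorModel-class].
#' @export
ErrorModel <- function(runDetectorCv = 0.015, channelNoiseCv = 0.01,
                       enzymeEfficiencyCv = 0.05,
                       baselineNoiseAmplitude = 8000, peakWidthSigma = 0.05,
                       retentionTimes = c(analyte = 5.6, IS1 = 5.6, IS2 = 5.7),
                       responseFactor = 5e4) {
  new("ErrorModel", runDetectorCv = runDetectorCv,
      channelNoiseCv = channelNoiseCv,
      enzymeEfficiencyCv = enzymeEfficiencyCv,
      baselineNoiseAmplitude = baselineNoiseAmplitude,
      peakWidthSigma = peakWidthSigma, retentionTimes = retentionTimes,
      responseFactor = responseFactor)
}

#' Noise-free error model
#'
#' All CVs and the baseline amplitude zero: the generator becomes exactly
#' invertible by the quantification formulas.
#'
#' @return An [ErrorModel-class].
#' @export
zeroErrorModel <- function() {
  ErrorModel(runDetectorCv = 0, channelNoiseCv = 0, enzymeEfficiencyCv = 0,
             baselineNoiseAmplitude = 0)
}

#' Digestion yield as a function of enzyme activity
#'
#' Saturating (Michaelis-type) map, normalized so that the yield at the
#' reference activity equals `yieldRef`:
#' `E(act) = yieldRef * [act / (K + act)] / [ref / (K + ref)]`.
#' With the default half-saturation constant K = 1000 U/mL the three
#' robustness activities 1000/2000/5000 U/mL give yields 0.6/0.8/1.0 for
#' `yieldRef = 0.8` -- a 50 percent spread.
#'
#' @param activity Enzyme activity (U/mL).
#' @param yieldRef Yield at `referenceActivity`.
#' @param K Half-saturation constant (U/mL).
#' @param referenceActivity Reference activity (U/mL).
#' @return Yield fraction.
#' @export
digestionYield <- function(activity, yieldRef = 0.8, K = 1000,
                           referenceActivity = 2000) {
  stopifnot(all(activity > 0))
  yieldRef * (activity / (K + activity)) /
    (referenceActivity / (K + referenceActivity))
}

#' In-assay endogenous concentration implied by a matrix and design
#'
#' @param matrix A [MatrixSpec-class].
#' @param design An [AssayDesign-class].
#' @return ug/mL in the assay.
#' @export
endogenousInAssay <- function(matrix, design) {
  matrix@trueConc / dilutionFactor(matrix, design)
}

#' Cumulative dilution factor from original matrix to assay
#'
#' Predilution times the product of `total/aliquot` over the dilution chain;
#' multiplies the SAM x-intercept back to original-matrix units.
#'
#' @param matrix A [MatrixSpec-class].
#' @param design An [AssayDesign-class].
#' @return Positive scalar (97.2 for the default BVH-like chain).
#' @export
dilutionFactor <- function(matrix, design) {
  matrix@predilution *
    prod(vapply(design@dilutionChain, function(p) p[2] / p[1], numeric(1)))
}

.emptyAreaTable <- function() {
  data.frame(sample_id = character(), design_role = character(),
             spike_level = numeric(), replicate = integer(),
             activity = numeric(), channel = character(), area = numeric(),
             height = numeric(), local_noise = numeric())
}

.areaRows <- function(id, role, spike, replicate, activity, areas, errors) {
  height <- areas / (errors@peakWidthSigma * sqrt(2 * pi))
  data.frame(sample_id = id, design_role = role, spike_level = spike,
             replicate = replicate, activity = activity,
             channel = c("analyte", "IS1", "IS2"), area = unname(areas),
             height = unname(height),
             local_noise = errors@baselineNoiseAmplitude)
}

#' Simulate a standard-addition peak-area table
#'
#' Draws the generative model above for every spike level and replicate.
#'
#' @param matrix A [MatrixSpec-class].
#' @param design An [AssayDesign-class].
#' @param errors An [ErrorModel-class].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param role Design role recorded in the table.
#' @param concScale Multiplier on the endogenous concentration (used by the
#'   freeze-thaw generator).
#' @return Area table `data.frame` with columns `sample_id`, `design_role`,
#'   `spike_level`, `replicate`, `activity`, `channel`, `area`, `height`,
#'   `local_noise`; three channel rows per sample.
#' @examples
#' tab <- simulateAssay(bvhMatrix(), bvhDesign(), ErrorModel(), seed = 1)
#' head(tab)
#' @export
simulateAssay <- function(matrix, design, errors = ErrorModel(), seed = NULL,
                          role = "SAM_level", concScale = 1) {
  stopifnot(is(matrix, "MatrixSpec"), is(design, "AssayDesign"),
            is(errors, "ErrorModel"))
  validObject(matrix); validObject(design); validObject(errors)
  if (!is.null(seed)) set.seed(seed)
  c0 <- endogenousInAssay(matrix, design) * concScale
  X <- matrix@extractionRecovery
  M <- matrix@matrixFactor
  R <- errors@responseFactor
  Eref <- digestionYield(design@enzymeActivity,
                         yieldRef = matrix@digestionYieldRef)
  out <- list()
  for (rep in seq_len(design@replicates)) {
    for (spike in design@spikeLevels) {
      E <- Eref * .lnormFactor(1, errors@enzymeEfficiencyCv)
      D <- .lnormFactor(1, errors@runDetectorCv)
      eta <- .lnormFactor(3, errors@channelNoiseCv)
      areas <- c(
        analyte = R * (c0 + spike) * E * X * M * D * eta[1],
        IS1     = R * design@is1Conc * E * X * M * D * eta[2],
        IS2     = R * design@is2Conc * M * D * eta[3])
      id <- sprintf("%s_r%d_s%g", role, rep, spike)
      out[[length(out) + 1L]] <-
        .areaRows(id, role, spike, rep, design@enzymeActivity, areas, errors)
    }
  }
  do.call(rbind, out)
}

#' Simulate the A/B/C/D recovery and matrix-effect aliquots
#'
#' Role A: unspiked matrix through the full workup. Role B: spiked with HA at
#' the endogenous-equivalent level before workup (spike experiences digestion,
#' extraction and ionization). Role C: processed unspiked, then spiked after
#' workup with pre-hydrolyzed tetramer (ionization only). Role D: neat
#' standard, no matrix and no workup. The spike material for C and D is
#' hydrolyzed under reference conditions, so with the recovery and
#' matrix-effect formulas the estimators converge to `extractionRecovery` and
#' `matrixFactor`.
#'
#' @inheritParams simulateAssay
#' @param replicates Aliquots per role.
#' @return Area table with `design_role` in `A`, `B`, `C`, `D`.
#' @export
makeValidationSet <- function(matrix, design, errors = ErrorModel(),
                              seed = NULL, replicates = design@replicates) {
  stopifnot(is(matrix, "MatrixSpec"), is(design, "AssayDesign"),
            is(errors, "ErrorModel"))
  if (!is.null(seed)) set.seed(seed)
  c0 <- endogenousInAssay(matrix, design)
  X <- matrix@extractionRecovery
  M <- matrix@matrixFactor
  R <- errors@responseFactor
  Eref <- digestionYield(design@enzymeActivity,
                         yieldRef = matrix@digestionYieldRef)
  out <- list()
  for (rep in seq_len(replicates)) {
    E <- Eref * .lnormFactor(1, errors@enzymeEfficiencyCv)
    for (role in c("A", "B", "C", "D")) {
      D <- .lnormFactor(1, errors@runDetectorCv)
      eta <- .lnormFactor(3, errors@channelNoiseCv)
      analyte <- switch(role,
        A = R * c0 * E * X * M,
        B = R * (c0 + c0) * E * X * M,
        C = R * (c0 * E * X + c0 * Eref) * M,  # endogenous + post-workup spike
        D = R * c0 * Eref)
      is1 <- switch(role,
        D = R * design@is1Conc * Eref,
        R * design@is1Conc * E * X * M)
      is2 <- switch(role,
        D = R * design@is2Conc,
        R * design@is2Conc * M)
      areas <- c(analyte = analyte * D * eta[1], IS1 = is1 * D * eta[2],
                 IS2 = is2 * D * eta[3])
      id <- sprintf("val_%s_r%d", role, rep)
      out[[length(out) + 1L]] <-
        .areaRows(id, role, 0, rep, design@enzymeActivity, areas, errors)
    }
  }
  do.call(rbind, out)
}

#' Simulate the enzyme-activity robustness series
#'
#' Neat HA aliquots digested at several enzyme activities; the digestion
#' factor is shared by analyte and IS1 within each sample, which is the
#' premise the normalized/unnormalized CV comparison tests.
#'
#' @inheritParams simulateAssay
#' @param activities Enzyme activities (U/mL).
#' @param replicates Aliquots per activity.
#' @param haConc In-assay HA-equivalent concentration of the digested aliquot
#'   (default: 100 ug/mL through the standard 20-into-162 uL chain).
#' @return Area table with `design_role = "robustness"` and the `activity`
#'   column filled.
#' @export
makeRobustnessSet <- function(matrix, design, errors = ErrorModel(),
                              activities = c(1000, 2000, 5000),
                              replicates = 3, haConc = 100 * 20 / 162,
                              seed = NULL) {
  stopifnot(length(activities) >= 1)
  if (!is.null(seed)) set.seed(seed)
  R <- errors@responseFactor
  out <- list()
  for (act in activities) {
    Eact <- digestionYield(act, yieldRef = matrix@digestionYieldRef)
    for (rep in seq_len(replicates)) {
      E <- Eact * .lnormFactor(1, errors@enzymeEfficiencyCv)
      D <- .lnormFactor(1, errors@runDetectorCv)
      eta <- .lnormFactor(3, errors@channelNoiseCv)
      areas <- c(analyte = R * haConc * E * D * eta[1],
                 IS1 = R * design@is1Conc * E * D * eta[2],
                 IS2 = R * design@is2Conc * D * eta[3])
      id <- sprintf("rob_a%g_r%d", act, rep)
      out[[length(out) + 1L]] <-
        .areaRows(id, "robustness", 0, rep, act, areas, errors)
    }
  }
  do.call(rbind, out)
}

#' Simulate the freeze-thaw stability set
#'
#' The endogenous concentration decays by `perCycleLoss` per cycle before a
#' full standard-addition table is generated, so the downstream pipeline
#' measures a `100 * (1 - (1 - perCycleLoss)^cycles)` percent decrease.
#'
#' @inheritParams simulateAssay
#' @param cycles Number of freeze-thaw cycles.
#' @param perCycleLoss Fractional analyte loss per cycle.
#' @return Area table with `design_role = "freeze_thaw"`.
#' @export
makeFreezeThawSet <- function(matrix, design, errors = ErrorModel(),
                              cycles = 2, perCycleLoss = 0.075, seed = NULL) {
  stopifnot(cycles >= 0, perCycleLoss >= 0, perCycleLoss < 1)
  simulateAssay(matrix, design, errors, seed = seed, role = "freeze_thaw",
                concScale = (1 - perCycleLoss)^cycles)
}

#' Render MRM chromatogram traces from an area table
#'
#' Each sample/channel becomes a Gaussian peak of the stated area and width at
#' the channel's retention time, on a baseline with additive uniform noise of
#' the stated amplitude. Trapezoidal re-integration of a rendered trace
#' recovers the input area within 1 percent.
#'
#' @param table Area table from [simulateAssay()] and relatives.
#' @param errors An [ErrorModel-class] (peak width, retention times, baseline
#'   noise).
#' @param samplingRate Points per second (Hz).
#' @param span Half-width of the rendered time window around the retention
#'   time (minutes).
#' @param seed Optional integer seed for the baseline noise.
#' @return Long `data.frame`: `sample_id`, `channel`, `time_min`,
#'   `intensity`.
#' @export
renderChromatograms <- function(table, errors = ErrorModel(),
                                samplingRate = 5, span = 1, seed = NULL) {
  stopifnot(samplingRate > 0, span > 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / (60 * samplingRate)
  out <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    ch <- table$channel[i]
    rt <- errors@retentionTimes[[ch]]
    t <- seq(rt - span, rt + span, by = dt)
    sig <- table$area[i] * stats::dnorm(t, rt, errors@peakWidthSigma)
    if (errors@baselineNoiseAmplitude > 0)
      sig <- sig + stats::runif(length(t), -errors@baselineNoiseAmplitude,
                                errors@baselineNoiseAmplitude)
    out[[i]] <- data.frame(sample_id = table$sample_id[i], channel = ch,
                           time_min = t, intensity = sig)
  }
  do.call(rbind, out)
}
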