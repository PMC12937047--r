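#' @import methods
NULL

## ---------------------------------------------------------------------------
## Formula layer
## ---------------------------------------------------------------------------

#' Molecular formula of a CHNO compound
#'
#' Element counts for carbon, hydrogen, nitrogen and oxygen. HA-derived
#' oligosaccharides and their fragment ions contain no other elements, so the
#' class is deliberately restricted to CHNO.
#'
#' @slot counts Named integer vector with elements `C`, `H`, `N`, `O`,
#'   all non-negative.
#' @seealso [MolecularFormula()], [buildFormula()], [monoisotopicMass()]
#' @exportClass MolecularFormula
setClass("MolecularFormula", representation(counts = "integer"))

setValidity("MolecularFormula", function(object) {
  cnt <- object@counts
  if (!identical(names(cnt), .ELEMENTS))
    return("counts must be named C, H, N, O (in that order)")
  if (anyNA(cnt) || any(cnt < 0L))
    return("element counts must be non-negative integers")
  TRUE
})

#' Structural description of an HA-derived oligosaccharide
#'
#' Hyaluronic acid is a linear polymer of GlcA-GlcNAc disaccharides. Enzymatic
#' depolymerization yields even-length oligomers: lyase-type enzymes (e.g. a
#' recombinant bacterial hyaluronidase) leave a 4,5-unsaturated uronate at the
#' nonreducing end, hydrolase-type enzymes (e.g. bovine testicular
#' hyaluronidase) and acid hydrolysis give saturated oligomers, 18 Da heavier.
#' Harsh acid hydrolysis additionally deacetylates GlcNAc residues.
#'
#' @slot nDisaccharides Number of GlcA-GlcNAc repeats (tetramer = 2).
#' @slot saturation `"delta_unsaturated"` or `"saturated"`.
#' @slot nDeacetylated Number of GlcNAc residues converted to GlcN
#'   (each removes C2H2O); at most `nDisaccharides`.
#' @slot provenance Informational origin tag: `"RSK"` (lyase, unsaturated),
#'   `"BTH"` or `"acid"` (saturated), or `"unspecified"`.
#' @seealso [OligomerSpec()], [buildFormula()]
#' @exportClass OligomerSpec
setClass("OligomerSpec",
  representation(nDisaccharides = "integer", saturation = "character",
                 nDeacetylated = "integer", provenance = "character"))

setValidity("OligomerSpec", function(object) {
  if (length(object@nDisaccharides) != 1L || is.na(object@nDisaccharides) ||
      object@nDisaccharides < 1L)
    return("nDisaccharides must be a single positive integer (whole disaccharides only)")
  if (!object@saturation %in% c("delta_unsaturated", "saturated"))
    return("saturation must be 'delta_unsaturated' or 'saturated'")
  if (length(object@nDeacetylated) != 1L || is.na(object@nDeacetylated) ||
      object@nDeacetylated < 0L)
    return("nDeacetylated must be a single non-negative integer")
  if (object@nDeacetylated > object@nDisaccharides)
    return("nDeacetylated cannot exceed nDisaccharides")
  if (!object@provenance %in% c("RSK", "BTH", "acid", "unspecified"))
    return("provenance must be one of 'RSK', 'BTH', 'acid', 'unspecified'")
  TRUE
})

## ---------------------------------------------------------------------------
## Isotopologue layer
## ---------------------------------------------------------------------------

#' Carbon-13 labeling model of a biosynthetically labeled oligomer
#'
#' Three-parameter generative model of 13C incorporation when HA is produced by
#' fermentation on labeled glucose: monosaccharide skeletons (6 carbons) derive
#' from the glucose pool all-or-none; acetyl groups (2 carbons) are installed
#' by an acetyltransferase drawing partly on unlabeled carbon sources; and the
#' commercial 13C-glucose itself carries a small per-atom 12C impurity.
#'
#' @slot fUnit Probability a 6-carbon monosaccharide skeleton is labeled.
#' @slot qAcetyl Probability an acetyl group is unlabeled despite a labeled
#'   feed.
#' @slot epsilon Per-atom probability that a carbon inside a labeled unit is
#'   12C (feedstock isotopic impurity).
#' @seealso [LabelingScheme()], [labelEnvelope()], [fitLabelingParameters()]
#' @exportClass LabelingScheme
setClass("LabelingScheme",
  representation(fUnit = "numeric", qAcetyl = "numeric", epsilon = "numeric"))

setValidity("LabelingScheme", function(object) {
  for (s in c("fUnit", "qAcetyl", "epsilon")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(sprintf("%s must be a single value in [0, 1]", s))
  }
  TRUE
})

#' Isotopologue envelope of a labeled ion
#'
#' Probability distribution over the number of 13C atoms in an ion, with the
#' corresponding exact m/z values and abundances relative to the base (most
#' probable) isotopologue.
#'
#' @slot entries `data.frame` with columns `n13C`, `mz`, `probability`,
#'   `rel_abundance` (percent of base peak), sorted by `n13C`.
#' @slot charge Deprotonation count used for the m/z values.
#' @slot truncation Minimum probability retained; entries below it were
#'   dropped after normalization.
#' @seealso [labelEnvelope()], [envelopeTable()]
#' @exportClass IsotopeEnvelope
setClass("IsotopeEnvelope",
  representation(entries = "data.frame", charge = "integer",
                 truncation = "numeric"))

setValidity("IsotopeEnvelope", function(object) {
  e <- object@entries
  need <- c("n13C", "mz", "probability", "rel_abundance")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (nrow(e) && is.unsorted(e$n13C, strictly = TRUE))
    return("entries must be strictly sorted by n13C")
  if (nrow(e) && abs(max(e$rel_abundance) - 100) > 1e-9)
    return("base-peak relative abundance must be 100")
  TRUE
})

#' Partition of residual 12C atoms between a fragment ion and its neutral loss
#'
#' When a precursor carrying a fixed number of 12C atoms fragments, the 12C
#' atoms are distributed hypergeometrically between the retained fragment and
#' the neutral loss (carbon positions are exchangeable under the labeling
#' model). This is the model behind the +/- 1 and +/- 2 Da product-ion
#' doublets of partially labeled precursors.
#'
#' @slot parentCarbons,fragmentCarbons,parentN12C Carbon bookkeeping.
#' @slot distribution Named numeric: probability of each possible 12C count in
#'   the fragment; sums to 1.
#' @seealso [fragmentLabelDistribution()]
#' @exportClass FragmentPartition
setClass("FragmentPartition",
  representation(parentCarbons = "integer", fragmentCarbons = "integer",
                 parentN12C = "integer", distribution = "numeric"))

setValidity("FragmentPartition", function(object) {
  if (abs(sum(object@distribution) - 1) > 1e-9)
    return("distribution must sum to 1")
  if (is.null(names(object@distribution)))
    return("distribution must be named by fragment 12C count")
  TRUE
})

## ---------------------------------------------------------------------------
## MRM channel layer
## ---------------------------------------------------------------------------

#' A single MRM transition (precursor -> product channel)
#'
#' @slot label Channel name (e.g. `"analyte"`, `"IS1"`, `"IS2"`).
#' @slot precursorMz,productMz Nominal m/z of the monitored pair.
#' @slot ce,dp,cxp Collision energy, declustering potential, collision exit
#'   potential (signed volts, informational).
#' @slot productFormula [MolecularFormula-class] of the product ion (neutral
#'   form); carbon count drives label partitioning in interference checks.
#' @slot productN13C Number of 13C atoms in the nominal product ion.
#' @seealso [MRMTransition()], [defaultTransitions()], [checkInterference()]
#' @exportClass MRMTransition
setClass("MRMTransition",
  representation(label = "character", precursorMz = "numeric",
                 productMz = "numeric", ce = "numeric", dp = "numeric",
                 cxp = "numeric", productFormula = "MolecularFormula",
                 productN13C = "integer"))

setValidity("MRMTransition", function(object) {
  if (!(object@precursorMz > object@productMz && object@productMz > 0))
    return("must satisfy precursorMz > productMz > 0")
  TRUE
})

#' A quantification species: oligomer + labeling scheme + assigned channel
#'
#' Bundles what [checkInterference()] needs to know about one molecular species
#' in the assay: its structure, its labeling model, the channel it is meant to
#' be measured on, and the product-ion formulas it can generate on
#' fragmentation.
#'
#' @slot label Species name.
#' @slot spec [OligomerSpec-class].
#' @slot scheme [LabelingScheme-class].
#' @slot channel Label of the MRM channel assigned to this species (matches on
#'   that channel are signal, not interference).
#' @slot fragmentFormulas List of [MolecularFormula-class] product-ion
#'   candidates (neutral-form formulas of deprotonated fragments).
#' @seealso [quantSpecies()], [defaultSpeciesSet()]
#' @exportClass QuantSpecies
setClass("QuantSpecies",
  representation(label = "character", spec = "OligomerSpec",
                 scheme = "LabelingScheme", channel = "character",
                 fragmentFormulas = "list"))

#' Result of an MRM cross-talk check
#'
#' @slot flags `data.frame` of confirmed interferences (precursor within
#'   tolerance AND some fragment isotopologue within product tolerance):
#'   columns `species`, `channel`, `n13C`, `precursor_mz`, `precursor_delta`,
#'   `product_matched`.
#' @slot candidates `data.frame` of precursor-level near-misses that the
#'   product-ion check cleared (same columns).
#' @slot precursorTolerance,productTolerance Tolerances used (Da).
#' @seealso [checkInterference()], [isClean()]
#' @exportClass InterferenceReport
setClass("InterferenceReport",
  representation(flags = "data.frame", candidates = "data.frame",
                 precursorTolerance = "numeric", productTolerance = "numeric"))

## ---------------------------------------------------------------------------
## Synthetic-data layer
## ---------------------------------------------------------------------------

#' Description of a biological matrix for the synthetic-assay generator
#'
#' @slot name Matrix name.
#' @slot trueConc True endogenous HA concentration in the original matrix
#'   (ug/mL).
#' @slot predilution Fold dilution in water before the assay (12 for a bovine
#'   vitreous humor-like matrix, 10 for synovial fluid-like).
#' @slot matrixFactor Ionization matrix factor (1 = none, <1 suppression,
#'   >1 enhancement).
#' @slot extractionRecovery Fraction of analyte surviving workup, in (0, 1].
#' @slot digestionYieldRef Tetramer yield of the enzymatic digestion at the
#'   reference enzyme activity, in (0, 1].
#' @seealso [MatrixSpec()], [bvhMatrix()], [hsfMatrix()], [simulateAssay()]
#' @exportClass MatrixSpec
setClass("MatrixSpec",
  representation(name = "character", trueConc = "numeric",
                 predilution = "numeric", matrixFactor = "numeric",
                 extractionRecovery = "numeric", digestionYieldRef = "numeric"))

setValidity("MatrixSpec", function(object) {
  if (object@trueConc <= 0 || object@predilution <= 0 ||
      object@matrixFactor <= 0)
    return("trueConc, predilution and matrixFactor must be positive")
  if (object@extractionRecovery <= 0 || object@extractionRecovery > 1)
    return("extractionRecovery must be in (0, 1]")
  if (object@digestionYieldRef <= 0 || object@digestionYieldRef > 1)
    return("digestionYieldRef must be in (0, 1]")
  TRUE
})

#' Standard-addition assay design
#'
#' @slot spikeLevels In-assay spike concentrations (ug/mL), sorted ascending,
#'   first element 0 (the unspiked portion).
#' @slot is1Conc,is2Conc In-assay concentrations (ug/mL HA equivalents) of the
#'   100 percent-13C internal standard (added before digestion) and the
#'   50 percent-13C pre-hydrolyzed internal standard (added before injection).
#' @slot replicates Replicate curves per design.
#' @slot enzymeActivity Hyaluronidase activity (U/mL); reference is 2000.
#' @slot dilutionChain List of `c(aliquot_volume, total_volume)` pairs applied
#'   after the predilution; converts the in-assay axis back to original-matrix
#'   units.
#' @seealso [AssayDesign()], [bvhDesign()], [hsfDesign()], [dilutionFactor()]
#' @exportClass AssayDesign
setClass("AssayDesign",
  representation(spikeLevels = "numeric", is1Conc = "numeric",
                 is2Conc = "numeric", replicates = "integer",
                 enzymeActivity = "numeric", dilutionChain = "list"))

setValidity("AssayDesign", function(object) {
  s <- object@spikeLevels
  if (length(s) < 1L || s[1] != 0 || is.unsorted(s, strictly = TRUE))
    return("spikeLevels must be strictly ascending and start at 0")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (object@is1Conc <= 0 || object@is2Conc <= 0)
    return("internal standard concentrations must be positive")
  if (object@enzymeActivity <= 0) return("enzymeActivity must be positive")
  ok <- vapply(object@dilutionChain, function(p)
    is.numeric(p) && length(p) == 2L && all(p > 0) && p[2] >= p[1],
    logical(1))
  if (!all(ok))
    return("dilutionChain entries must be c(aliquot, total) with total >= aliquot > 0")
  TRUE
})

#' Stochastic error model for the synthetic generator
#'
#' All area-level noise is multiplicative log-normal with unit mean;
#' chromatogram baselines carry additive uniform noise.
#'
#' @slot runDetectorCv Per-sample detector/injection drift CV.
#' @slot channelNoiseCv Per-channel measurement CV.
#' @slot enzymeEfficiencyCv Per-sample digestion-yield CV (shared by analyte
#'   and IS1, not IS2).
#' @slot baselineNoiseAmplitude Half peak-to-peak baseline noise (intensity).
#' @slot peakWidthSigma Gaussian peak sigma (minutes).
#' @slot retentionTimes Named numeric, minutes per channel.
#' @slot responseFactor Detector response (area per ug/mL).
#' @seealso [ErrorModel()], [zeroErrorModel()], [renderChromatograms()]
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(runDetectorCv = "numeric", channelNoiseCv = "numeric",
                 enzymeEfficiencyCv = "numeric",
                 baselineNoiseAmplitude = "numeric", peakWidthSigma = "numeric",
                 retentionTimes = "numeric", responseFactor = "numeric"))

setValidity("ErrorModel", function(object) {
  if (object@runDetectorCv < 0 || object@channelNoiseCv < 0 ||
      object@enzymeEfficiencyCv < 0 || object@baselineNoiseAmplitude < 0)
    return("CVs and noise amplitudes must be >= 0")
  if (object@peakWidthSigma <= 0) return("peakWidthSigma must be positive")
  if (object@responseFactor <= 0) return("responseFactor must be positive")
  if (!all(c("analyte", "IS1", "IS2") %in% names(object@retentionTimes)))
    return("retentionTimes must name analyte, IS1, IS2")
  TRUE
})

## ---------------------------------------------------------------------------
## Quantification layer
## ---------------------------------------------------------------------------

#' Standard-addition regression fit
#'
#' Ordinary least squares of the dual-normalized response against the in-assay
#' spike concentration; the endogenous in-assay concentration is the negated
#' x-intercept `x0 = -b/a` with a delta-method standard error.
#'
#' @slot slope,intercept OLS coefficients (response per ug/mL; response).
#' @slot rSquared Coefficient of determination.
#' @slot x0,x0Se Endogenous in-assay concentration (ug/mL) and its standard
#'   error.
#' @slot nPoints Number of points fitted.
#' @seealso [fitStandardAddition()], [endogenousConcentration()]
#' @exportClass SAMFit
setClass("SAMFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", x0 = "numeric", x0Se = "numeric",
                 nPoints = "integer"))

setValidity("SAMFit", function(object) {
  if (object@rSquared < 0 || object@rSquared > 1)
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' LOD/LOQ estimate obtained by S/N scaling
#'
#' @slot cMeasured Concentration whose peak gave the S/N (ug/mL).
#' @slot snr Observed signal-to-noise ratio.
#' @slot lod,loq Estimated limits (ug/mL); `loq/lod` is 10/3 by construction.
#' @seealso [estimateLodLoq()]
#' @exportClass SensitivityEstimate
setClass("SensitivityEstimate",
  representation(cMeasured = "numeric", snr = "numeric", lod = "numeric",
                 loq = "numeric"))

#' Bioanalytical validation report
#'
#' @slot endogenous Named numeric: `conc` and `se` in original-matrix ug/mL.
#' @slot sam [SAMFit-class] of the pooled standard-addition curve.
#' @slot samReplicates List of per-replicate [SAMFit-class] objects.
#' @slot accuracy `data.frame`: per spike level, mean accuracy percent and
#'   precision (RSD percent) of the net measured concentrations.
#' @slot recovery,matrixEffect Percent.
#' @slot sensitivity [SensitivityEstimate-class].
#' @slot stability Percent decrease after the freeze-thaw cycles.
#' @slot robustness Named numeric: `cv_unnormalized`, `cv_normalized` percent.
#' @slot thresholds Acceptance bands (list: `accuracy`, `lloq`, `stability`,
#'   percent).
#' @seealso [runPipeline()], [writeReport()]
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(endogenous = "numeric", sam = "SAMFit",
                 samReplicates = "list", accuracy = "data.frame",
                 recovery = "numeric", matrixEffect = "numeric",
                 sensitivity = "SensitivityEstimate", stability = "numeric",
                 robustness = "numeric", thresholds = "list"))

#' Pipeline run configuration
#'
#' @slot matrix [MatrixSpec-class].
#' @slot design [AssayDesign-class].
#' @slot errors [ErrorModel-class].
#' @slot seed Integer RNG seed for the whole run.
#' @slot options List of pipeline options (noise window widths, freeze-thaw
#'   settings, robustness activities, acceptance bands).
#' @seealso [runConfig()], [readRunConfig()], [runPipeline()]
#' @exportClass RunConfig
setClass("RunConfig",
  representation(matrix = "MatrixSpec", design = "AssayDesign",
                 errors = "ErrorModel", seed = "integer", options = "list"))
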