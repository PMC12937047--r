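## MRM acquisition table and channel cross-talk verification.
##
## The assay monitors three channels on a unit-resolution triple quadrupole:
##   analyte  757 -> 554   unlabeled delta-tetramer, loss of the reducing-end
##                         GlcNAc residue (product C20H29NO17)
##   IS1      785 -> 392   all-13C delta-tetramer, fully labeled unsaturated
##                         nonreducing dimer fragment (C14H21NO11, 14 x 13C)
##   IS2      789 -> 199   saturated tetramer with 14 of 28 carbons labeled,
##                         all-13C GlcA fragment (C6H10O7, 6 x 13C)
## The product-ion formulas are structural reconstructions from the observed
## fragment series; their computed exact m/z values reproduce the printed
## observed values, which is the evidence for the assignments.

#' Create an MRM transition
#'
#' @param label Channel name.
#' @param precursorMz,productMz Nominal m/z pair.
#' @param ce,dp,cxp Collision energy, declustering potential, collision exit
#'   potential (informational).
#' @param productFormula [MolecularFormula-class] of the product ion (neutral
#'   form).
#' @param productN13C 13C count of the nominal product ion.
#' @return An [MRMTransition-class].
#' @export
MRMTransition <- function(label, precursorMz, productMz, ce = -48, dp = -100,
                          cxp = -15, productFormula = MolecularFormula(),
                          productN13C = 0) {
  new("MRMTransition", label = label, precursorMz = precursorMz,
      productMz = productMz, ce = ce, dp = dp, cxp = cxp,
      productFormula = productFormula, productN13C = as.integer(productN13C))
}

setMethod("show", "MRMTransition", function(object) {
  cat(sprintf("MRMTransition %-8s %g -> %g (CE %g, DP %g, CXP %g)\n",
              object@label, object@precursorMz, object@productMz,
              object@ce, object@dp, object@cxp))
})

#' The three quantification channels of the assay
#'
#' @return Named list of [MRMTransition-class] objects: `analyte` (757 to
#'   554), `IS1` (785 to 392), `IS2` (789 to 199), all with CE -48, DP -100,
#'   CXP -15.
#' @examples
#' defaultTransitions()$analyte
#' @export
defaultTransitions <- function() {
  list(
    analyte = MRMTransition("analyte", 757, 554,
                            productFormula = parseFormula("C20H29NO17"),
                            productN13C = 0),
    IS1 = MRMTransition("IS1", 785, 392,
                        productFormula = parseFormula("C14H21NO11"),
                        productN13C = 14),
    IS2 = MRMTransition("IS2", 789, 199,
                        productFormula = parseFormula("C6H10O7"),
                        productN13C = 6))
}

#' Fragment-ion formula candidates for an oligomer
#'
#' Glycosidic cleavages of a tetramer retaining the nonreducing end: loss of
#' the reducing-end GlcNAc residue, the nonreducing dimer, and the
#' (nonreducing) uronate monosaccharide. Saturation of the parent carries
#' through to every nonreducing-end fragment.
#'
#' @param spec An [OligomerSpec-class].
#' @return List of [MolecularFormula-class] objects.
#' @export
defaultFragmentFormulas <- function(spec) {
  stopifnot(is(spec, "OligomerSpec"))
  parent <- buildFormula(spec)
  frags <- list()
  glcnacResidue <- MolecularFormula(C = 8, H = 13, N = 1, O = 5)
  if (elementCount(parent, "N") >= 1)          # loss of reducing-end GlcNAc
    frags <- c(frags, list(.formulaSubtract(parent, glcnacResidue)))
  if (spec@nDisaccharides > 1L)                # nonreducing dimer
    frags <- c(frags, list(buildFormula(
      OligomerSpec(1, spec@saturation))))
  uronate <- if (spec@saturation == "delta_unsaturated")
    MolecularFormula(C = 6, H = 8, O = 6) else MolecularFormula(C = 6, H = 10, O = 7)
  c(frags, list(uronate))
}

#' Bundle a species for interference checking
#'
#' @param label Species name.
#' @param spec An [OligomerSpec-class].
#' @param scheme A [LabelingScheme-class].
#' @param channel Label of the channel assigned to this species.
#' @param fragmentFormulas List of [MolecularFormula-class]; defaults to
#'   [defaultFragmentFormulas()].
#' @return A [QuantSpecies-class].
#' @export
quantSpecies <- function(label, spec, scheme, channel,
                         fragmentFormulas = defaultFragmentFormulas(spec)) {
  new("QuantSpecies", label = label, spec = spec, scheme = scheme,
      channel = channel, fragmentFormulas = fragmentFormulas)
}

#' Default three-species system of the assay
#'
#' The analyte (unlabeled unsaturated tetramer), IS1 (fully labeled
#' unsaturated tetramer with the acetyl-heterogeneity/impurity parameters
#' obtained from the satellite-abundance inversion), and IS2 (saturated
#' tetramer from a 1:1 labeled/unlabeled feed, hydrolase-produced, hence
#' +18 Da).
#'
#' @param is1Scheme,is2Scheme Override the labeling schemes.
#' @return List of [QuantSpecies-class] objects named `analyte`, `IS1`,
#'   `IS2`.
#' @export
defaultSpeciesSet <- function(
    is1Scheme = fitLabelingParameters(30.1, 18.9, 28, 2),
    is2Scheme = LabelingScheme(fUnit = 0.5, qAcetyl = 0.5,
                               epsilon = is1Scheme@epsilon)) {
  list(
    analyte = quantSpecies("analyte",
                           OligomerSpec(2, "delta_unsaturated", provenance = "RSK"),
                           LabelingScheme(fUnit = 0), "analyte"),
    IS1 = quantSpecies("IS1",
                       OligomerSpec(2, "delta_unsaturated", provenance = "RSK"),
                       is1Scheme, "IS1"),
    IS2 = quantSpecies("IS2",
                       OligomerSpec(2, "saturated", provenance = "BTH"),
                       is2Scheme, "IS2"))
}

#' Check the MRM channels for isotopologue cross-talk
#'
#' A species interferes with a channel other than its own if (i) one of its
#' precursor isotopologues falls within `precursorTolerance` of the channel's
#' precursor m/z and (ii) at least one isotopologue of one of its fragment
#' ions -- obtained by hypergeometric partitioning of the precursor's residual
#' 12C atoms into the fragment ([fragmentLabelDistribution()]) -- falls within
#' `productTolerance` of the channel's product m/z. Precursor-level hits that
#' the product stage clears are reported separately as candidates.
#'
#' @param species List of [QuantSpecies-class] objects.
#' @param transitions List of [MRMTransition-class]; default
#'   [defaultTransitions()].
#' @param precursorTolerance,productTolerance Match tolerances in Da
#'   (default 0.5, unit-mass resolution).
#' @param truncation Envelope truncation passed to [labelEnvelope()].
#' @return An [InterferenceReport-class]; empty `flags` means the channel
#'   design is clean at the given tolerances.
#' @examples
#' isClean(checkInterference(defaultSpeciesSet()))  # TRUE: the +18 Da design
#' @export
checkInterference <- function(species, transitions = defaultTransitions(),
                              precursorTolerance = 0.5,
                              productTolerance = 0.5, truncation = 1e-3) {
  if (precursorTolerance <= 0 || productTolerance <= 0)
    stop("tolerances must be positive")
  cols <- c("species", "channel", "n13C", "precursor_mz", "precursor_delta",
            "product_matched")
  empty <- data.frame(species = character(), channel = character(),
                      n13C = integer(), precursor_mz = numeric(),
                      precursor_delta = numeric(),
                      product_matched = logical())
  rows <- list()
  for (sp in species) {
    stopifnot(is(sp, "QuantSpecies"))
    if (!length(sp@fragmentFormulas))
      stop("species '", sp@label, "' has no fragment formulas configured")
    env <- envelopeTable(labelEnvelope(sp@spec, sp@scheme,
                                       truncation = truncation))
    parentC <- elementCount(buildFormula(sp@spec), "C")
    for (tr in transitions) {
      if (tr@label == sp@channel) next   # its own channel is signal
      hit <- abs(env$mz - tr@precursorMz) <= precursorTolerance
      for (i in which(hit)) {
        n12 <- parentC - env$n13C[i]
        matched <- FALSE
        for (ff in sp@fragmentFormulas) {
          fc <- elementCount(ff, "C")
          part <- fragmentLabelDistribution(parentC, n12, fc)
          j <- as.integer(names(part@distribution))
          fragMz <- vapply(fc - j, function(k) ionMz(ff, 1, k), numeric(1))
          if (any(abs(fragMz - tr@productMz) <= productTolerance &
                  part@distribution > 0)) {
            matched <- TRUE
            break
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp@label, channel = tr@label, n13C = env$n13C[i],
          precursor_mz = env$mz[i],
          precursor_delta = env$mz[i] - tr@precursorMz,
          product_matched = matched)
      }
    }
  }
  all <- if (length(rows)) do.call(rbind, rows) else empty
  new("InterferenceReport",
      flags = all[all$product_matched, cols, drop = FALSE],
      candidates = all[!all$product_matched, cols, drop = FALSE],
      precursorTolerance = precursorTolerance,
      productTolerance = productTolerance)
}

#' Is an interference report free of confirmed cross-talk?
#'
#' @param report An [InterferenceReport-class].
#' @return Logical.
#' @export
isClean <- function(report) {
  stopifnot(is(report, "InterferenceReport"))
  nrow(report@flags) == 0L
}

#' Confirmed interference flags
#'
#' @param report An [InterferenceReport-class].
#' @return `data.frame` of confirmed species/channel collisions.
#' @export
interferenceFlags <- function(report) {
  stopifnot(is(report, "InterferenceReport"))
  report@flags
}

setMethod("show", "InterferenceReport", function(object) {
  cat(sprintf("InterferenceReport (Q1 tol %.2g Da, Q3 tol %.2g Da): %d flag(s), %d cleared candidate(s)\n",
              object@precursorTolerance, object@productTolerance,
              nrow(object@flags), nrow(object@candidates)))
  if (nrow(object@flags)) print(object@flags, row.names = FALSE)
})
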