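## Molecular-formula arithmetic for HA-derived oligosaccharides.
##
## Building blocks (free monosaccharides):
##   GlcA    C6H10O7
##   GlcNAc  C8H15NO6
## A chain of n disaccharides condenses 2n residues with loss of (2n - 1) H2O.
## Lyase cleavage leaves a 4,5-unsaturated uronate: one further H2O less than
## the hydrolase (saturated) product. Deacetylation removes C2H2O per residue.

.GLCA   <- c(C = 6L, H = 10L, N = 0L, O = 7L)
.GLCNAC <- c(C = 8L, H = 15L, N = 1L, O = 6L)
.H2O    <- c(C = 0L, H = 2L,  N = 0L, O = 1L)
.KETENE <- c(C = 2L, H = 2L,  N = 0L, O = 1L)  # acetyl loss on deacetylation

#' Create a molecular formula
#'
#' @param C,H,N,O Non-negative element counts.
#' @return A [MolecularFormula-class] object.
#' @examples
#' MolecularFormula(C = 28, H = 42, N = 2, O = 22)
#' @export
MolecularFormula <- function(C = 0, H = 0, N = 0, O = 0) {
  counts <- as.integer(c(C, H, N, O))
  names(counts) <- .ELEMENTS
  new("MolecularFormula", counts = counts)
}

#' Parse a Hill-order CHNO formula string
#'
#' @param x String such as `"C28H42N2O22"`.
#' @return A [MolecularFormula-class] object.
#' @examples
#' parseFormula("C14H21NO11")
#' @export
parseFormula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([CHNO])([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (!length(parts) || nchar(x) != sum(attr(m, "match.length")))
    stop("cannot parse formula string: ", x)
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L)
  for (p in parts) {
    el <- substr(p, 1L, 1L)
    n <- substring(p, 2L)
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  MolecularFormula(counts["C"], counts["H"], counts["N"], counts["O"])
}

#' Element count accessor
#'
#' @param formula A [MolecularFormula-class].
#' @param element One of `"C"`, `"H"`, `"N"`, `"O"`.
#' @return Integer count.
#' @export
elementCount <- function(formula, element = "C") {
  stopifnot(is(formula, "MolecularFormula"), element %in% .ELEMENTS)
  unname(formula@counts[element])
}

#' Hill-order formula string
#'
#' @param formula A [MolecularFormula-class].
#' @return Character scalar, e.g. `"C28H42N2O22"`.
#' @export
formulaString <- function(formula) {
  stopifnot(is(formula, "MolecularFormula"))
  cnt <- formula@counts
  paste0(vapply(.ELEMENTS, function(el) {
    n <- cnt[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula:", formulaString(object),
      sprintf("(monoisotopic %.4f Da)\n", monoisotopicMass(object)))
})

.formulaAdd <- function(a, b) {
  MolecularFormula(a@counts["C"] + b@counts["C"], a@counts["H"] + b@counts["H"],
                   a@counts["N"] + b@counts["N"], a@counts["O"] + b@counts["O"])
}

.formulaSubtract <- function(a, b) {
  d <- a@counts - b@counts
  if (any(d < 0L))
    stop("formula subtraction would give negative element counts")
  MolecularFormula(d["C"], d["H"], d["N"], d["O"])
}

#' Describe an HA-derived oligosaccharide
#'
#' @param nDisaccharides Number of GlcA-GlcNAc repeats (tetramer = 2). Only
#'   whole disaccharides are representable: both enzymes cleave at
#'   disaccharide periodicity.
#' @param saturation `"delta_unsaturated"` (lyase product) or `"saturated"`
#'   (hydrolase/acid product).
#' @param nDeacetylated Number of GlcNAc residues converted to GlcN.
#' @param provenance Informational: `"RSK"`, `"BTH"`, `"acid"` or
#'   `"unspecified"`. `"RSK"` implies an unsaturated product, `"BTH"`/`"acid"`
#'   a saturated one; a mismatch is an error.
#' @return An [OligomerSpec-class] object.
#' @examples
#' OligomerSpec(2, "delta_unsaturated")            # the analyte tetramer
#' OligomerSpec(1, "saturated", nDeacetylated = 1) # acid-hydrolysis GlcA-GlcN
#' @export
OligomerSpec <- function(nDisaccharides, saturation = c("delta_unsaturated",
                         "saturated"), nDeacetylated = 0,
                         provenance = "unspecified") {
  saturation <- match.arg(saturation)
  if (provenance == "RSK" && saturation != "delta_unsaturated")
    stop("RSK (lyase) products are delta-unsaturated")
  if (provenance %in% c("BTH", "acid") && saturation != "saturated")
    stop(provenance, " products are saturated")
  new("OligomerSpec", nDisaccharides = as.integer(nDisaccharides),
      saturation = saturation, nDeacetylated = as.integer(nDeacetylated),
      provenance = provenance)
}

setMethod("show", "OligomerSpec", function(object) {
  cat(sprintf("OligomerSpec: %d-mer (%d disaccharides), %s%s [%s]\n",
              2L * object@nDisaccharides, object@nDisaccharides,
              object@saturation,
              if (object@nDeacetylated > 0L)
                sprintf(", %d deacetylated", object@nDeacetylated) else "",
              object@provenance))
})

#' Assemble the molecular formula of an HA oligomer
#'
#' Condenses `nDisaccharides` GlcA + GlcNAc pairs with loss of
#' `2 * nDisaccharides - 1` waters (free reducing end, no derivatization),
#' subtracts one further water for the 4,5-unsaturated (lyase) product, and
#' removes C2H2O per deacetylated residue.
#'
#' @param spec An [OligomerSpec-class].
#' @return A [MolecularFormula-class].
#' @examples
#' formulaString(buildFormula(OligomerSpec(2, "delta_unsaturated"))) # C28H42N2O22
#' @export
buildFormula <- function(spec) {
  stopifnot(is(spec, "OligomerSpec"))
  validObject(spec)
  n <- spec@nDisaccharides
  f <- MolecularFormula(n * (.GLCA["C"] + .GLCNAC["C"]),
                        n * (.GLCA["H"] + .GLCNAC["H"]),
                        n * (.GLCA["N"] + .GLCNAC["N"]),
                        n * (.GLCA["O"] + .GLCNAC["O"]))
  nWater <- 2L * n - 1L + (spec@saturation == "delta_unsaturated")
  f <- .formulaSubtract(f, MolecularFormula(0, 2 * nWater, 0, nWater))
  if (spec@nDeacetylated > 0L) {
    k <- spec@nDeacetylated
    f <- .formulaSubtract(f, MolecularFormula(2 * k, 2 * k, 0, k))
  }
  f
}

#' Number of acetyl groups carried by an oligomer
#'
#' One acetyl per GlcNAc residue, i.e. `nDisaccharides - nDeacetylated`.
#'
#' @param spec An [OligomerSpec-class].
#' @return Integer.
#' @export
nAcetylGroups <- function(spec) {
  stopifnot(is(spec, "OligomerSpec"))
  spec@nDisaccharides - spec@nDeacetylated
}

#' Monoisotopic mass with optional 13C substitution
#'
#' Sum of monoisotopic atomic masses with `n13C` carbons replaced by 13C.
#' Exactly additive: `mass(n13C) - mass(0) = n13C * (13.0033548 - 12)`.
#'
#' @param formula A [MolecularFormula-class].
#' @param n13C Number of 13C atoms; at most the carbon count.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(parseFormula("C28H42N2O22"))      # 758.2229
#' monoisotopicMass(parseFormula("C28H42N2O22"), 28)  # + 28 mass defects
#' @export
monoisotopicMass <- function(formula, n13C = 0) {
  stopifnot(is(formula, "MolecularFormula"))
  n13C <- as.integer(n13C)
  if (n13C < 0L || n13C > formula@counts[["C"]])
    stop("n13C must be between 0 and the carbon count (",
         formula@counts[["C"]], ")")
  sum(formula@counts * .ELEMENT_MASS) + n13C * .MASS_DEFECT_13C
}

#' m/z of a deprotonated ([M - zH]z-) ion
#'
#' Negative-mode m/z: `(M - z * m_proton) / z`, i.e. the electron mass is
#' retained by the anion. `mode = "nominal"` rounds the exact value to the
#' nearest integer (unit-mass grid of a triple quadrupole).
#'
#' @param formula A [MolecularFormula-class].
#' @param charge Deprotonation count z (positive integer, at most the H
#'   count).
#' @param n13C Number of 13C atoms.
#' @param mode `"exact"` or `"nominal"`.
#' @return m/z value.
#' @examples
#' ionMz(parseFormula("C28H42N2O22"), mode = "nominal")            # 757
#' ionMz(parseFormula("C28H42N2O22"), n13C = 28, mode = "nominal") # 785
#' @export
ionMz <- function(formula, charge = 1, n13C = 0, mode = c("exact", "nominal")) {
  mode <- match.arg(mode)
  charge <- as.integer(charge)
  if (charge < 1L)
    stop("charge must be a positive deprotonation count (neutral has no m/z)")
  if (charge > formula@counts[["H"]])
    stop("cannot remove more protons than hydrogens present")
  mz <- (monoisotopicMass(formula, n13C) - charge * .MASS_PROTON) / charge
  if (mode == "nominal") round(mz) else mz
}
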