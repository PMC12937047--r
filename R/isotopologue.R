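## 13C isotopologue model for biosynthetically labeled HA oligomers.
##
## Labeling is unit-level, not per-atom: a 6-carbon monosaccharide skeleton
## derives all-or-none from the glucose pool (probability fUnit), and each
## 2-carbon acetyl group is installed all-or-none from an acetyl pool that can
## be unlabeled even under a fully labeled feed (probability qAcetyl).
## Within labeled units each carbon independently reverts to 12C with the
## feedstock impurity probability epsilon. A pure per-atom binomial cannot
## reproduce the observed support (multiples of 6 and 2 for a 50 percent feed;
## -1/-2 Da satellites for a 100 percent feed) -- the unit structure is the
## model.

#' Create a labeling scheme
#'
#' @param fUnit Probability a monosaccharide skeleton (6 carbons) is labeled.
#' @param qAcetyl Probability an acetyl group (2 carbons) is unlabeled despite
#'   a labeled feed.
#' @param epsilon Per-atom 12C probability inside labeled units (feedstock
#'   isotopic impurity).
#' @return A [LabelingScheme-class] object.
#' @examples
#' LabelingScheme(fUnit = 1, qAcetyl = 0.123, epsilon = 0.0067) # IS1-like
#' LabelingScheme(fUnit = 0.5, qAcetyl = 0.5)                   # 1:1 feed
#' @export
LabelingScheme <- function(fUnit = 1, qAcetyl = 0, epsilon = 0) {
  new("LabelingScheme", fUnit = fUnit, qAcetyl = qAcetyl, epsilon = epsilon)
}

setMethod("show", "LabelingScheme", function(object) {
  cat(sprintf("LabelingScheme: f(unit) = %.4g, q(acetyl unlabeled) = %.4g, epsilon = %.4g\n",
              object@fUnit, object@qAcetyl, object@epsilon))
})

#' Isotopologue envelope of a labeled oligomer ion
#'
#' Exact enumeration of the labeling model: over the number of labeled
#' 6-carbon skeletons `a` (binomial in `fUnit`), the number of labeled acetyl
#' groups `b` (binomial in `1 - qAcetyl`), and binomial 12C impurity flips
#' among the `6a + 2b` labeled carbons. The 13C count of a molecule is the
#' number of labeled carbons minus the impurity flips; m/z values come from
#' [ionMz()].
#'
#' @param spec An [OligomerSpec-class].
#' @param scheme A [LabelingScheme-class].
#' @param charge Deprotonation count for the m/z column.
#' @param truncation Minimum probability retained; entries below it are
#'   dropped after normalization (relative abundances are computed against the
#'   untruncated base peak). In `[0, 1)`.
#' @return An [IsotopeEnvelope-class] object.
#' @examples
#' is1 <- labelEnvelope(OligomerSpec(2, "delta_unsaturated"),
#'                      LabelingScheme(1, 0.123, 0.0067))
#' envelopeTable(is1)
#' @export
labelEnvelope <- function(spec, scheme, charge = 1, truncation = 1e-4) {
  stopifnot(is(spec, "OligomerSpec"), is(scheme, "LabelingScheme"))
  validObject(spec); validObject(scheme)
  if (truncation < 0 || truncation >= 1)
    stop("truncation must lie in [0, 1)")
  formula <- buildFormula(spec)
  nC <- elementCount(formula, "C")
  U <- 2L * spec@nDisaccharides          # monosaccharide skeletons
  A <- nAcetylGroups(spec)               # acetyl groups
  stopifnot(6L * U + 2L * A == nC)       # carbon bookkeeping

  p <- numeric(nC + 1L)                  # index k + 1 = P(n13C == k)
  for (a in 0:U) {
    wa <- stats::dbinom(a, U, scheme@fUnit)
    if (wa == 0) next
    for (b in 0:A) {
      wb <- if (A > 0L) stats::dbinom(b, A, 1 - scheme@qAcetyl) else 1
      if (wb == 0) next
      L <- 6L * a + 2L * b               # labeled carbons in this stratum
      if (L == 0L) {
        p[1L] <- p[1L] + wa * wb
      } else {
        flips <- 0:L                     # impurity reversions to 12C
        k <- L - flips
        p[k + 1L] <- p[k + 1L] +
          wa * wb * stats::dbinom(flips, L, scheme@epsilon)
      }
    }
  }
  stopifnot(abs(sum(p) - 1) < 1e-9)
  rel <- 100 * p / max(p)
  keep <- p >= truncation & p > 0
  k <- which(keep) - 1L
  entries <- data.frame(
    n13C = k,
    mz = vapply(k, function(i) ionMz(formula, charge, i), numeric(1)),
    probability = p[keep],
    rel_abundance = rel[keep])
  new("IsotopeEnvelope", entries = entries, charge = as.integer(charge),
      truncation = truncation)
}

#' Envelope entries as a data.frame
#'
#' @param envelope An [IsotopeEnvelope-class].
#' @return `data.frame` with columns `n13C`, `mz`, `probability`,
#'   `rel_abundance`.
#' @export
envelopeTable <- function(envelope) {
  stopifnot(is(envelope, "IsotopeEnvelope"))
  envelope@entries
}

setMethod("show", "IsotopeEnvelope", function(object) {
  e <- object@entries
  cat(sprintf("IsotopeEnvelope: %d isotopologues, charge %d-, base peak at n13C = %d (m/z %.4f)\n",
              nrow(e), object@charge, e$n13C[which.max(e$probability)],
              e$mz[which.max(e$probability)]))
  print(format(e, digits = 4), row.names = FALSE)
})

#' Hypergeometric partition of 12C atoms between fragment and neutral loss
#'
#' Under the exchangeable-position labeling model, the `parentN12C` residual
#' 12C atoms of a precursor are allocated to a `fragmentCarbons`-carbon
#' fragment by sampling without replacement from the `parentCarbons` carbon
#' positions.
#'
#' @param parentCarbons Total carbons in the precursor.
#' @param parentN12C Number of 12C atoms in the precursor.
#' @param fragmentCarbons Carbons retained by the fragment ion.
#' @return A [FragmentPartition-class]; its `distribution` maps the fragment
#'   12C count `j` to `dhyper(j, parentN12C, parentCarbons - parentN12C,
#'   fragmentCarbons)`.
#' @examples
#' # one 12C in a 14-carbon dimer: P(in 6-carbon GlcA fragment) = 6/14
#' fragmentLabelDistribution(14, 1, 6)
#' @export
fragmentLabelDistribution <- function(parentCarbons, parentN12C,
                                      fragmentCarbons) {
  parentCarbons <- as.integer(parentCarbons)
  parentN12C <- as.integer(parentN12C)
  fragmentCarbons <- as.integer(fragmentCarbons)
  if (fragmentCarbons > parentCarbons)
    stop("fragmentCarbons cannot exceed parentCarbons")
  if (parentN12C > parentCarbons || parentN12C < 0L)
    stop("parentN12C must lie in [0, parentCarbons]")
  j <- max(0L, fragmentCarbons - (parentCarbons - parentN12C)):
       min(parentN12C, fragmentCarbons)
  pr <- stats::dhyper(j, parentN12C, parentCarbons - parentN12C,
                      fragmentCarbons)
  names(pr) <- j
  new("FragmentPartition", parentCarbons = parentCarbons,
      fragmentCarbons = fragmentCarbons, parentN12C = parentN12C,
      distribution = pr)
}

#' Mean of a fragment 12C partition
#'
#' Hypergeometric mean identity:
#' `parentN12C * fragmentCarbons / parentCarbons`.
#'
#' @param partition A [FragmentPartition-class].
#' @return Numeric.
#' @export
partitionMean <- function(partition) {
  stopifnot(is(partition, "FragmentPartition"))
  j <- as.integer(names(partition@distribution))
  sum(j * partition@distribution)
}

setMethod("show", "FragmentPartition", function(object) {
  cat(sprintf("FragmentPartition: %d of %d carbons retained, %d parent 12C\n",
              object@fragmentCarbons, object@parentCarbons,
              object@parentN12C))
  print(round(object@distribution, 4))
})

#' Invert the labeling model from observed satellite abundances
#'
#' For a fully labeled feed (`fUnit = 1`) the forward model gives, relative to
#' the all-13C base peak with `n` carbons and `A` acetyl groups:
#' \deqn{r_{n-1} = n \epsilon / (1 - \epsilon)}
#' \deqn{r_{n-2} = [A q/(1-q) + \binom{n}{2}\epsilon^2] (1-\epsilon)^{-2}}
#' Both are exact under the model, so the inversion is closed-form and
#' round-trips through [labelEnvelope()] to the observed abundances.
#'
#' @param rNminus2 Relative abundance (percent of base peak) of the
#'   `(n-2)`-13C species (the one-unlabeled-acetyl satellite).
#' @param rNminus1 Relative abundance (percent) of the `(n-1)`-13C species
#'   (the single-impurity satellite).
#' @param nCarbons Carbon count of the oligomer.
#' @param nAcetylGroups Number of acetyl groups (>= 1).
#' @return A [LabelingScheme-class] with `fUnit = 1` and fitted `qAcetyl`,
#'   `epsilon`.
#' @examples
#' fitLabelingParameters(30.1, 18.9, 28, 2) # epsilon ~ 0.0067, q ~ 0.123
#' @export
fitLabelingParameters <- function(rNminus2, rNminus1, nCarbons = 28,
                                  nAcetylGroups = 2) {
  stopifnot(nAcetylGroups >= 1, nCarbons > 2)
  if (rNminus1 < 0 || rNminus1 >= 100 || rNminus2 < 0 || rNminus2 >= 100)
    stop("satellite abundances must be percentages in [0, 100)")
  r1 <- rNminus1 / 100
  r2 <- rNminus2 / 100
  epsilon <- r1 / (nCarbons + r1)          # from r1 = n * eps / (1 - eps)
  t <- r2 * (1 - epsilon)^2 - choose(nCarbons, 2) * epsilon^2
  if (t < 0)
    stop("fit failure: abundances imply a negative acetyl-unlabeled odds ",
         "(two-impurity contribution alone exceeds the (n-2) satellite)")
  odds <- t / nAcetylGroups                # = q / (1 - q)
  qAcetyl <- odds / (1 + odds)
  if (epsilon >= 1 || qAcetyl >= 1)
    stop("fit failure: parameters outside [0, 1)")
  LabelingScheme(fUnit = 1, qAcetyl = qAcetyl, epsilon = epsilon)
}
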