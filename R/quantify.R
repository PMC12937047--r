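## Standard-addition quantification and bioanalytical validation formulas.
##
## The assay's response is the dual-normalized ratio
##   y = [area(analyte) / area(IS1)] / area(IS2):
## dividing by IS1 cancels digestion, extraction, ionization and drift (IS1
## travels with the analyte from the start); the further division by the raw
## IS2 area normalizes the detector response between injections. The SAM line
## y = a x + b over the spike ladder gives the endogenous in-assay
## concentration as x0 = -b/a.

#' Dual-normalized response ratio
#'
#' @param analyteArea,is1Area,is2Area Peak areas; both IS areas must be
#'   positive.
#' @return `(analyteArea / is1Area) / is2Area`. Invariant under joint scaling
#'   of analyte and IS1; inversely proportional to the IS2 area.
#' @examples
#' responseRatio(100, 50, 10)  # 0.2
#' @export
responseRatio <- function(analyteArea, is1Area, is2Area) {
  if (any(is1Area <= 0)) stop("undefined ratio: IS1 area must be positive")
  if (any(is2Area <= 0)) stop("undefined ratio: IS2 area must be positive")
  (analyteArea / is1Area) / is2Area
}

#' Response ratios for an area table
#'
#' Reshapes a long area table (three channel rows per sample) into one row
#' per sample with the dual-normalized response.
#'
#' @param table Area table (see [simulateAssay()]).
#' @return `data.frame`: `sample_id`, `design_role`, `spike_level`,
#'   `replicate`, `activity`, `analyte`, `IS1`, `IS2`, `response`.
#' @export
responseTable <- function(table) {
  need <- c("sample_id", "spike_level", "channel", "area")
  stopifnot(all(need %in% names(table)))
  ids <- unique(table$sample_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- table[table$sample_id == ids[i], ]
    a <- function(ch) {
      v <- rows$area[rows$channel == ch]
      if (length(v) != 1L)
        stop("sample '", ids[i], "' lacks a unique ", ch, " channel row")
      v
    }
    out[[i]] <- data.frame(
      sample_id = ids[i],
      design_role = rows$design_role[1],
      spike_level = rows$spike_level[1],
      replicate = if ("replicate" %in% names(rows)) rows$replicate[1] else NA,
      activity = if ("activity" %in% names(rows)) rows$activity[1] else NA,
      analyte = a("analyte"), IS1 = a("IS1"), IS2 = a("IS2"),
      response = responseRatio(a("analyte"), a("IS1"), a("IS2")))
  }
  do.call(rbind, out)
}

#' Fit a standard-addition calibration line
#'
#' Unweighted ordinary least squares of response against spike concentration.
#' The line crosses zero response at the negative spike `-b/a`; the
#' endogenous in-assay concentration is its magnitude `x0 = b/a`, with a
#' first-order (delta-method) standard error propagated from the coefficient
#' covariance. `x0` is invariant under any rescaling of the response axis.
#'
#' @param spikes In-assay spike concentrations (ug/mL); at least 3 distinct
#'   levels including 0.
#' @param responses Dual-normalized responses, same length.
#' @return A [SAMFit-class].
#' @examples
#' fitStandardAddition(c(0, 4, 12, 20), c(0.8, 1.2, 2.0, 2.8)) # x0 = 8
#' @export
fitStandardAddition <- function(spikes, responses) {
  if (length(spikes) != length(responses))
    stop("spikes and responses must have equal length")
  lv <- sort(unique(spikes))
  if (length(lv) < 3L || lv[1] != 0)
    stop("design error: need >= 3 distinct spike levels including 0")
  fit <- stats::lm(responses ~ spikes)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(a) || a <= 0)
    stop("non-responsive assay: standard-addition slope is not positive")
  x0 <- b / a                # negated x-intercept: -(-b/a)
  V <- stats::vcov(fit)      # order: (Intercept), spikes
  ## gradient of b/a wrt (b, a): (1/a, -b/a^2)
  g <- c(1 / a, -b / a^2)
  x0Var <- g[1]^2 * V[1, 1] + g[2]^2 * V[2, 2] + 2 * g[1] * g[2] * V[1, 2]
  r2 <- summary(fit)$r.squared
  new("SAMFit", slope = a, intercept = b, rSquared = r2, x0 = x0,
      x0Se = sqrt(max(x0Var, 0)), nPoints = length(spikes))
}

setMethod("show", "SAMFit", function(object) {
  cat(sprintf("SAMFit: y = %.4g x + %.4g (r2 = %.4f, n = %d)\n",
              object@slope, object@intercept, object@rSquared,
              object@nPoints))
  cat(sprintf("  endogenous (in-assay) x0 = %.4g +/- %.4g ug/mL\n",
              object@x0, object@x0Se))
})

#' Endogenous concentration in the original matrix
#'
#' Scales the SAM x-intercept (and its SE) by the cumulative dilution factor.
#'
#' @param fit A [SAMFit-class].
#' @param dilution Cumulative dilution factor (see [dilutionFactor()]), or 1
#'   to stay in in-assay units.
#' @return Named numeric: `conc`, `se` (ug/mL in the original matrix).
#' @export
endogenousConcentration <- function(fit, dilution = 1) {
  stopifnot(is(fit, "SAMFit"), is.finite(fit@x0), dilution > 0)
  c(conc = fit@x0 * dilution, se = fit@x0Se * dilution)
}

#' Estimate LOD and LOQ by S/N scaling
#'
#' Scales a measured concentration to the concentrations at which S/N would
#' reach 3 and 10: `LOD = c * 3/SNR`, `LOQ = c * 10/SNR`; `LOQ/LOD` is 10/3
#' for every input.
#'
#' @param cMeasured Measured concentration (ug/mL).
#' @param snr Observed signal-to-noise ratio (> 0).
#' @return A [SensitivityEstimate-class].
#' @examples
#' estimateLodLoq(0.9, 18.3)  # LOD 0.148, LOQ 0.492 ug/mL
#' @export
estimateLodLoq <- function(cMeasured, snr) {
  if (snr <= 0) stop("S/N must be positive")
  stopifnot(cMeasured >= 0)
  new("SensitivityEstimate", cMeasured = cMeasured, snr = snr,
      lod = cMeasured * 3 / snr, loq = cMeasured * 10 / snr)
}

setMethod("show", "SensitivityEstimate", function(object) {
  cat(sprintf("SensitivityEstimate: C = %.4g ug/mL at S/N %.3g -> LOD %.4g, LOQ %.4g ug/mL\n",
              object@cMeasured, object@snr, object@lod, object@loq))
})

#' Accuracy of a spiked measurement
#'
#' `100 * (B - A) / nominal`: net measured concentration over the nominal
#' spike, the standard-addition surrogate for accuracy when no blank matrix
#' exists.
#'
#' @param totalMeasured Total measured concentration B (ug/mL).
#' @param endogenous Endogenous concentration A (ug/mL).
#' @param nominalSpike Nominal spiked concentration (> 0).
#' @return Percent.
#' @export
accuracyPercent <- function(totalMeasured, endogenous, nominalSpike) {
  if (any(nominalSpike <= 0)) stop("nominal spiked concentration must be positive")
  100 * (totalMeasured - endogenous) / nominalSpike
}

#' Relative standard deviation (precision)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values At least three replicate measurements with nonzero mean.
#' @return Percent RSD.
#' @export
precisionRsd <- function(values) {
  if (length(values) < 3L)
    stop("design error: precision needs at least 3 replicates")
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Extraction recovery from the A/B/C aliquots
#'
#' `100 * (B - A) / (C - A)`: pre-extraction spike response over
#' post-extraction spike response, endogenous signal subtracted.
#'
#' @param A,B,C Areas (or concentrations) of the unspiked, pre-extraction
#'   spiked, and post-extraction spiked aliquots.
#' @return Percent.
#' @export
recoveryPercent <- function(A, B, C) {
  if (any(C == A)) stop("undefined recovery: C equals A")
  100 * (B - A) / (C - A)
}

#' Ionization matrix effect from the A/C/D aliquots
#'
#' `100 * (C - A) / D`: the post-extraction spike response relative to the
#' neat standard. 100 means no matrix effect; below 100 suppression; above
#' 100 enhancement.
#'
#' @param A,C,D Areas (or concentrations) of the unspiked, post-extraction
#'   spiked, and neat aliquots.
#' @return Percent.
#' @export
matrixEffectPercent <- function(A, C, D) {
  if (any(D <= 0)) stop("neat-standard response D must be positive")
  100 * (C - A) / D
}

#' Stability as percent change from a reference
#'
#' `100 * (reference - after) / reference`; positive values are losses.
#'
#' @param reference Initial concentration (> 0).
#' @param after Concentration after the stress (e.g. freeze-thaw cycles).
#' @return Percent decrease.
#' @export
stabilityPercentChange <- function(reference, after) {
  if (any(reference <= 0)) stop("reference concentration must be positive")
  100 * (reference - after) / reference
}

#' Robustness CVs with and without IS1 normalization
#'
#' CV percent of the raw analyte peak areas and of the analyte/IS1 area
#' ratios across all robustness samples. Because the digestion factor is
#' shared within a sample, normalization removes the enzyme-activity spread.
#'
#' @param table Area table containing `design_role == "robustness"` rows (or
#'   any table; all samples present are used).
#' @return Named numeric: `cv_unnormalized`, `cv_normalized` (percent).
#' @export
robustnessCv <- function(table) {
  rt <- responseTable(table)
  if (nrow(rt) < 2L) stop("need at least 2 robustness samples")
  cv <- function(v) if (all(v == v[1])) 0 else 100 * stats::sd(v) / mean(v)
  c(cv_unnormalized = cv(rt$analyte), cv_normalized = cv(rt$analyte / rt$IS1))
}
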