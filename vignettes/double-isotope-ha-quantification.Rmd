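---
title: "Models and methods: double-isotopic-standard HA quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: double-isotopic-standard HA quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haquant)
```

This vignette is the package's own account of the science it implements: the
mass and labeling models, the generative model behind the synthetic data, the
quantification calculus, the numerical conventions, and what the test suite
does and does not demonstrate.

## 1. Oligomer formulas and masses

An HA oligomer of $n$ disaccharides is assembled as

$$n\,(\mathrm{GlcA} + \mathrm{GlcNAc}) - (2n-1)\,\mathrm{H_2O},$$

with GlcA = C$_6$H$_{10}$O$_7$ and GlcNAc = C$_8$H$_{15}$NO$_6$ as free
monosaccharides. Two conventions matter and are fixed once:

* **Reducing end.** The reducing end is a free hemiacetal; no derivatization.
  This reproduces C$_{28}$H$_{42}$N$_2$O$_{22}$ for the unsaturated tetramer.
* **Unsaturation.** The 4,5-unsaturated uronate left by lyase cleavage is
  encoded purely as one further H$_2$O removed from the saturated formula.
  The hydrolase (saturated) product of the same length is therefore heavier
  by exactly one water, 18.0106 Da — the mass offset that the channel design
  exploits.

Only whole disaccharides are representable (`OligomerSpec` takes a
disaccharide count): both cleavage chemistries in scope work at disaccharide
periodicity, and odd-mers would multiply the fragment bookkeeping without a
use case. Deacetylation (acid hydrolysis) removes C$_2$H$_2$O per residue.

Atomic masses are hard-coded scalars (¹²C = 12 exactly, ¹³C = 13.0033548,
H = 1.0078250, N = 14.0030740, O = 15.9949146, electron = 0.0005486 Da), and
deprotonated m/z is $(M - z\,m_p)/z$ with the proton mass $m_p = m_H - m_e$ —
the anion keeps its electrons. At unit charge the electron-mass correction is
0.5 mDa, which is material when the test surface is agreement with
high-resolution observed values at the 1–3 mDa level. Theory is treated as
ground truth; printed observed values are tolerance-checked anchors
(instrument calibration puts them 1–3 mDa off theory).

## 2. The isotopologue model

Biosynthetic labeling on ¹³C glucose is **unit-level, not per-atom**:

* each 6-carbon monosaccharide skeleton derives all-or-none from the glucose
  pool, with probability `fUnit`;
* each 2-carbon acetyl group is installed all-or-none by the
  acetyltransferase, and can come from unlabeled carbon sources even under a
  fully labeled feed, with probability `qAcetyl`;
* inside labeled units, each carbon independently reverts to ¹²C with the
  feedstock impurity probability `epsilon`.

A per-atom binomial cannot produce the observed structure — dominant species
at 6/8/12/14 ¹³C for a 1:1 feed (multiples of 6 and 2), and −1/−2 Da
satellites next to the all-¹³C peak for a 100 % feed. The envelope is an
exact finite enumeration over (labeled skeletons $a$, labeled acetyls $b$,
binomial impurity flips among the $6a + 2b$ labeled carbons); no sampling and
no truncation error beyond the user-chosen reporting cutoff (default
$10^{-4}$ probability, applied after normalization, with relative abundances
referred to the untruncated base peak).

**Parameter inversion.** For `fUnit = 1` the model gives, relative to the
all-¹³C base peak of an $n$-carbon, $A$-acetyl oligomer,

$$r_{n-1} = \frac{n\,\epsilon}{1-\epsilon}, \qquad
  r_{n-2} = \Bigl[A\,\frac{q}{1-q} + \binom{n}{2}\epsilon^2\Bigr]
            (1-\epsilon)^{-2}.$$

Both expressions are exact, so `fitLabelingParameters` inverts them in closed
form, including the two-impurity-flip term $\binom{n}{2}\epsilon^2$ in
$r_{n-2}$. Dropping that term (a tempting first-order shortcut) biases $q$ by
about 5 % relative and breaks the forward–inverse round trip by ~1.7
percentage points at the abundances of interest; with the exact inversion the
round trip is numerically exact, and a brute-force two-parameter grid search
lands on the same optimum (a test asserts both). Fitting `fUnit` itself from
1:1-feed spectra is out of scope.

Natural-abundance isotopes of H, N and O are ignored throughout: the model is
carbon-only, its targets are the monoisotopic peaks of each isotopologue, and
the satellite interpretation never involves heteroatom isotopes.

Two open readings are resolved as configuration rather than claims. First,
the single-¹²C satellite is attributed to per-atom enrichment shortfall
(`epsilon`) rather than to intact unlabeled glucose — intact unlabeled
glucose would shift by 6 carbons at once and could not produce a −1 Da
species. Second, the effective acetyl labeling of a 1:1 feed is not
derivable from first principles here; the default IS2 scheme uses
`qAcetyl = 0.5`, which reproduces the observed most-abundant 6/8/12/14
species, and the parameter is exposed.

**Fragments.** Conditional on a precursor with $k$ residual ¹²C atoms, carbon
positions are exchangeable, so a fragment retaining $c$ of $C$ carbons
receives $j$ of them hypergeometrically
(`dhyper(j, k, C - k, c)`). The same law applied at the acetyl level (one
unlabeled acetyl of two, fragment keeps one) gives the 1:1 split behind the
±2 Da product-ion doublets.

## 3. Channel design checking

`checkInterference` formalizes the design argument for producing IS2 with a
hydrolase: a species flags a foreign channel only if one of its precursor
isotopologues lies within the Q1 tolerance *and* one of its fragment
isotopologues — fragment formulas per species, labels partitioned
hypergeometrically — lies within the Q3 tolerance. Defaults are ±0.5 Da on
both quadrupoles (unit-resolution instrument), configurable; the flag set is
monotone in both tolerances.

With the default species set the report is empty. The one near miss is
instructive: the saturated 10-¹³C isotopologue grazes the IS1 precursor at
m/z 785.26, but its GlcA-containing fragments cannot reach m/z 392, so the
product stage clears it — the report keeps such cleared candidates visible.
Re-running the check with a hypothetical lyase-made IS2 (unsaturated,
half-labeled) flags the analyte and IS1 channels at its 0- and 28-¹³C
envelope ends, which is exactly why the saturated (+18 Da) standard is the
right construction.

The product-ion formulas (554 = tetramer minus the reducing-end GlcNAc
residue, C$_{20}$H$_{29}$NO$_{17}$; 392 = fully labeled unsaturated
nonreducing dimer, C$_{14}$H$_{21}$NO$_{11}$; 199 = all-¹³C GlcA,
C$_6$H$_{10}$O$_7$) are structural reconstructions: the assignments are given
graphically in the source spectra, and the evidence for the reconstruction is
that their computed exact m/z reproduce the printed observed values (e.g.
199.0555 vs 199.055).

## 4. The synthetic-data generator

No public dataset exists for this assay, so the generator *is* the study
description, and its defaults are the study conditions. Per sample $s$:

$$\begin{aligned}
\text{analyte} &\propto (C_0 + \text{spike}) \cdot E_s X M D_s \eta\\
\text{IS1} &\propto C_{IS1} \cdot E_s X M D_s \eta\\
\text{IS2} &\propto C_{IS2} \cdot M D_s \eta
\end{aligned}$$

with digestion factor $E_s$, extraction recovery $X$, ionization matrix
factor $M$, detector drift $D_s$ and per-channel noise $\eta$ (all noise
multiplicative log-normal with unit mean, so expectations equal the
noise-free algebra and the dual ratio's expectation is affine in the spike).
The structural content is the sharing pattern: IS1 experiences digestion and
extraction, IS2 — added to the reconstituted extract — does not. That
covariance is the entire case for the dual-standard design, and an ablation
test (IS1 stripped of the shared digestion factor) shows the normalized
ratio's variance advantage disappear.

Defaults, chosen once for realism and not revisited:

| Parameter | Default | Why |
|---|---|---|
| Endogenous conc. | 800 (BVH-like), 1100 (HSF-like) µg/mL | physiological scale of the two matrices |
| Predilution | 12× / 10× | assay design for the two matrices |
| Dilution chain | 20 µL into 162 µL | stated assay volumes; total factor 97.2 (12×) made explicit since only the volumes are stated |
| Spike ladders | 0/4/12/20 and 0/8/24/40 µg/mL in-assay | assay design |
| IS1 in-assay | 50·40/162 ≈ 12.3 µg/mL | 40 µL of 50 µg/mL dosed into the assay |
| IS2 in-assay | 12 µg/mL equivalents | unstated in the source; set comparable to IS1, configurable |
| Matrix factor | 0.5323 / 1.1315 | set to the estimands the validation reports (suppression in BVH, mild enhancement in HSF) |
| Extraction recovery | 0.9913 / 0.9298 | same rationale |
| Digestion yield | 0.8 at 2000 U/mL, saturating in activity with K = 1000 U/mL | yields 0.6/0.8/1.0 at 1000/2000/5000 U/mL — a 50 % spread, comfortably past the ≥20 % the robustness analysis needs, while staying ≤ 1 |
| Channel noise CV | 1 % | replicate-injection precision of a strong MRM signal |
| Detector drift CV | 1.5 % | within-batch drift |
| Enzyme CV | 5 % | digestion variability (cancels in the ratio; visible in raw areas) |
| Response factor, baseline noise | 5·10⁴ area/(µg/mL), 8000 | put the unspiked S/N near 10², hence LOD on the 0.1–0.2 µg/mL scale |

The spike material in the recovery aliquots (and the neat standard) is
hydrolyzed under reference conditions, so the recovery estimator converges to
$X$ and the matrix-effect estimator to $M$ — the generator makes the A/B/C/D
estimators consistent for their own parameters, which is what the
estimator-consistency tests check. Freeze–thaw stress multiplies the
endogenous level by $(1-\ell)^{\text{cycles}}$ before simulation; the default
$\ell = 0.075$ over two cycles gives a 14.4 % decrease measured downstream.

Chromatograms are rendered as Gaussian peaks (σ = 0.05 min) on a uniform
baseline and re-integrate to their generating areas within 1 %; every
generator is bit-reproducible given `(seed, design)`, and `runPipeline` seeds
a single RNG stream for the whole run.

What the generator does **not** emulate: oligomer length distributions and
digestion kinetics (a scalar yield stands in for the time course), retention
drift and peak-shape pathology, carryover, heteroscedastic noise at the
detection limit, and between-day effects beyond a single drift term. Passing
tests therefore demonstrate the *calculus* — that every estimator inverts the
stated generative model, exactly at zero noise and within stated tolerances
under realistic noise — not the field performance of the physical assay. The
printed concentrations and validation percentages of the physical experiment
derive from real samples and are covered only by estimator-consistency and
arithmetic checks.

## 5. Quantification conventions

* **Response.** $y = [\text{area(analyte)}/\text{area(IS1)}]/\text{area(IS2)}$,
  implemented verbatim. Dividing by the *raw* IS2 area makes $y$ carry units
  of 1/area and re-introduces the drift that A/IS1 had cancelled; the
  division is retained as the method's definition, and the SAM intercept
  ratio $x_0 = b/a$ is invariant to any common rescaling of $y$, so the
  estimate is unaffected.
* **SAM fit.** Unweighted OLS (no weighting is part of the method); the
  endogenous in-assay level is the magnitude of the x-intercept,
  $x_0 = b/a > 0$, with a delta-method SE from the coefficient covariance.
  Per-replicate-curve fits are also reported, supporting the
  replicate-SD style of summary. A non-positive slope is an error, not a
  result.
* **LOD/LOQ.** No blank matrix exists, so limits are S/N-scaled from a
  measured concentration: LOD $= C\cdot 3/(S/N)$, LOQ $= C\cdot 10/(S/N)$;
  their 10/3 ratio is an identity, asserted as such. The S/N itself is
  measured on rendered chromatograms of the unspiked samples.
* **Noise amplitude.** "Baseline noise height" is operationalized as half
  the peak-to-peak excursion in two flanking windows (default 0.3 min per
  side in the pipeline; width configurable — the convention cancels in the
  LOQ/LOD ratio and only scales both limits together). A flank truncated by
  the trace edge degrades to a one-sided estimate with a warning.
* **Integration.** Trapezoidal, above a linear baseline drawn between the
  window endpoints; fixed windows at known retention times (±4σ), no peak
  detection. Offset invariance and linearity are tested properties.
* **Acceptance bands.** ±15 % accuracy/precision (±20 % at the LLOQ) and
  20 % stability are carried in the report as configurable thresholds, not
  hard-coded pass/fail logic.

## 6. Problem sizes and determinism

The shipped tests and the acceptance script run the default designs: 4 spike
levels × 3 replicates per curve, 3–4 validation aliquot roles × 3 replicates,
3 enzyme activities × 3 replicates, one $10^6$-draw Monte-Carlo comparison of
the analytic envelope (total-variation distance < 0.005), a 1000-fit coverage
simulation for the $x_0$ interval (4 levels × 6 replicates, so the residual
degrees of freedom support the 3-SE/99 % statement being tested), and a
200-replication robustness comparison. All stochastic results flow from
explicit integer seeds.

## 7. Known limitations

* CHNO-only formulas; no sulfation, adducts other than [M−zH]$^{z-}$, or
  positive mode.
* The carbon-only envelope under-counts +1 peaks of *unlabeled* species
  (natural ¹³C is ~1.1 % per carbon); for the labeled standards, where the
  model is actually used, the satellite structure dominates and the
  approximation is the interpretive convention of the assay.
* `fitLabelingParameters` assumes the base peak is the all-¹³C species;
  schemes with large `qAcetyl` or `epsilon` violate that and are rejected by
  its validity checks rather than refit.
* Interference checking is m/z-only; retention-time separation and fragment
  intensity prediction are out of scope.
* The pipeline quantifies one analyte on three fixed channels; it is not a
  general MRM processing tool.
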