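## Monoisotopic atomic masses (NIST/CODATA, Da). The mass table is part of the
## quantitative surface of this package: sub-ppm agreement with high-resolution
## observed values is what the isotopologue assignments rest on, so the
## constants carry >= 7 significant decimals and m/z includes the electron mass
## (via the proton mass) rather than the 1.00794 average-H shortcut.

.MASS_12C <- 12               # exact by definition
.MASS_13C <- 13.0033548
.MASS_H   <- 1.0078250
.MASS_N   <- 14.0030740
.MASS_O   <- 15.9949146
.MASS_ELECTRON <- 0.0005486
.MASS_PROTON   <- .MASS_H - .MASS_ELECTRON  # 1.0072764

## 13C - 12C mass defect; additivity of labeling rests on this single constant
.MASS_DEFECT_13C <- .MASS_13C - .MASS_12C

## Supported elements, in Hill order for CHNO-only formulas
.ELEMENTS <- c("C", "H", "N", "O")
.ELEMENT_MASS <- c(C = .MASS_12C, H = .MASS_H, N = .MASS_N, O = .MASS_O)
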