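# Independent oracles, deliberately decoupled from the package internals.

# Per-element hand sum with its own copy of the atomic masses (NIST).
oracleMass <- function(C = 0, H = 0, N = 0, O = 0, n13C = 0) {
  C * 12 + H * 1.0078250 + N * 14.0030740 + O * 15.9949146 +
    n13C * (13.0033548 - 12)
}
oracleMz <- function(..., z = 1) {
  (oracleMass(...) - z * 1.0072764) / z
}

# Brute-force hypergeometric: enumerate all placements of the fragment carbon
# subset among the parent carbon positions.
oracleFragmentSplit <- function(parentC, n12, fragC) {
  positions <- seq_len(parentC)
  labeled12 <- seq_len(n12)            # wlog the first n12 positions are 12C
  subsets <- utils::combn(positions, fragC)
  j <- apply(subsets, 2, function(s) sum(s %in% labeled12))
  tab <- table(factor(j, levels = 0:fragC)) / ncol(subsets)
  tab[tab > 0]
}

# Monte-Carlo simulation of the unit labeling model for a tetramer:
# 4 six-carbon skeletons, `nAcetyl` two-carbon acetyls, per-atom impurity.
oracleEnvelopeMC <- function(f, q, eps, n, nSkeleton = 4, nAcetyl = 2) {
  a <- stats::rbinom(n, nSkeleton, f)
  b <- stats::rbinom(n, nAcetyl, 1 - q)
  L <- 6 * a + 2 * b
  k <- L - stats::rbinom(n, L, eps)
  nC <- 6 * nSkeleton + 2 * nAcetyl
  tabulate(k + 1L, nbins = nC + 1L) / n
}

# Total-variation distance between two distributions on 0..n carbons.
tvDistance <- function(p, q) 0.5 * sum(abs(p - q))

# Expand an envelope to a dense probability vector over 0..nC atoms.
denseEnvelope <- function(env, nC) {
  p <- numeric(nC + 1L)
  tab <- envelopeTable(env)
  p[tab$n13C + 1L] <- tab$probability
  p
}
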