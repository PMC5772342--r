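# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths: nested 1-D root bracketing instead of the
# Newton solver, and direct quadratic root-finding instead of the stable
# closed form.

# Brute-force speciation for a 2-component system: free B from its own mass
# balance by bisection at fixed free A, then free A by bisection on the A
# balance. Both balances are monotone in the free concentration.
# The bisections run on log10 free concentration so that roots many orders
# of magnitude below the totals are still located to full relative precision.
oracle_speciation_2comp <- function(S, log_beta, totals) {
  stopifnot(ncol(S) == 2, all(totals > 0))
  cplx <- function(xA, xB) 10^log_beta * xA^S[, 1] * xB^S[, 2]
  log_bisect <- function(g, hi) {
    lo <- hi - 40
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(10^mid) > 0) hi <- mid else lo <- mid
    }
    10^((lo + hi) / 2)
  }
  xB_of <- function(xA) {
    log_bisect(function(xB) xB + sum(S[, 2] * cplx(xA, xB)) - totals[2],
               log10(totals[2]))
  }
  xA <- log_bisect(function(xA) {
    xA + sum(S[, 1] * cplx(xA, xB_of(xA))) - totals[1]
  }, log10(totals[1]))
  xB <- xB_of(xA)
  list(free = unname(c(xA, xB)), complexes = unname(cplx(xA, xB)))
}

# Bound fraction by numeric root of the binding polynomial, parameterised in
# the bound fraction itself so precision is absolute in [0, 1].
oracle_fraction_bound <- function(ka, ptot, dtot) {
  if (dtot == 0) return(ka * ptot / (1 + ka * ptot))
  if (ka == 0 || ptot == 0) return(0)
  h <- function(fb) ka * (ptot - fb * dtot) * (1 - fb) - fb
  lo <- 0; hi <- 1
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random peptide sequences over the 20 standard residues.
random_peptides <- function(n, len_range = c(5, 20), seed = 1) {
  withr::with_seed(seed, {
    replicate(n, {
      len <- sample(seq(len_range[1], len_range[2]), 1)
      paste(sample(c("G","A","S","P","V","T","C","L","I","N","D","Q","K",
                     "E","M","H","F","R","Y","W"), len, replace = TRUE),
            collapse = "")
    })
  })
}
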