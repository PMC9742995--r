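# Shared fixtures: random feasible parameter sets and bisection oracles on
# the raw elemental-balance residuals.  The oracles are built from the
# exported constitutive relations only (chlorophyll, protein, RNA quotas),
# never from the closed-form budget polynomials they are used to check.

# Draw one feasible parameter set from broad physiological ranges,
# rejecting draws whose constant pools leave no room for growth machinery.
randomFeasibleParams <- function() {
  repeat {
    p <- try(cfmParams(
      P_max_chl = runif(1, 20, 80),
      O_I = runif(1, 0.004, 0.02),
      I = runif(1, 50, 500),
      E = runif(1, 0.2, 1.0),
      m = runif(1, 0, 0.3),
      A_pho = runif(1, 1, 6),
      A_plip = runif(1, 0, 0.3),
      r_bio_pho = runif(1, 5, 30),
      Q_pro_ess_C = runif(1, 0.05, 0.25),
      A_rna = runif(1, 0.05, 0.6),
      Q_rna_min_C = runif(1, 0, 0.03),
      Q_dna_C = runif(1, 0.002, 0.015),
      Q_oth_C = runif(1, 0.1, 0.35),
      Q_nsto_C = runif(1, 0, 0.05),
      Y_rna_NC = runif(1, 0.3, 0.45),
      Y_dna_NC = runif(1, 0.3, 0.45),
      Y_chl_NC = runif(1, 0.05, 0.09),
      Y_nsto_NC = runif(1, 0.2, 1),
      A_N = runif(1, 0.02, 0.3)), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# Sum of the eight C pools at growth rate mu with C storage empty and N
# storage at its replete level, assembled from the constitutive relations.
qcPoolSum <- function(mu, p) {
  chl <- chlorophyllQuota(mu, p)
  pro <- proteinQuota(mu, p)$total
  rna <- rnaQuota(mu, pro, p)
  pro + rna + p@Q_dna_C + chl + p@A_plip * chl + p@Q_nsto_C + p@Q_oth_C
}

# Total N quota at mu with N storage empty (N-limited composition).
qnTotal <- function(mu, p) {
  chl <- chlorophyllQuota(mu, p)
  pro <- proteinQuota(mu, p)$total
  rna <- rnaQuota(mu, pro, p)
  p@Y_pro_NC * pro + p@Y_rna_NC * rna + p@Y_dna_NC * p@Q_dna_C +
    p@Y_chl_NC * chl
}

# Bisection oracle for the C-limited growth rate: root of 1 - sum(QC(mu)).
bisectMuC <- function(p, tol = 1e-12) {
  f <- function(mu) 1 - qcPoolSum(mu, p)
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = tol)$root
}

# Bisection oracle for the N-limited growth rate: root of the steady-state
# balance A_N * no3 - mu * Q_N(mu).
bisectMuN <- function(p, no3, tol = 1e-12) {
  g <- function(mu) p@A_N * no3 - mu * qnTotal(mu, p)
  if (no3 == 0) return(0)
  hi <- 1
  while (g(hi) > 0) hi <- hi * 2
  uniroot(g, c(0, hi), tol = tol)$root
}
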