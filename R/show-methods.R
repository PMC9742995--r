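#' @describeIn cfmParams show method
#' @param object a \code{CfmParams} object.
#' @export
setMethod("show", "CfmParams", function(object) {
  cat("CfmParams: allocation-model parameter set\n")
  cat(sprintf("  fitted:   A_pho = %.4g, A_N = %.4g (k_bio = %.4g)\n",
              object@A_pho, object@A_N, object@k_bio))
  cat(sprintf("  light:    I = %.4g umol m-2 s-1, P_max_chl = %.4g /d, O_I = %.4g\n",
              object@I, object@P_max_chl, object@O_I))
  cat(sprintf("  costs:    E = %.4g, m = %.4g /d\n", object@E, object@m))
  cat(sprintf("  quotas:   pro_ess %.4g, rna_min %.4g, dna %.4g, oth %.4g, nsto %.4g\n",
              object@Q_pro_ess_C, object@Q_rna_min_C, object@Q_dna_C,
              object@Q_oth_C, object@Q_nsto_C))
  cat(sprintf("  protein C:N = %.4g\n", 1 / object@Y_pro_NC))
})

setMethod("show", "MacromolecularState", function(object) {
  cat(sprintf("MacromolecularState (%s) at mu = %.4g /d\n",
              object@limitation, object@mu))
  qc <- c(pro = object@QC_pro, rna = object@QC_rna, dna = object@QC_dna,
          chl = object@QC_chl, plip_thy = object@QC_plip_thy,
          nsto = object@QC_nsto, csto = object@QC_csto,
          oth = object@QC_oth)
  cat("  C quotas:", paste(sprintf("%s=%.4f", names(qc), qc),
                           collapse = " "), "\n")
  cat(sprintf("  N:C = %.4f\n", object@QN_total))
})

setMethod("show", "BudgetPolynomial", function(object) {
  cat(sprintf("BudgetPolynomial degree %d (%s): [%s]\n", object@degree,
              object@regime,
              paste(signif(object@coefficients, 6), collapse = ", ")))
})

setMethod("show", "MonodParams", function(object) {
  cat(sprintf("MonodParams: mu_max = %.4g /d, Ks = %.4g uM\n",
              object@mu_max, object@Ks))
})

setMethod("show", "GrowthDataset", function(object) {
  cat(sprintf("GrowthDataset '%s' (%s): %d points, I = %.4g umol m-2 s-1\n",
              object@species, object@provenance, length(object@no3),
              object@irradiance))
  cat(sprintf("  no3 range %.4g-%.4g uM, mu range %.4g-%.4g /d\n",
              min(object@no3), max(object@no3), min(object@mu_obs),
              max(object@mu_obs)))
})

setMethod("show", "McmcChain", function(object) {
  cat(sprintf("McmcChain: %d iterations x %d parameter(s), acceptance %.3f, burn-in %d\n",
              nrow(object@samples), ncol(object@samples),
              object@acceptanceRate, object@burnIn))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s model), RSS = %.4g\n", object@model,
              object@rss))
  for (p in names(object@estimate))
    cat(sprintf("  %s: %.5g  [95%% %.5g, %.5g]\n", p,
                object@estimate[[p]], object@ci[p, 1L], object@ci[p, 2L]))
})

# ---------------------------------------------------------------------------
# accessors
# ---------------------------------------------------------------------------

#' Growth rate of a state or dataset
#' @param x a [MacromolecularState-class].
#' @return the specific growth rate (day^-1).
#' @export
growthRate <- function(x) {
  stopifnot(is(x, "MacromolecularState"))
  x@mu
}

#' Limitation label of a state
#' @param x a [MacromolecularState-class].
#' @return \code{"N_limited"} or \code{"C_limited"}.
#' @export
limitation <- function(x) {
  stopifnot(is(x, "MacromolecularState"))
  x@limitation
}

#' Carbon quotas of a state
#' @param x a [MacromolecularState-class].
#' @return named numeric vector of the eight C quotas (sums to 1).
#' @export
carbonQuotas <- function(x) {
  stopifnot(is(x, "MacromolecularState"))
  c(pro = x@QC_pro, rna = x@QC_rna, dna = x@QC_dna, chl = x@QC_chl,
    plip_thy = x@QC_plip_thy, nsto = x@QC_nsto, csto = x@QC_csto,
    oth = x@QC_oth)
}

#' Nitrogen quotas of a state
#' @param x a [MacromolecularState-class].
#' @return named numeric vector of the five N quotas plus \code{total}.
#' @export
nitrogenQuotas <- function(x) {
  stopifnot(is(x, "MacromolecularState"))
  c(pro = x@QN_pro, rna = x@QN_rna, dna = x@QN_dna, chl = x@QN_chl,
    nsto = x@QN_nsto, total = x@QN_total)
}

#' @describeIn fitMonod point estimates of a fit
#' @param object a [FitResult-class].
#' @param ... unused.
#' @export
setMethod("coef", "FitResult", function(object, ...) object@estimate)

#' Posterior samples of a fit or chain
#' @param x a [FitResult-class] or [McmcChain-class].
#' @param afterBurnIn drop the burn-in segment (default TRUE).
#' @return iteration x parameter matrix.
#' @export
posteriorSamples <- function(x, afterBurnIn = TRUE) {
  ch <- if (is(x, "FitResult")) x@chain else x
  stopifnot(is(ch, "McmcChain"))
  if (afterBurnIn && ch@burnIn > 0L)
    ch@samples[-seq_len(ch@burnIn), , drop = FALSE]
  else ch@samples
}

#' Acceptance rate of a fit or chain
#' @param x a [FitResult-class] or [McmcChain-class].
#' @return fraction of accepted proposals in [0, 1].
#' @export
acceptanceRate <- function(x) {
  ch <- if (is(x, "FitResult")) x@chain else x
  stopifnot(is(ch, "McmcChain"))
  ch@acceptanceRate
}

#' Credible intervals of a fit
#' @param x a [FitResult-class].
#' @return parameter x 2 matrix of central 95 percent intervals.
#' @export
credibleIntervals <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@ci
}

#' Residual sum of squares at the point estimate
#' @param x a [FitResult-class].
#' @return RSS ((day^-1)^2).
#' @export
fitRss <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@rss
}

#' Convert a growth dataset to a data.frame
#' @param x a [GrowthDataset-class].
#' @return data.frame with columns \code{no3} and \code{mu_obs}.
#' @export
datasetPoints <- function(x) {
  stopifnot(is(x, "GrowthDataset"))
  data.frame(no3 = x@no3, mu_obs = x@mu_obs)
}
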