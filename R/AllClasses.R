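#' @import methods
NULL

# ---------------------------------------------------------------------------
# CfmParams
# ---------------------------------------------------------------------------

#' Physiological parameter set of the allocation model
#'
#' Holds every physiological constant of the coarse-grained allocation model
#' together with the two parameters that are fitted to data (the
#' photosynthetic-protein-to-chlorophyll ratio \code{A_pho} and the nitrate
#' uptake affinity \code{A_N}) and the irradiance of the experiment being
#' modelled.  All quotas are expressed per mol of cellular carbon, rates in
#' per day, concentrations in micromolar.
#'
#' @slot P_max_chl maximum C-fixation rate per chlorophyll C
#'   (mol C (mol chl-C)^-1 day^-1), > 0.
#' @slot O_I irradiance saturation coefficient
#'   ((umol photons m^-2 s^-1)^-1), > 0.
#' @slot I irradiance (umol photons m^-2 s^-1), >= 0; set per experiment.
#' @slot E biosynthesis excretion/cost fraction (dimensionless), >= 0.
#' @slot m maintenance respiration rate (day^-1), >= 0.
#' @slot A_pho photosynthetic protein C : chlorophyll C ratio
#'   (dimensionless), > 0.  One of the two fitted parameters.
#' @slot A_plip thylakoid-membrane lipid C : chlorophyll C ratio
#'   (dimensionless), >= 0.
#' @slot k_bio biosynthetic protein C quota per unit growth rate (day), > 0.
#'   During fitting it is slaved to \code{A_pho} through \code{r_bio_pho}.
#' @slot r_bio_pho fixed ratio \code{A_pho / k_bio} used to tie the
#'   biosynthetic protein demand to the photosynthetic apparatus, > 0.
#' @slot Q_pro_ess_C essential protein C quota (mol C / mol cell C), >= 0.
#' @slot A_rna RNA C per protein C per unit growth rate (day), >= 0.
#' @slot Q_rna_min_C minimum RNA C quota (mol C / mol cell C), >= 0.
#' @slot Q_dna_C DNA C quota, constant (mol C / mol cell C), >= 0.
#' @slot Q_oth_C other essential C quota, constant (mol C / mol cell C), >= 0.
#' @slot Q_nsto_C C quota of the N-storage pool when N is replete
#'   (mol C / mol cell C), >= 0.
#' @slot Y_pro_NC N:C ratio of protein (mol N / mol C), > 0; default 1/4.49.
#' @slot Y_rna_NC N:C ratio of RNA, > 0.
#' @slot Y_dna_NC N:C ratio of DNA, > 0.
#' @slot Y_chl_NC N:C ratio of chlorophyll, > 0.
#' @slot Y_nsto_NC N:C ratio of the N-storage pool, > 0.
#' @slot A_N nitrate uptake affinity
#'   (mol N (mol cell C)^-1 day^-1 uM^-1), > 0.  The second fitted parameter.
#'
#' @seealso [cfmParams()] for the user-facing constructor with defaults,
#'   [cLimitedGrowth()], [nLimitedGrowth()], [realizedGrowth()].
#' @export
setClass("CfmParams",
  representation(
    P_max_chl = "numeric", O_I = "numeric", I = "numeric",
    E = "numeric", m = "numeric",
    A_pho = "numeric", A_plip = "numeric",
    k_bio = "numeric", r_bio_pho = "numeric",
    Q_pro_ess_C = "numeric", A_rna = "numeric", Q_rna_min_C = "numeric",
    Q_dna_C = "numeric", Q_oth_C = "numeric", Q_nsto_C = "numeric",
    Y_pro_NC = "numeric", Y_rna_NC = "numeric", Y_dna_NC = "numeric",
    Y_chl_NC = "numeric", Y_nsto_NC = "numeric",
    A_N = "numeric"
  )
)

setValidity("CfmParams", function(object) {
  msgs <- character()
  chk1 <- function(x, nm) {
    if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
      msgs <<- c(msgs, sprintf("'%s' must be a single finite number", nm))
  }
  for (nm in slotNames(object)) chk1(slot(object, nm), nm)
  if (length(msgs)) return(msgs)
  pos <- c("P_max_chl", "O_I", "A_pho", "k_bio", "r_bio_pho",
           "Y_pro_NC", "Y_rna_NC", "Y_dna_NC", "Y_chl_NC", "Y_nsto_NC",
           "A_N")
  nneg <- c("I", "E", "m", "A_plip", "Q_pro_ess_C", "A_rna", "Q_rna_min_C",
            "Q_dna_C", "Q_oth_C", "Q_nsto_C")
  for (nm in pos)
    if (slot(object, nm) <= 0)
      msgs <- c(msgs, sprintf("'%s' must be > 0", nm))
  for (nm in nneg)
    if (slot(object, nm) < 0)
      msgs <- c(msgs, sprintf("'%s' must be >= 0", nm))
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# MacromolecularState
# ---------------------------------------------------------------------------

#' Macromolecular allocation state at a given growth rate
#'
#' The eight carbon quotas and five nitrogen quotas of the cell at a steady
#' state, together with the realized growth rate and a label saying which
#' elemental budget is binding.  Quotas are mol per mol cellular C, so the
#' carbon pools sum to one and \code{QN_total} equals the cellular N:C ratio.
#'
#' @slot mu specific growth rate (day^-1).
#' @slot QC_pro,QC_rna,QC_dna,QC_chl,QC_plip_thy,QC_nsto,QC_csto,QC_oth
#'   carbon quotas of the protein, RNA, DNA, chlorophyll, thylakoid-lipid,
#'   N-storage, C-storage and other pools; each in [0, 1] and summing to 1.
#' @slot QN_pro,QN_rna,QN_dna,QN_chl,QN_nsto nitrogen quotas of the five
#'   N-bearing pools (mol N / mol cell C), each >= 0.
#' @slot QN_total total N quota, equal to the sum of the five N pools and to
#'   the cellular N:C ratio.
#' @slot limitation \code{"N_limited"} or \code{"C_limited"}.
#'
#' @seealso [allocationState()], [realizedGrowth()].
#' @export
setClass("MacromolecularState",
  representation(
    mu = "numeric",
    QC_pro = "numeric", QC_rna = "numeric", QC_dna = "numeric",
    QC_chl = "numeric", QC_plip_thy = "numeric", QC_nsto = "numeric",
    QC_csto = "numeric", QC_oth = "numeric",
    QN_pro = "numeric", QN_rna = "numeric", QN_dna = "numeric",
    QN_chl = "numeric", QN_nsto = "numeric",
    QN_total = "numeric",
    limitation = "character"
  )
)

setValidity("MacromolecularState", function(object) {
  msgs <- character()
  if (!object@limitation %in% c("N_limited", "C_limited"))
    msgs <- c(msgs, "limitation must be 'N_limited' or 'C_limited'")
  if (object@mu < 0) msgs <- c(msgs, "mu must be >= 0")
  qc <- c(object@QC_pro, object@QC_rna, object@QC_dna, object@QC_chl,
          object@QC_plip_thy, object@QC_nsto, object@QC_csto, object@QC_oth)
  qn <- c(object@QN_pro, object@QN_rna, object@QN_dna, object@QN_chl,
          object@QN_nsto)
  if (any(qc < -1e-12) || any(qc > 1 + 1e-12))
    msgs <- c(msgs, "all C quotas must lie in [0, 1]")
  if (any(qn < -1e-12))
    msgs <- c(msgs, "all N quotas must be >= 0")
  if (abs(sum(qc) - 1) > 1e-9)
    msgs <- c(msgs, "C quotas must sum to 1 within 1e-9")
  if (abs(sum(qn) - object@QN_total) > 1e-12)
    msgs <- c(msgs, "QN_total must equal the sum of the five N pools")
  if (object@limitation == "N_limited" &&
      (object@QC_nsto != 0 || object@QN_nsto != 0))
    msgs <- c(msgs, "under N limitation the N-storage pools must be 0")
  if (object@limitation == "C_limited" && object@QC_csto != 0)
    msgs <- c(msgs, "under C limitation QC_csto must be 0")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# BudgetPolynomial
# ---------------------------------------------------------------------------

#' Elemental-budget polynomial in the growth rate
#'
#' The carbon budget closes as a quadratic in the growth rate and the
#' nitrogen steady state as a cubic; this class carries the coefficients
#' (highest degree first) together with the regime they belong to.
#'
#' @slot degree 2 (carbon budget) or 3 (nitrogen budget).
#' @slot coefficients numeric vector of length degree + 1, highest first.
#' @slot regime \code{"C_limited"} or \code{"N_limited"}.
#' @seealso [buildCBudget()], [buildNBudget()], [evalBudget()].
#' @export
setClass("BudgetPolynomial",
  representation(degree = "integer", coefficients = "numeric",
                 regime = "character")
)

setValidity("BudgetPolynomial", function(object) {
  msgs <- character()
  if (!object@degree %in% c(2L, 3L))
    msgs <- c(msgs, "degree must be 2 or 3")
  if (length(object@coefficients) != object@degree + 1L)
    msgs <- c(msgs, "need degree + 1 coefficients (highest degree first)")
  if (!object@regime %in% c("C_limited", "N_limited"))
    msgs <- c(msgs, "regime must be 'C_limited' or 'N_limited'")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# MonodParams
# ---------------------------------------------------------------------------

#' Monod kinetics parameters
#'
#' @slot mu_max maximum specific growth rate (day^-1), > 0.
#' @slot Ks half-saturation constant (uM), > 0: the substrate concentration
#'   at which growth equals half its maximum.
#' @seealso [monodParams()], [monodGrowth()].
#' @export
setClass("MonodParams",
  representation(mu_max = "numeric", Ks = "numeric"))

setValidity("MonodParams", function(object) {
  msgs <- character()
  if (length(object@mu_max) != 1L || !is.finite(object@mu_max) ||
      object@mu_max <= 0)
    msgs <- c(msgs, "mu_max must be a single finite number > 0")
  if (length(object@Ks) != 1L || !is.finite(object@Ks) || object@Ks <= 0)
    msgs <- c(msgs, "Ks must be a single finite number > 0")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# GrowthDataset
# ---------------------------------------------------------------------------

#' Growth-versus-nitrate dataset for one species
#'
#' @slot species free-text species label.
#' @slot irradiance irradiance of the growth experiment
#'   (umol photons m^-2 s^-1).
#' @slot no3 nitrate concentrations (uM), finite and non-negative.
#' @slot mu_obs observed specific growth rates (day^-1).
#' @slot provenance \code{"synthetic"} or \code{"file"}.
#' @seealso [growthDataset()], [generateMonodDataset()],
#'   [generateCfmDataset()], [readDatasetCsv()].
#' @export
setClass("GrowthDataset",
  representation(species = "character", irradiance = "numeric",
                 no3 = "numeric", mu_obs = "numeric",
                 provenance = "character")
)

setValidity("GrowthDataset", function(object) {
  msgs <- character()
  if (length(object@no3) < 1L)
    msgs <- c(msgs, "dataset needs at least one point")
  if (length(object@no3) != length(object@mu_obs))
    msgs <- c(msgs, "no3 and mu_obs must have equal length")
  if (any(!is.finite(object@no3)) || any(object@no3 < 0))
    msgs <- c(msgs, "no3 values must be finite and non-negative")
  if (any(!is.finite(object@mu_obs)))
    msgs <- c(msgs, "mu_obs values must be finite")
  if (length(object@irradiance) != 1L || !is.finite(object@irradiance) ||
      object@irradiance < 0)
    msgs <- c(msgs, "irradiance must be a single non-negative number")
  if (!object@provenance %in% c("synthetic", "file"))
    msgs <- c(msgs, "provenance must be 'synthetic' or 'file'")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# McmcChain
# ---------------------------------------------------------------------------

#' Metropolis-Hastings chain
#'
#' @slot samples iteration x parameter matrix of sampled values (on the
#'   scale the target was defined on).
#' @slot logPost log-posterior trace, one value per iteration.
#' @slot accepted logical accept/reject sequence.
#' @slot acceptanceRate fraction of accepted proposals, in [0, 1].
#' @slot seed integer seed the chain was generated under.
#' @slot burnIn number of initial iterations regarded as burn-in.
#' @seealso [metropolisHastings()].
#' @export
setClass("McmcChain",
  representation(samples = "matrix", logPost = "numeric",
                 accepted = "logical", acceptanceRate = "numeric",
                 seed = "numeric", burnIn = "integer")
)

setValidity("McmcChain", function(object) {
  msgs <- character()
  n <- nrow(object@samples)
  if (length(object@logPost) != n || length(object@accepted) != n)
    msgs <- c(msgs, "logPost and accepted must match the number of samples")
  if (abs(object@acceptanceRate - mean(object@accepted)) > 1e-12)
    msgs <- c(msgs, "acceptanceRate inconsistent with accept/reject record")
  if (object@burnIn < 0L || object@burnIn >= n)
    msgs <- c(msgs, "burnIn must be in [0, iterations)")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# FitResult
# ---------------------------------------------------------------------------

#' Result of a model fit
#'
#' @slot model \code{"monod"} or \code{"cfm"}.
#' @slot estimate named point estimates: the chain state attaining the
#'   maximum recorded log-posterior.
#' @slot postMean named posterior means (after burn-in).
#' @slot ci parameter x 2 matrix of central 95 percent posterior intervals.
#' @slot rss residual sum of squares of the model curve at the point
#'   estimate ((day^-1)^2).
#' @slot sigma observation noise scale used in the likelihood (day^-1).
#' @slot chain the underlying [McmcChain-class].
#' @seealso [fitMonod()], [fitCfm()].
#' @export
setClass("FitResult",
  representation(model = "character", estimate = "numeric",
                 postMean = "numeric", ci = "matrix", rss = "numeric",
                 sigma = "numeric", chain = "McmcChain")
)

setValidity("FitResult", function(object) {
  msgs <- character()
  if (!object@model %in% c("monod", "cfm"))
    msgs <- c(msgs, "model must be 'monod' or 'cfm'")
  p <- length(object@estimate)
  if (is.null(names(object@estimate)))
    msgs <- c(msgs, "estimate must be named")
  if (nrow(object@ci) != p || ncol(object@ci) != 2L)
    msgs <- c(msgs, "ci must be a parameter x 2 matrix")
  if (object@rss < 0) msgs <- c(msgs, "rss must be >= 0")
  if (length(msgs)) msgs else TRUE
})
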