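#' Construct an allocation-model parameter set
#'
#' User-facing constructor for [CfmParams-class].  The defaults describe a
#' generic nitrate-limited phytoplankton culture growing at about one
#' doubling per day under 200 umol photons m^-2 s^-1; see the package
#' vignette for the reasoning behind each value.  The biosynthetic protein
#' coefficient \code{k_bio} is tied to the photosynthetic apparatus through
#' \code{k_bio = A_pho / r_bio_pho} unless given explicitly, so that fitting
#' \code{A_pho} rescales both protein demands coherently.
#'
#' Feasibility is checked eagerly: the carbon pools that persist at zero
#' growth (essential protein, minimum RNA, DNA, other C, N storage,
#' maintenance-driven chlorophyll and its lipid) must sum to less than one,
#' otherwise no carbon remains for growth machinery and the parameter set is
#' rejected with a diagnostic naming the offending total.
#'
#' @param P_max_chl maximum C fixation per chlorophyll C (day^-1).
#' @param O_I irradiance saturation coefficient ((umol m^-2 s^-1)^-1).
#' @param I irradiance of the experiment (umol photons m^-2 s^-1).
#' @param E biosynthesis excretion/cost fraction (dimensionless).
#' @param m maintenance respiration (day^-1).
#' @param A_pho photosynthetic protein C : chlorophyll C ratio (fitted).
#' @param A_plip thylakoid lipid C : chlorophyll C ratio.
#' @param r_bio_pho fixed ratio \code{A_pho / k_bio}.
#' @param k_bio biosynthetic protein C quota per unit growth rate (day);
#'   defaults to \code{A_pho / r_bio_pho}.
#' @param Q_pro_ess_C essential protein C quota.
#' @param A_rna RNA C per protein C per unit growth rate (day).
#' @param Q_rna_min_C minimum RNA C quota.
#' @param Q_dna_C DNA C quota.
#' @param Q_oth_C other essential C quota.
#' @param Q_nsto_C N-storage C quota when N is replete.
#' @param Y_pro_NC,Y_rna_NC,Y_dna_NC,Y_chl_NC,Y_nsto_NC N:C ratios of the
#'   N-bearing pools (mol N / mol C).  The protein default 1/4.49 encodes
#'   the canonical protein C:N ratio of 4.49:1; RNA and DNA use nucleotide
#'   stoichiometry, chlorophyll the 4 N per 55 C of the chlorin ring.
#' @param A_N nitrate uptake affinity
#'   (mol N (mol cell C)^-1 day^-1 uM^-1) (fitted).
#' @param check if \code{TRUE} (default) reject infeasible sets eagerly.
#' @return a validated [CfmParams-class] object.
#' @examples
#' p <- cfmParams()
#' cLimitedGrowth(p)
#' @export
cfmParams <- function(P_max_chl = 50, O_I = 0.008, I = 200,
                      E = 0.6, m = 0.1,
                      A_pho = 3.0, A_plip = 0.12,
                      r_bio_pho = 15, k_bio = A_pho / r_bio_pho,
                      Q_pro_ess_C = 0.15, A_rna = 0.3, Q_rna_min_C = 0.01,
                      Q_dna_C = 0.008, Q_oth_C = 0.25, Q_nsto_C = 0,
                      Y_pro_NC = 1 / 4.49, Y_rna_NC = 0.394,
                      Y_dna_NC = 0.394, Y_chl_NC = 4 / 55,
                      Y_nsto_NC = 0.5,
                      A_N = 0.1, check = TRUE) {
  obj <- new("CfmParams",
    P_max_chl = P_max_chl, O_I = O_I, I = I, E = E, m = m,
    A_pho = A_pho, A_plip = A_plip, k_bio = k_bio, r_bio_pho = r_bio_pho,
    Q_pro_ess_C = Q_pro_ess_C, A_rna = A_rna, Q_rna_min_C = Q_rna_min_C,
    Q_dna_C = Q_dna_C, Q_oth_C = Q_oth_C, Q_nsto_C = Q_nsto_C,
    Y_pro_NC = Y_pro_NC, Y_rna_NC = Y_rna_NC, Y_dna_NC = Y_dna_NC,
    Y_chl_NC = Y_chl_NC, Y_nsto_NC = Y_nsto_NC, A_N = A_N)
  if (check) .assert_feasible(obj)
  obj
}

#' Copy a parameter set with fitted parameters replaced
#'
#' Returns \code{params} with \code{A_pho} and/or \code{A_N} replaced;
#' \code{k_bio} is re-slaved to \code{A_pho / r_bio_pho} whenever
#' \code{A_pho} changes, preserving the fixed biosynthesis-to-photosynthesis
#' protein ratio used during fitting.
#'
#' @param params a [CfmParams-class] object.
#' @param A_pho,A_N new values (omit to keep).
#' @param check eager feasibility check (default \code{TRUE}).
#' @return a [CfmParams-class] object.
#' @export
setFittedParams <- function(params, A_pho = NULL, A_N = NULL, check = TRUE) {
  stopifnot(is(params, "CfmParams"))
  if (!is.null(A_pho)) {
    params@A_pho <- A_pho
    params@k_bio <- A_pho / params@r_bio_pho
  }
  if (!is.null(A_N)) params@A_N <- A_N
  validObject(params)
  if (check) .assert_feasible(params)
  params
}

# Constant C pools at mu = 0 (essential protein + maintenance-driven
# chlorophyll apparatus + minimum RNA + DNA + other + replete N storage).
.constant_pools_mu0 <- function(params) {
  tm <- .budget_terms(params)
  tm$p0 + params@Q_rna_min_C + params@Q_dna_C +
    (1 + params@A_plip) * tm$i_chl + params@Q_nsto_C + params@Q_oth_C
}

.assert_feasible <- function(params) {
  tot <- .constant_pools_mu0(params)
  if (tot >= 1)
    stop("infeasible parameter set: constant C pools at mu = 0 sum to ",
         signif(tot, 6),
         " >= 1 (essential protein + min RNA + DNA + other C + ",
         "N storage + maintenance chlorophyll); no carbon left for growth",
         call. = FALSE)
  invisible(TRUE)
}
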