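## Core constitutive relations and the two elemental-budget solvers.
##
## All quotas are per mol cellular C.  Writing the chlorophyll quota as an
## affine function of growth rate, QC_chl = s_chl*mu + i_chl, the protein
## quota is affine too (p1*mu + p0) and the RNA quota quadratic; closing the
## carbon budget (pools sum to 1, C storage empty) then gives a quadratic in
## mu, and balancing diffusive nitrate uptake A_N*[NO3-] against growth
## dilution mu*Q_N(mu) gives a cubic, because Q_N(mu) is quadratic.

#' Per-chlorophyll photosynthesis rate
#'
#' Saturating light response \eqn{P = P^{Chl}_{max}(1 - e^{-O_I I})}:
#' gross C fixation per mol chlorophyll C per day.
#'
#' @param I irradiance (umol photons m^-2 s^-1), >= 0; vectorized.
#' @param params a [CfmParams-class] object (uses \code{P_max_chl}, \code{O_I}).
#' @return fixation rate(s) in [0, P_max_chl) (day^-1).
#' @export
photosynthesisRate <- function(I, params) {
  stopifnot(is(params, "CfmParams"))
  if (any(!is.finite(I)) || any(I < 0))
    stop("irradiance must be finite and >= 0", call. = FALSE)
  params@P_max_chl * (1 - exp(-params@O_I * I))
}

# Affine/quadratic building blocks shared by every budget computation.
# Returns slopes/intercepts of QC_chl and QC_pro, the N-quota quadratic
# (q2, q1, q0) and the C-budget quadratic (aC, bC, cC).
.budget_terms <- function(params) {
  P <- photosynthesisRate(params@I, params)
  if (P <= 0)
    stop("infeasible environment: zero photosynthesis (I = ", params@I,
         ") cannot meet any carbon demand", call. = FALSE)
  s_chl <- (1 + params@E) / P
  i_chl <- params@m / P
  p1 <- params@A_pho * s_chl + params@k_bio
  p0 <- params@A_pho * i_chl + params@Q_pro_ess_C
  q2 <- params@Y_rna_NC * params@A_rna * p1
  q1 <- params@Y_pro_NC * p1 + params@Y_rna_NC * params@A_rna * p0 +
    params@Y_chl_NC * s_chl
  q0 <- params@Y_pro_NC * p0 + params@Y_rna_NC * params@Q_rna_min_C +
    params@Y_dna_NC * params@Q_dna_C + params@Y_chl_NC * i_chl
  aC <- params@A_rna * p1
  bC <- p1 + params@A_rna * p0 + (1 + params@A_plip) * s_chl
  cC <- p0 + params@Q_rna_min_C + params@Q_dna_C +
    (1 + params@A_plip) * i_chl + params@Q_nsto_C + params@Q_oth_C - 1
  list(P = P, s_chl = s_chl, i_chl = i_chl, p1 = p1, p0 = p0,
       q2 = q2, q1 = q1, q0 = q0, aC = aC, bC = bC, cC = cC)
}

#' Chlorophyll carbon quota at a given growth rate
#'
#' Chlorophyll is sized so that gross C fixation covers net growth, the
#' biosynthetic cost fraction and maintenance respiration:
#' \eqn{Q_C^{Chl} = (\mu(1+E) + m) / P(I)}.
#'
#' @param mu specific growth rate (day^-1), >= 0; vectorized.
#' @param params a [CfmParams-class] object.
#' @return chlorophyll C quota(s), affine and increasing in \code{mu}.
#' @export
chlorophyllQuota <- function(mu, params) {
  stopifnot(is(params, "CfmParams"))
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("growth rate must be finite and >= 0", call. = FALSE)
  tm <- .budget_terms(params)
  tm$s_chl * mu + tm$i_chl
}

#' Protein carbon quota and its three components
#'
#' Photosynthetic protein scales with the chlorophyll quota
#' (constant machinery composition, factor \code{A_pho}), biosynthetic
#' protein with growth rate (\code{k_bio * mu}), and a constant essential
#' protein pool remains at zero growth.
#'
#' @inheritParams chlorophyllQuota
#' @return a list with vectors \code{total}, \code{pho}, \code{bio},
#'   \code{ess}; \code{total} is their sum.
#' @export
proteinQuota <- function(mu, params) {
  qchl <- chlorophyllQuota(mu, params)
  pho <- params@A_pho * qchl
  bio <- params@k_bio * mu
  ess <- rep(params@Q_pro_ess_C, length(mu))
  list(total = pho + bio + ess, pho = pho, bio = bio, ess = ess)
}

#' RNA carbon quota
#'
#' Linear RNA--protein--growth coupling:
#' \eqn{Q_C^{RNA} = Q^{RNA,min}_C + A_{RNA}\,\mu\,Q_C^{Pro}}.
#'
#' @inheritParams chlorophyllQuota
#' @param QC_pro protein C quota(s) at the same growth rate(s).
#' @return RNA C quota(s), always >= \code{Q_rna_min_C}.
#' @export
rnaQuota <- function(mu, QC_pro, params) {
  stopifnot(is(params, "CfmParams"))
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("growth rate must be finite and >= 0", call. = FALSE)
  if (any(QC_pro < 0)) stop("QC_pro must be >= 0", call. = FALSE)
  params@Q_rna_min_C + params@A_rna * mu * QC_pro
}

# Total nitrogen quota Q_N(mu) (mol N / mol cell C).  Under N limitation the
# N-storage pool is empty; under C limitation it holds Q_nsto_C worth of C.
.nitrogen_quota <- function(mu, tm, params, regime = "N_limited") {
  qn <- (tm$q2 * mu + tm$q1) * mu + tm$q0
  if (regime == "C_limited")
    qn <- qn + params@Y_nsto_NC * params@Q_nsto_C
  qn
}

#' Total nitrogen quota at a given growth rate
#'
#' Sum of the five N-bearing pools (protein, RNA, DNA, chlorophyll and,
#' when C-limited, N storage); equals the cellular N:C ratio since quotas
#' are per cell C.  Quadratic in \code{mu} through the RNA--protein--growth
#' coupling.
#'
#' @inheritParams chlorophyllQuota
#' @param regime \code{"N_limited"} (N storage empty, default) or
#'   \code{"C_limited"}.
#' @return total N quota(s) (mol N / mol cell C).
#' @export
nitrogenQuota <- function(mu, params, regime = c("N_limited", "C_limited")) {
  regime <- match.arg(regime)
  stopifnot(is(params, "CfmParams"))
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("growth rate must be finite and >= 0", call. = FALSE)
  .nitrogen_quota(mu, .budget_terms(params), params, regime)
}

#' Build the carbon-budget polynomial
#'
#' Substituting the constitutive relations into the carbon closure (all C
#' pools sum to one, C storage empty, N storage at its replete level) gives
#' a quadratic \eqn{0 = a_C\mu^2 + b_C\mu + c_C}; its positive root is the
#' C-limited growth rate.  The quadratic term exists only through the
#' RNA--protein--growth coupling, so it vanishes when \code{A_rna = 0}.
#'
#' @param params a [CfmParams-class] object.
#' @return a degree-2 [BudgetPolynomial-class] (coefficients highest first).
#' @export
buildCBudget <- function(params) {
  stopifnot(is(params, "CfmParams"))
  tm <- .budget_terms(params)
  new("BudgetPolynomial", degree = 2L,
      coefficients = c(tm$aC, tm$bC, tm$cC), regime = "C_limited")
}

#' Build the nitrogen-budget polynomial
#'
#' At steady state diffusive uptake balances growth dilution,
#' \eqn{A_N[\mathrm{NO_3^-}] = \mu\,Q_N(\mu)}; because \eqn{Q_N} is
#' quadratic in \eqn{\mu} this is a cubic
#' \eqn{0 = a_N\mu^3 + b_N\mu^2 + c_N\mu + d_N} with
#' \eqn{d_N = -A_N[\mathrm{NO_3^-}]}.
#'
#' @param params a [CfmParams-class] object.
#' @param no3 nitrate concentration (uM), >= 0.
#' @return a degree-3 [BudgetPolynomial-class] (coefficients highest first).
#' @export
buildNBudget <- function(params, no3) {
  stopifnot(is(params, "CfmParams"))
  if (length(no3) != 1L || !is.finite(no3) || no3 < 0)
    stop("no3 must be a single finite concentration >= 0", call. = FALSE)
  tm <- .budget_terms(params)
  new("BudgetPolynomial", degree = 3L,
      coefficients = c(tm$q2, tm$q1, tm$q0, -params@A_N * no3),
      regime = "N_limited")
}

#' Evaluate a budget polynomial
#'
#' @param poly a [BudgetPolynomial-class].
#' @param mu growth rate(s) at which to evaluate.
#' @return polynomial value(s); ~0 at the corresponding budget's root.
#' @export
evalBudget <- function(poly, mu) {
  stopifnot(is(poly, "BudgetPolynomial"))
  co <- poly@coefficients
  out <- rep(co[1L], length(mu))
  for (k in seq_along(co)[-1L]) out <- out * mu + co[k]
  out
}

# All eight C quotas at growth rate mu, storage pools excluded (returned as
# a named vector so infeasibility diagnostics can name the pool).
.qc_pools <- function(mu, tm, params) {
  qchl <- tm$s_chl * mu + tm$i_chl
  qpro <- tm$p1 * mu + tm$p0
  c(pro = qpro,
    rna = params@Q_rna_min_C + params@A_rna * mu * qpro,
    dna = params@Q_dna_C,
    chl = qchl,
    plip_thy = params@A_plip * qchl,
    oth = params@Q_oth_C)
}

#' Carbon-limited growth rate
#'
#' Solves the carbon-budget quadratic from [buildCBudget()].  Among the real
#' roots, those whose implied pools all lie in [0, 1] are feasible; the
#' larger feasible root is returned (growth uses the full carbon budget).
#' Independent of nitrate concentration.
#'
#' @param params a [CfmParams-class] object.
#' @return the C-limited growth rate mu_C (day^-1), > 0.
#' @export
cLimitedGrowth <- function(params) {
  stopifnot(is(params, "CfmParams"))
  .assert_feasible(params)
  tm <- .budget_terms(params)
  a <- tm$aC; b <- tm$bC; cc <- tm$cC
  if (a == 0) {
    roots <- if (b != 0) -cc / b else numeric(0)
  } else {
    disc <- b * b - 4 * a * cc
    if (disc < 0)
      stop("no real root of the carbon budget: ",
           "growth machinery cannot fit the carbon budget", call. = FALSE)
    # numerically stable quadratic roots
    if (b == 0) {
      roots <- c(-1, 1) * sqrt(disc) / (2 * a)
    } else {
      qq <- -(b + sign(b) * sqrt(disc)) / 2
      roots <- unique(c(qq / a, cc / qq))
    }
  }
  roots <- roots[is.finite(roots) & roots > 0]
  feasible <- roots[vapply(roots, function(r) {
    qc <- .qc_pools(r, tm, params)
    all(qc >= -1e-12 & qc <= 1 + 1e-12)
  }, logical(1))]
  if (!length(feasible)) {
    if (length(roots)) {
      qc <- .qc_pools(max(roots), tm, params)
      bad <- names(qc)[which.max(pmax(qc - 1, -qc))]
      stop("no feasible C-limited growth rate: pool '", bad,
           "' falls outside [0, 1] at every root", call. = FALSE)
    }
    stop("no positive root of the carbon budget", call. = FALSE)
  }
  max(feasible)
}

# Root of the monotone cubic mu*Q_N(mu) = rhs for each rhs >= 0, by
# safeguarded Newton from an upper bound.  f is increasing and convex on
# mu >= 0 (non-negative coefficients), so Newton from the right converges
# monotonically; a bisection fallback guards degenerate coefficient sets.
.solve_n_balance <- function(rhs, q2, q1, q0) {
  if (q2 <= 0 && q1 <= 0 && q0 <= 0) {
    if (all(rhs == 0)) return(rep(0, length(rhs)))
    stop("no feasible N-limited growth rate: the nitrogen quota is ",
         "identically zero but uptake is positive", call. = FALSE)
  }
  ub <- rep(Inf, length(rhs))
  if (q0 > 0) ub <- pmin(ub, rhs / q0)
  if (q1 > 0) ub <- pmin(ub, sqrt(rhs / q1))
  if (q2 > 0) ub <- pmin(ub, (rhs / q2)^(1 / 3))
  mu <- ub
  for (it in 1:100) {
    f <- ((q2 * mu + q1) * mu + q0) * mu - rhs
    fp <- (3 * q2 * mu + 2 * q1) * mu + q0
    step <- ifelse(fp > 0, f / fp, 0)
    mu_new <- pmax(mu - step, 0)
    if (max(abs(mu_new - mu)) < 1e-15 * (1 + max(mu))) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  mu[rhs == 0] <- 0
  mu
}

#' Nitrogen-limited growth rate
#'
#' Solves the steady-state nitrogen balance
#' \eqn{A_N[\mathrm{NO_3^-}] = \mu\,Q_N(\mu)} (the cubic from
#' [buildNBudget()]) on the physical branch continuous from \eqn{\mu = 0}
#' at zero nitrate.  Because \eqn{\mu Q_N(\mu)} is strictly increasing for
#' \eqn{\mu \ge 0}, that branch is the unique non-negative root, and the
#' returned rate is continuous and non-decreasing in nitrate.  Equivalently
#' the growth rate is nitrogen uptake per cellular N quota,
#' \eqn{\mu = V_N / Q_N}.
#'
#' @param params a [CfmParams-class] object.
#' @param no3 nitrate concentration(s) (uM), >= 0; vectorized.
#' @return N-limited growth rate(s) mu_N (day^-1), with mu_N(0) = 0.
#' @export
nLimitedGrowth <- function(params, no3) {
  stopifnot(is(params, "CfmParams"))
  if (any(!is.finite(no3)) || any(no3 < 0))
    stop("no3 must be finite and >= 0", call. = FALSE)
  tm <- .budget_terms(params)
  .solve_n_balance(params@A_N * no3, tm$q2, tm$q1, tm$q0)
}

#' Nitrate concentration at the N-to-C limitation crossover
#'
#' The concentration at which the nitrogen-limited growth rate reaches the
#' carbon-limited one; beyond it the growth curve is flat.  Closed form:
#' \eqn{[\mathrm{NO_3^-}]^* = \mu_C\,Q_N(\mu_C) / A_N}.
#'
#' @param params a [CfmParams-class] object.
#' @return crossover concentration (uM).
#' @export
crossoverNo3 <- function(params) {
  stopifnot(is(params, "CfmParams"))
  mu_C <- cLimitedGrowth(params)
  tm <- .budget_terms(params)
  mu_C * .nitrogen_quota(mu_C, tm, params, "N_limited") / params@A_N
}

#' Assemble the full macromolecular state at a growth rate
#'
#' Populates every C and N pool from the constitutive relations.  Under N
#' limitation the N-storage pools are empty and C storage takes up the
#' residual of the carbon budget, closing it exactly; under C limitation C
#' storage is empty, N storage holds its replete quota, and \code{mu} must
#' be the C-limited rate for the budget to close.
#'
#' @param mu specific growth rate (day^-1), >= 0.
#' @param params a [CfmParams-class] object.
#' @param regime \code{"N_limited"} or \code{"C_limited"}.
#' @return a [MacromolecularState-class] object.
#' @export
allocationState <- function(mu, params,
                            regime = c("N_limited", "C_limited")) {
  regime <- match.arg(regime)
  stopifnot(is(params, "CfmParams"))
  if (length(mu) != 1L || !is.finite(mu) || mu < 0)
    stop("mu must be a single finite growth rate >= 0", call. = FALSE)
  tm <- .budget_terms(params)
  qc <- .qc_pools(mu, tm, params)
  bad_qc <- names(qc)[qc < -1e-12 | qc > 1 + 1e-12]
  if (length(bad_qc))
    stop("infeasible state: pool '", bad_qc[1L],
         "' outside [0, 1] at mu = ", signif(mu, 6), call. = FALSE)
  qc_nsto <- if (regime == "C_limited") params@Q_nsto_C else 0
  resid <- 1 - sum(qc) - qc_nsto
  if (regime == "N_limited") {
    if (resid < -1e-9)
      stop("internal consistency: negative carbon-storage residual (",
           signif(resid, 4), ") at mu = ", signif(mu, 6), call. = FALSE)
    qc_csto <- max(resid, 0)
  } else {
    if (abs(resid) > 1e-9)
      stop("carbon budget does not close at mu = ", signif(mu, 6),
           " under C limitation (residual ", signif(resid, 4), ")",
           call. = FALSE)
    qc_csto <- 0
  }
  pools <- c(qc, nsto = qc_nsto, csto = qc_csto)
  bad <- names(pools)[pools < -1e-12 | pools > 1 + 1e-12]
  if (length(bad))
    stop("infeasible state: pool '", bad[1L], "' outside [0, 1] at mu = ",
         signif(mu, 6), call. = FALSE)
  qn <- c(pro = params@Y_pro_NC * qc[["pro"]],
          rna = params@Y_rna_NC * qc[["rna"]],
          dna = params@Y_dna_NC * qc[["dna"]],
          chl = params@Y_chl_NC * qc[["chl"]],
          nsto = params@Y_nsto_NC * qc_nsto)
  new("MacromolecularState", mu = mu,
      QC_pro = qc[["pro"]], QC_rna = qc[["rna"]], QC_dna = qc[["dna"]],
      QC_chl = qc[["chl"]], QC_plip_thy = qc[["plip_thy"]],
      QC_nsto = qc_nsto, QC_csto = qc_csto, QC_oth = qc[["oth"]],
      QN_pro = qn[["pro"]], QN_rna = qn[["rna"]], QN_dna = qn[["dna"]],
      QN_chl = qn[["chl"]], QN_nsto = qn[["nsto"]],
      QN_total = sum(qn), limitation = regime)
}

#' Realized growth rate and allocation at a nitrate concentration
#'
#' The realized rate is the minimum of the carbon-limited and
#' nitrogen-limited rates, labelled by the binding budget: at low nitrate
#' growth tracks nitrogen uptake (with carbon accumulating as storage),
#' while beyond the crossover concentration the carbon budget caps growth
#' and the curve is exactly flat.  The min rule produces the saturating,
#' two-regime growth-versus-nitrate relationship.
#'
#' @param params a [CfmParams-class] object.
#' @param no3 nitrate concentration (uM), >= 0.
#' @return a list with elements \code{mu} (day^-1) and \code{state}
#'   (a [MacromolecularState-class]).
#' @export
realizedGrowth <- function(params, no3) {
  stopifnot(is(params, "CfmParams"))
  if (length(no3) != 1L || !is.finite(no3) || no3 < 0)
    stop("no3 must be a single finite concentration >= 0", call. = FALSE)
  mu_C <- cLimitedGrowth(params)
  mu_N <- nLimitedGrowth(params, no3)
  if (mu_N < mu_C)
    list(mu = mu_N, state = allocationState(mu_N, params, "N_limited"))
  else
    list(mu = mu_C, state = allocationState(mu_C, params, "C_limited"))
}

# Vectorized realized growth rate only (no state assembly); used by the
# fitting likelihood and the generators where speed matters.
.realized_mu <- function(params, no3) {
  pmin(cLimitedGrowth(params), nLimitedGrowth(params, no3))
}

#' Sweep nitrate and tabulate growth, stoichiometry and C allocation
#'
#' One row per grid concentration: realized growth rate, binding
#' limitation, cellular N:C ratio and the percentage of cellular carbon in
#' each of the eight pools (columns \code{pct_*}, summing to 100).
#'
#' @param params a [CfmParams-class] object.
#' @param no3_grid non-empty, sorted, non-negative nitrate grid (uM).
#' @return a data.frame with columns \code{no3}, \code{mu},
#'   \code{limitation}, \code{NC_ratio} and \code{pct_pro}, \code{pct_rna},
#'   \code{pct_dna}, \code{pct_chl}, \code{pct_plip_thy}, \code{pct_nsto},
#'   \code{pct_csto}, \code{pct_oth}.
#' @export
allocationSweep <- function(params, no3_grid) {
  stopifnot(is(params, "CfmParams"))
  if (!length(no3_grid))
    stop("no3_grid must be non-empty", call. = FALSE)
  if (any(!is.finite(no3_grid)) || any(no3_grid < 0))
    stop("no3_grid must be finite and >= 0", call. = FALSE)
  if (is.unsorted(no3_grid))
    stop("no3_grid must be sorted increasing", call. = FALSE)
  rows <- lapply(no3_grid, function(s) {
    rg <- realizedGrowth(params, s)
    st <- rg$state
    data.frame(no3 = s, mu = rg$mu, limitation = st@limitation,
               NC_ratio = st@QN_total,
               pct_pro = 100 * st@QC_pro, pct_rna = 100 * st@QC_rna,
               pct_dna = 100 * st@QC_dna, pct_chl = 100 * st@QC_chl,
               pct_plip_thy = 100 * st@QC_plip_thy,
               pct_nsto = 100 * st@QC_nsto, pct_csto = 100 * st@QC_csto,
               pct_oth = 100 * st@QC_oth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
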