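# Constitutive relations, the two budget polynomials and their solvers.

test_that("photosynthesis rate saturates with irradiance", {
  p <- cfmParams()
  expect_identical(photosynthesisRate(0, p), 0)
  expect_equal(photosynthesisRate(log(2) / p@O_I, p), p@P_max_chl / 2)
  expect_lt(abs(photosynthesisRate(10 / p@O_I, p) - p@P_max_chl),
            1e-4 * p@P_max_chl)
  # strictly increasing and concave
  I <- seq(0, 600, by = 50)
  r <- photosynthesisRate(I, p)
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(diff(r)) < 0))
  expect_true(all(r < p@P_max_chl))
  expect_error(photosynthesisRate(-1, p), "irradiance")
})

test_that("chlorophyll quota covers growth, cost and maintenance demand", {
  # O_I * I large makes the light response saturate to exactly P_max_chl
  p <- cfmParams(P_max_chl = 5, O_I = 100, I = 1, E = 0.3, m = 0.1)
  expect_equal(chlorophyllQuota(0.5, p), (0.5 * 1.3 + 0.1) / 5)
  expect_equal(chlorophyllQuota(0.5, p), 0.15)
  p0 <- cfmParams(m = 0)
  expect_identical(chlorophyllQuota(0, p0), 0)
  # linear in the total C demand mu*(1+E)+m: doubling demand doubles quota
  mu1 <- 0.4
  mu2 <- (2 * (mu1 * (1 + p@E) + p@m) - p@m) / (1 + p@E)
  expect_equal(chlorophyllQuota(mu2, p), 2 * chlorophyllQuota(mu1, p))
  expect_error(chlorophyllQuota(0.1, cfmParams(I = 0, check = FALSE)),
               "infeasible environment")
})

test_that("protein quota splits into photosynthetic, biosynthetic, essential", {
  p <- cfmParams(m = 0)
  pq <- proteinQuota(0, p)
  expect_equal(pq$total, p@Q_pro_ess_C)
  expect_equal(pq$pho, 0)
  # near-zero photosynthetic protein isolates the k_bio*mu + ess terms
  p2 <- cfmParams(A_pho = 1e-12, r_bio_pho = 1e-12, Q_pro_ess_C = 0.05,
                  m = 0)
  expect_equal(proteinQuota(0.2, p2)$total, 1 * 0.2 + 0.05,
               tolerance = 1e-9)
  # slope of the total equals k_bio + A_pho*(1+E)/P (finite difference)
  p3 <- cfmParams()
  h <- 1e-6
  slope_fd <- (proteinQuota(0.5 + h, p3)$total -
               proteinQuota(0.5 - h, p3)$total) / (2 * h)
  slope_sym <- p3@k_bio +
    p3@A_pho * (1 + p3@E) / photosynthesisRate(p3@I, p3)
  expect_equal(slope_fd, slope_sym, tolerance = 1e-6)
})

test_that("RNA quota is the minimum plus growth-protein coupling", {
  p <- cfmParams()
  expect_equal(rnaQuota(0, 0.3, p), p@Q_rna_min_C)
  p0 <- cfmParams(A_rna = 0)
  expect_equal(rnaQuota(1.3, 0.5, p0), p0@Q_rna_min_C)
  p1 <- cfmParams(A_rna = 2, Q_rna_min_C = 0.01)
  expect_equal(rnaQuota(0.3, 0.4, p1), 0.01 + 2 * 0.3 * 0.4)
})

test_that("carbon-budget quadratic matches direct pool substitution", {
  p <- cfmParams()
  poly <- buildCBudget(p)
  expect_s4_class(poly, "BudgetPolynomial")
  expect_identical(poly@degree, 2L)
  # value at mu = 0 is (constant pools incl. maintenance chlorophyll) - 1
  expect_equal(evalBudget(poly, 0), qcPoolSum(0, p) - 1)
  # at arbitrary mu the polynomial is the closure residual with sign
  # convention sum(QC) - 1
  for (mu in c(0.2, 0.7, 1.4))
    expect_equal(evalBudget(poly, mu), qcPoolSum(mu, p) - 1)
  # the quadratic term exists only through the RNA-protein-growth coupling
  expect_identical(buildCBudget(cfmParams(A_rna = 0))@coefficients[1L], 0)
})

test_that("C-limited growth matches the bisection oracle on random sets", {
  set.seed(101)
  for (i in 1:25) {
    p <- randomFeasibleParams()
    mu <- cLimitedGrowth(p)
    expect_equal(mu, bisectMuC(p), tolerance = 1e-8)
    expect_lt(abs(evalBudget(buildCBudget(p), mu)), 1e-9)
    expect_gt(mu, 0)
  }
})

test_that("more light-harvesting capacity never slows C-limited growth", {
  set.seed(102)
  p <- randomFeasibleParams()
  mus <- vapply(seq(p@P_max_chl, 4 * p@P_max_chl, length.out = 12),
                function(pm) {
                  q <- p; q@P_max_chl <- pm; cLimitedGrowth(q)
                }, numeric(1))
  expect_true(all(diff(mus) >= -1e-12))
})

test_that("infeasible constant pools are rejected with a diagnostic", {
  expect_error(cfmParams(Q_oth_C = 0.7, Q_pro_ess_C = 0.35),
               "infeasible parameter set")
  expect_error(cLimitedGrowth(cfmParams(Q_oth_C = 0.7, Q_pro_ess_C = 0.35,
                                        check = FALSE)),
               "infeasible")
})

test_that("nitrogen-budget cubic encodes the steady-state balance", {
  p <- cfmParams()
  poly <- buildNBudget(p, 1.5)
  expect_identical(poly@degree, 3L)
  # the constant term carries the uptake side
  expect_equal(poly@coefficients[4L], -p@A_N * 1.5)
  # zero nitrate: mu = 0 is a root
  expect_identical(evalBudget(buildNBudget(p, 0), 0), 0)
  # polynomial equals mu*Q_N(mu) - A_N*no3 built from the pools
  for (mu in c(0.1, 0.6, 1.1))
    expect_equal(evalBudget(poly, mu), mu * qnTotal(mu, p) - p@A_N * 1.5)
  # without RNA and photosynthetic-protein coupling Q_N is affine in mu,
  # so the cubic degenerates (leading coefficient 0)
  pd <- cfmParams(A_rna = 0)
  expect_identical(buildNBudget(pd, 1)@coefficients[1L], 0)
  expect_error(buildNBudget(p, -0.1), "no3")
})

test_that("N-limited growth matches the bisection oracle and Eq.-9 form", {
  set.seed(103)
  for (i in 1:15) {
    p <- randomFeasibleParams()
    for (no3 in c(0.05, 0.5, 2, 10)) {
      mu <- nLimitedGrowth(p, no3)
      expect_equal(mu, bisectMuN(p, no3), tolerance = 1e-8)
      # steady state: uptake balances growth dilution
      expect_lt(abs(p@A_N * no3 - mu * qnTotal(mu, p)), 1e-9)
      # growth rate = uptake per cellular N quota
      expect_equal(mu, p@A_N * no3 / qnTotal(mu, p), tolerance = 1e-9)
    }
    expect_identical(nLimitedGrowth(p, 0), 0)
    # strictly increasing along a nitrate grid
    grid <- seq(0, 4 * crossoverNo3(p), length.out = 20)
    expect_true(all(diff(nLimitedGrowth(p, grid)) > 0))
  }
})

test_that("realized growth is the min rule with matching storage", {
  p <- cfmParams()
  mu_C <- cLimitedGrowth(p)
  hi <- realizedGrowth(p, 1e4)
  expect_equal(hi$mu, mu_C)
  expect_identical(limitation(hi$state), "C_limited")
  expect_identical(hi$state@QC_csto, 0)
  lo <- realizedGrowth(p, 0)
  expect_identical(lo$mu, 0)
  expect_identical(limitation(lo$state), "N_limited")
  expect_identical(lo$state@QC_nsto, 0)
  expect_identical(lo$state@QN_nsto, 0)
  # under N limitation C storage is the budget residual, >= 0
  mid <- realizedGrowth(p, crossoverNo3(p) / 2)
  expect_gt(mid$state@QC_csto, 0)
  expect_equal(sum(carbonQuotas(mid$state)), 1, tolerance = 1e-12)
})

test_that("the growth curve is continuous at the limitation crossover", {
  set.seed(104)
  for (i in 1:10) {
    p <- randomFeasibleParams()
    mu_C <- cLimitedGrowth(p)
    # closed-form crossover agrees with bisection on mu_C - mu_N
    star <- crossoverNo3(p)
    f <- function(s) mu_C - nLimitedGrowth(p, s)
    star_bis <- uniroot(f, c(0, 4 * star + 1), tol = 1e-12)$root
    expect_equal(star, star_bis, tolerance = 1e-8)
    expect_lt(abs(mu_C - nLimitedGrowth(p, star)), 1e-8)
    # flat (exactly mu_C) beyond the crossover
    expect_identical(realizedGrowth(p, star * 1.5)$mu, mu_C)
    expect_identical(realizedGrowth(p, star * 3)$mu, mu_C)
  }
})

test_that("realized growth approaches the C-limited cap as affinity grows", {
  set.seed(105)
  p <- randomFeasibleParams()
  mu_C <- cLimitedGrowth(p)
  p@A_N <- p@A_N * 1e6
  expect_equal(realizedGrowth(p, 0.5)$mu, mu_C)
})

test_that("allocation states close both elemental budgets", {
  set.seed(106)
  for (i in 1:20) {
    p <- randomFeasibleParams()
    no3 <- runif(1, 0, 3 * crossoverNo3(p))
    st <- realizedGrowth(p, no3)$state
    expect_lt(abs(1 - sum(carbonQuotas(st))), 1e-9)
    qn <- nitrogenQuotas(st)
    expect_equal(unname(qn["total"]), sum(qn[c("pro", "rna", "dna", "chl",
                                               "nsto")]), tolerance = 1e-12)
    expect_true(all(carbonQuotas(st) >= 0 & carbonQuotas(st) <= 1))
  }
})

test_that("protein pool stoichiometry is the canonical C:N of 4.49", {
  st <- allocationState(0.5, cfmParams(), "N_limited")
  expect_equal(st@QC_pro / st@QN_pro, 4.49)
})

test_that("allocation state rejects growth rates the budget cannot hold", {
  p <- cfmParams()
  expect_error(allocationState(100, p, "N_limited"), "pool")
  expect_error(allocationState(-0.1, p), "mu")
})

test_that("allocation sweep reproduces the two-regime narrative", {
  set.seed(107)
  for (i in 1:8) {
    p <- randomFeasibleParams()
    grid <- seq(0, 3 * crossoverNo3(p), length.out = 25)
    sw <- allocationSweep(p, grid)
    expect_identical(nrow(sw), length(grid))
    pct <- rowSums(sw[, grep("^pct_", names(sw))])
    expect_true(all(abs(pct - 100) < 1e-6))
    # growth non-decreasing, exactly constant once C-limited
    expect_true(all(diff(sw$mu) >= -1e-12))
    first_c <- match("C_limited", sw$limitation)
    expect_false(is.na(first_c))
    expect_true(all(sw$mu[first_c:nrow(sw)] == sw$mu[first_c]))
    # within the N-limited branch: N:C rises, C storage drains
    nseg <- which(sw$limitation == "N_limited")
    expect_true(all(diff(sw$NC_ratio[nseg]) >= -1e-12))
    expect_true(all(diff(sw$pct_csto[nseg]) <= 1e-12))
  }
  p <- cfmParams()
  expect_error(allocationSweep(p, numeric(0)), "non-empty")
  expect_error(allocationSweep(p, c(2, 1)), "sorted")
  expect_error(allocationSweep(p, c(-1, 1)), "finite and >= 0")
})
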