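# Seeded synthetic growth-versus-nitrate generators.

test_that("zero-noise datasets lie exactly on their generating curves", {
  mp <- monodParams(1.1, 2.5)
  d <- generateMonodDataset(mp, seq(0, 10, 1), noise_sd = 0, seed = 1)
  expect_identical(d@mu_obs, monodGrowth(d@no3, mp))
  cp <- cfmParams()
  dc <- generateCfmDataset(cp, noise_sd = 0, seed = 1)
  mu_true <- vapply(dc@no3, function(s) realizedGrowth(cp, s)$mu,
                    numeric(1))
  expect_equal(dc@mu_obs, mu_true, tolerance = 1e-12)
  # flat beyond the crossover
  flat <- dc@mu_obs[dc@no3 > crossoverNo3(cp)]
  expect_true(all(flat == cLimitedGrowth(cp)))
})

test_that("generation is deterministic under a seed", {
  mp <- monodParams(1.1, 2.5)
  a <- generateMonodDataset(mp, noise_sd = 0.05, seed = 99)
  b <- generateMonodDataset(mp, noise_sd = 0.05, seed = 99)
  expect_identical(a@mu_obs, b@mu_obs)
  c2 <- generateMonodDataset(mp, noise_sd = 0.05, seed = 100)
  expect_false(identical(a@mu_obs, c2@mu_obs))
})

test_that("residual spread matches the requested noise level at large n", {
  mp <- monodParams(1.2, 3)
  grid <- rep(seq(2, 12, length.out = 10), 100)  # away from truncation
  d <- generateMonodDataset(mp, grid, noise_sd = 0.05, seed = 3)
  resid <- d@mu_obs - monodGrowth(d@no3, mp)
  expect_lt(abs(sd(resid) - 0.05), 0.005)
})

test_that("observed growth is never negative even under heavy noise", {
  mp <- monodParams(0.2, 5)
  d <- generateMonodDataset(mp, seq(0, 20, 0.5), noise_sd = 0.5, seed = 4)
  expect_true(all(d@mu_obs >= 0))
  dc <- generateCfmDataset(cfmParams(), noise_sd = 1.0, seed = 4)
  expect_true(all(dc@mu_obs >= 0))
})

test_that("the default allocation-model grid spans both regimes", {
  cp <- cfmParams()
  dc <- generateCfmDataset(cp, noise_sd = 0, seed = 5)
  labels <- vapply(dc@no3, function(s)
    limitation(realizedGrowth(cp, s)$state), character(1))
  expect_true(all(c("N_limited", "C_limited") %in% labels))
})

test_that("generator input validation", {
  mp <- monodParams(1, 1)
  expect_error(generateMonodDataset(mp, numeric(0)), "non-empty")
  expect_error(generateMonodDataset(mp, 1:3, noise_sd = -0.1), "noise_sd")
})
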