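# Metropolis-Hastings engine and the two fitting pipelines.

test_that("Gaussian log-likelihood has its analytic values and shape", {
  sig <- 0.07
  obs <- c(0.2, 0.5, 0.9)
  expect_equal(gaussianLogLikelihood(obs, obs, sig),
               3 * log(1 / (sig * sqrt(2 * pi))))
  # one point, residual exactly sigma
  expect_equal(gaussianLogLikelihood(0.5, 0.5 + sig, sig),
               -log(sig * sqrt(2 * pi)) - 0.5)
  # monotone decreasing in the residual magnitude
  base <- gaussianLogLikelihood(obs + 0.01, obs, sig)
  expect_lt(gaussianLogLikelihood(obs + 0.02, obs, sig), base)
  expect_error(gaussianLogLikelihood(1:3, 1:2, sig), "equal length")
  expect_error(gaussianLogLikelihood(1, 1, 0), "sigma")
})

test_that("sampler accepts everything on a flat target and is seeded", {
  flat <- metropolisHastings(function(th) 0, c(x = 0), 1, nIter = 500,
                             seed = 7)
  expect_identical(flat@acceptanceRate, 1)
  a <- metropolisHastings(function(th) -sum(th^2) / 2, c(x = 1), 0.8,
                          nIter = 2000, seed = 42)
  b <- metropolisHastings(function(th) -sum(th^2) / 2, c(x = 1), 0.8,
                          nIter = 2000, seed = 42)
  expect_identical(a@samples, b@samples)
  expect_identical(a@accepted, b@accepted)
  expect_error(metropolisHastings(function(th) -Inf, c(x = 0), 1, 10,
                                  seed = 1), "re-initialize")
})

test_that("sampler reproduces a standard normal target", {
  ch <- metropolisHastings(function(th) -th^2 / 2, c(x = 0), 2.4,
                           nIter = 50000, seed = 12)
  x <- posteriorSamples(ch)
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(var(as.numeric(x)) - 1), 0.1)
  expect_gt(ch@acceptanceRate, 0.05)
  expect_lt(ch@acceptanceRate, 0.95)
})

test_that("Monod fit recovers the generating parameters without noise", {
  true <- monodParams(1.2, 3.0)
  d <- generateMonodDataset(true, seq(0, 12, length.out = 10),
                            noise_sd = 0, seed = 5)
  f <- fitMonod(d, iterations = 20000, seed = 6)
  expect_lt(abs(coef(f)[["mu_max"]] / 1.2 - 1), 0.01)
  expect_lt(abs(coef(f)[["Ks"]] / 3.0 - 1), 0.01)
  expect_lt(fitRss(f), 1e-4)
  expect_gt(acceptanceRate(f), 0.05)
  expect_lt(acceptanceRate(f), 0.95)
  # the point estimate attains the maximum recorded log-posterior
  ch <- f@chain
  expect_identical(unname(coef(f)),
                   unname(ch@samples[which.max(ch@logPost), ]))
})

test_that("Monod fit rejects degenerate datasets", {
  expect_error(fitMonod(growthDataset(c(1, 2), c(0.1, 0.2))),
               "at least 3")
  expect_error(fitMonod(growthDataset(1:4, rep(0, 4))), "growth rates")
})

test_that("allocation-model fit recovers A_pho and A_N without noise", {
  true <- cfmParams(A_pho = 3.5, A_N = 0.08)
  d <- generateCfmDataset(true, noise_sd = 0, seed = 8)
  f <- fitCfm(d, cfmParams(), iterations = 12000, seed = 9)
  expect_lt(abs(coef(f)[["A_pho"]] / 3.5 - 1), 0.05)
  expect_lt(abs(coef(f)[["A_N"]] / 0.08 - 1), 0.05)
  # the fitted curve beats a Monod fit on its own (noise-free) data
  fm <- fitMonod(d, iterations = 8000, seed = 9)
  expect_lte(fitRss(f), fitRss(fm))
})

test_that("data-point order does not change the allocation-model fit", {
  true <- cfmParams(A_pho = 2.5, A_N = 0.12)
  d <- generateCfmDataset(true, noise_sd = 0.02, seed = 10)
  idx <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  d2 <- growthDataset(d@no3[idx], d@mu_obs[idx], irradiance = d@irradiance)
  f1 <- fitCfm(d, cfmParams(), iterations = 4000, seed = 11)
  f2 <- fitCfm(d2, cfmParams(), iterations = 4000, seed = 11)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("the fitted affinity scales inversely with the nitrate axis", {
  true <- cfmParams(A_pho = 3.0, A_N = 0.1)
  d <- generateCfmDataset(true, noise_sd = 0, seed = 12)
  f1 <- fitCfm(d, cfmParams(), iterations = 8000, seed = 13)
  cc <- 2.5
  d2 <- growthDataset(cc * d@no3, d@mu_obs, irradiance = d@irradiance)
  f2 <- fitCfm(d2, cfmParams(), iterations = 8000, seed = 13)
  expect_equal(coef(f2)[["A_N"]], coef(f1)[["A_N"]] / cc,
               tolerance = 0.05)
  expect_equal(coef(f2)[["A_pho"]], coef(f1)[["A_pho"]], tolerance = 0.05)
})
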