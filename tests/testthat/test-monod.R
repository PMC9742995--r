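# Monod kinetics reference model.

test_that("growth equals half its maximum at the half-saturation constant", {
  p <- monodParams(mu_max = 1.2, Ks = 3.0)
  expect_identical(monodGrowth(p@Ks, p), p@mu_max / 2)
})

test_that("Monod curve passes its anchor points and stays below mu_max", {
  p <- monodParams(mu_max = 1.0, Ks = 2.0)
  expect_identical(monodGrowth(0, p), 0)
  expect_equal(monodGrowth(6, p), 0.75)
  S <- seq(0, 100, by = 2)
  mu <- monodGrowth(S, p)
  expect_true(all(mu < p@mu_max))
  expect_true(all(diff(mu) > 0))
  expect_true(all(diff(diff(mu)) < 0))
  expect_equal(monodGrowth(1e9, p), p@mu_max, tolerance = 1e-8)
})

test_that("Monod growth is equivariant under joint concentration scaling", {
  set.seed(11)
  for (i in 1:10) {
    mu_max <- runif(1, 0.2, 3)
    Ks <- runif(1, 0.1, 20)
    S <- runif(1, 0, 50)
    cc <- runif(1, 0.01, 100)
    expect_equal(monodGrowth(cc * S, monodParams(mu_max, cc * Ks)),
                 monodGrowth(S, monodParams(mu_max, Ks)))
  }
})

test_that("invalid Monod inputs are rejected", {
  expect_error(monodGrowth(-1, monodParams(1, 1)), "substrate")
  expect_error(monodParams(0, 1))
  expect_error(monodParams(1, -2))
})
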