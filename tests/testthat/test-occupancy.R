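test_that("occupancy estimates follow the Poisson droplet model", {
  e <- estimate_occupancy(10000, 20000)
  expect_equal(e$p_hat, 0.5)
  expect_equal(e$mu, log(2), tolerance = 1e-12)
  expect_false(e$saturated)

  z <- estimate_occupancy(0, 20000)
  expect_equal(z$p_hat, 0)
  expect_equal(z$mu, 0)

  # high occupancy: verified by simulating a million droplets at the implied
  # rate and recovering the positive fraction
  h <- estimate_occupancy(19000, 20000)
  expect_equal(h$p_hat, 0.95)
  expect_equal(h$mu, -log(0.05), tolerance = 1e-12)
  set.seed(42)
  frac <- mean(stats::rpois(1e6, h$mu) > 0)
  se <- sqrt(0.95 * 0.05 / 1e6)
  expect_lt(abs(frac - 0.95), 3 * se)

  s <- estimate_occupancy(20000, 20000)
  expect_true(s$saturated)
  expect_identical(s$mu, Inf)
})

test_that("exact binomial intervals match the stats oracle", {
  for (W in c(0, 3, 150, 19999, 20000)) {
    e <- estimate_occupancy(W, 20000)
    ci <- stats::binom.test(W, 20000)$conf.int
    expect_equal(c(e$ci_low, e$ci_high), as.numeric(ci), tolerance = 1e-10)
  }
})

test_that("invalid droplet counts are rejected", {
  expect_error(estimate_occupancy(1, 0), "positive")
  expect_error(estimate_occupancy(5, 3), "0 <= W <= U")
  expect_error(estimate_occupancy(-1, 10), "0 <= W <= U")
})

test_that("monte-carlo occupancy recovery is unbiased across loads", {
  set.seed(7)
  for (mu in c(0.01, 0.1, 1, 3)) {
    U <- 1e6
    W <- sum(stats::rpois(U, mu) > 0)
    est <- estimate_occupancy(W, U)
    p <- 1 - exp(-mu)
    se_mu <- sqrt(p / (1 - p) / U)  # delta method on -log(1 - W/U)
    expect_lt(abs(est$mu - mu), 3 * se_mu)
  }
})

test_that("volume chain converts per-droplet copies to copies/L step by step", {
  # independent unit-chain evaluation: copies per uL of reaction, copies in
  # the reaction, per uL template, whole extract, per litre filtered
  chain <- volume_chain()
  mu <- 0.6931
  per_ul_rxn <- mu / 8.5e-4
  in_rxn <- per_ul_rxn * 22
  per_ul_template <- in_rxn / 2
  in_extract <- per_ul_template * 50
  per_litre <- in_extract / 2
  expect_equal(mean_copies_to_concentration(mu, chain), per_litre,
               tolerance = 1e-12)
  expect_equal(per_litre, 2.24e5, tolerance = 0.005)
  expect_equal(mean_copies_to_concentration(0, chain), 0)

  # linearity in the dilution factor
  c1 <- mean_copies_to_concentration(mu, volume_chain(dilution_d = 1))
  c2 <- mean_copies_to_concentration(mu, volume_chain(dilution_d = 2))
  expect_equal(c2, 2 * c1)
})

test_that("concentration round trip is exact for arbitrary chains", {
  set.seed(11)
  for (i in 1:25) {
    chain <- volume_chain(rvol = runif(1, 10, 30), tvol = runif(1, 1, 5),
                          evol = runif(1, 20, 100),
                          dvol = runif(1, 5e-4, 1e-3),
                          filt_vol = runif(1, 0.5, 3),
                          dilution_d = runif(1, 1, 4))
    mu <- runif(1, 0, 5)
    back <- concentration_to_mean_copies(
      mean_copies_to_concentration(mu, chain), chain)
    expect_equal(back, mu, tolerance = 1e-10)
  }
  expect_error(volume_chain(rvol = -1), "positive")
  expect_error(volume_chain(dilution_d = 0.5), "dilution_d")
})

test_that("No-RT subtraction floors at zero and logs adjustments", {
  expect_equal(as.numeric(subtract_no_rt(5, 1)), 4)
  expect_equal(as.numeric(subtract_no_rt(3, 0)), 3)
  expect_equal(as.numeric(subtract_no_rt(1, 2)), 0)
  set.seed(3)
  W <- rpois(100, 4)
  out <- subtract_no_rt(W, rep(0, 100))
  expect_equal(as.numeric(out), W)      # identity under zero control
  out2 <- subtract_no_rt(W, rpois(100, 2))
  expect_true(all(out2 >= 0))
  expect_error(subtract_no_rt(c(1, 2), c(1, 2, 3)), "paired")
})

test_that("size-fraction profile screens the dominant pore size", {
  p <- size_fraction_profile(c(5, 1, 0.45), c(950, 30, 20))
  expect_equal(unname(p$fractions[c("5", "1", "0.45")]), c(0.95, 0.03, 0.02))
  expect_equal(p$dominant, 5)
  expect_true(p$passes_screen)
  expect_match(p$verdict, "restrict analysis")

  one <- size_fraction_profile(5, 123)
  expect_equal(unname(one$fractions), 1)

  none <- size_fraction_profile(c(5, 1), c(0, 0))
  expect_true(none$undefined)
  expect_true(all(is.na(none$fractions)))

  spread <- size_fraction_profile(c(5, 1), c(60, 40))
  expect_false(spread$passes_screen)
})
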