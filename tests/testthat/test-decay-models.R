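test_that("biphasic curve matches its two-piece closed form", {
  p <- biphasic_params(C0 = 1e5, lambda1 = 0.114, lambda2 = 0.026, t_x = 41)
  expect_equal(biphasic_concentration(p, 0), 1e5)

  # independent longhand evaluation of both phases
  direct <- function(t) {
    if (t < 41) 1e5 * exp(-0.114 * t)
    else (1e5 * exp(-0.114 * 41)) * exp(-0.026 * (t - 41))
  }
  expect_equal(biphasic_concentration(p, 41), direct(41), tolerance = 1e-12)
  expect_equal(biphasic_concentration(p, 100), direct(100), tolerance = 1e-12)
  expect_equal(biphasic_concentration(p, 41), 933.6, tolerance = 1e-3)
  expect_equal(biphasic_concentration(p, 100), 201.3, tolerance = 1e-3)

  expect_error(biphasic_concentration(p, -1), ">= 0")
  expect_error(biphasic_params(0, 0.1, 0.1, 10), "C0")
  expect_error(biphasic_params(1, -0.1, 0.1, 10), "rates")
  expect_error(biphasic_params(1, 0.1, 0.1, 0), "t_x")
})

test_that("biphasic reduces to single exponential when the rates coincide", {
  p <- biphasic_params(C0 = 5e4, lambda1 = 0.07, lambda2 = 0.07, t_x = 30)
  t <- seq(0, 150, by = 1.7)
  expect_equal(biphasic_concentration(p, t), 5e4 * exp(-0.07 * t),
               tolerance = 1e-12)
})

test_that("biphasic curve is continuous at the changepoint", {
  p <- biphasic_params(C0 = 1e6, lambda1 = 0.2, lambda2 = 0.01, t_x = 33)
  eps <- 1e-9
  expect_lt(abs(biphasic_concentration(p, 33 - eps) -
                  biphasic_concentration(p, 33 + eps)) /
              biphasic_concentration(p, 33), 1e-8)
})

test_that("log-concentration is piecewise linear with the two decay slopes", {
  p <- biphasic_params(C0 = 1e6, lambda1 = 0.15, lambda2 = 0.03, t_x = 36)
  t1 <- seq(0, 35.9, by = 0.01)
  t2 <- seq(36, 188, by = 0.01)
  s1 <- stats::coef(stats::lm(log(biphasic_concentration(p, t1)) ~ t1))[2]
  s2 <- stats::coef(stats::lm(log(biphasic_concentration(p, t2)) ~ t2))[2]
  expect_equal(unname(s1), -0.15, tolerance = 1e-8)
  expect_equal(unname(s2), -0.03, tolerance = 1e-8)
})

test_that("menu models reduce to single exponential in their limits", {
  t <- seq(0, 100, by = 2.5)
  single <- evaluate_model("single_exp", list(C0 = 1e4, lambda1 = 0.12), t)
  expect_equal(single, 1e4 * exp(-0.12 * t), tolerance = 1e-12)
  expect_equal(evaluate_model("single_exp", list(C0 = 7, lambda1 = 0), t),
               rep(7, length(t)))

  wb <- evaluate_model("weibull", list(C0 = 1e4, lambda1 = 0.12, shape = 1), t)
  expect_equal(wb, single, tolerance = 1e-12)

  de <- evaluate_model("double_exp",
                       list(C0 = 1e4, lambda1 = 0.12, lambda2 = 0.7,
                            weight = 1), t)
  expect_equal(de, single, tolerance = 1e-12)

  pl0 <- evaluate_model("exp_plateau",
                        list(C0 = 1e4, lambda1 = 0.12, resid_frac = 0), t)
  expect_equal(pl0, single, tolerance = 1e-12)
})

test_that("every menu model is non-increasing for non-negative parameters", {
  set.seed(31)
  t <- seq(0, 200, by = 0.5)
  cases <- list(
    single_exp = function() list(C0 = 10^runif(1, 2, 7),
                                 lambda1 = runif(1, 0, 1)),
    biphasic = function() list(C0 = 10^runif(1, 2, 7),
                               lambda1 = runif(1, 0, 1),
                               lambda2 = runif(1, 0, 1),
                               t_x = runif(1, 5, 100)),
    exp_plateau = function() list(C0 = 10^runif(1, 2, 7),
                                  lambda1 = runif(1, 0, 1),
                                  resid_frac = runif(1)),
    weibull = function() list(C0 = 10^runif(1, 2, 7),
                              lambda1 = runif(1, 0, 1),
                              shape = runif(1, 0.3, 3)),
    power_law = function() list(C0 = 10^runif(1, 2, 7),
                                alpha = runif(1, 0, 5),
                                tau = runif(1, 1, 100)),
    double_exp = function() list(C0 = 10^runif(1, 2, 7),
                                 lambda1 = runif(1, 0, 1),
                                 lambda2 = runif(1, 0, 1),
                                 weight = runif(1)))
  for (mid in names(cases)) for (rep in 1:5) {
    pars <- cases[[mid]]()
    C <- evaluate_model(mid, pars, t)
    expect_true(all(diff(C) <= 1e-9 * C[1]), label = paste(mid, "monotone"))
    # positivity up to floating-point underflow of exp() deep in the tail
    expect_true(all(C >= 0) && C[1] > 0, label = paste(mid, "positive"))
  }
})

test_that("model dispatch validates ids and parameters", {
  expect_error(decay_model("exponential_with_typo"), "unknown decay model")
  expect_error(evaluate_model("biphasic", list(C0 = 1, lambda1 = 0.1), 1:3),
               "missing parameters")
})
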