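test_that("dataset assembly counts, groups and validates wells", {
  df <- expand.grid(carboy = 1:3, time_nominal_h = c(0, 4, 8, 12, 24, 48, 96,
                                                     140, 188), tech_rep = 1:2)
  df$marker <- "Cytb"
  df$component <- "eDNA"
  df$time_actual_h <- df$time_nominal_h
  df$droplets_total <- 20000
  df$droplets_positive <- 100
  ds <- build_dataset(df)
  expect_equal(nrow(ds$monoplex), 54)   # 3 carboys x 9 timepoints x 2 reps
  expect_equal(ds$components$comp, "Cytb_eDNA")

  # positive droplets in the control carboy trigger a validation warning
  df2 <- df
  df2$carboy[1] <- 4
  expect_warning(build_dataset(df2), "control carboy")

  # duplex rows failing the category sum identity are rejected
  dup <- data.frame(carboy = 1, time_nominal_h = 0, time_actual_h = 0,
                    tech_rep = 1, droplets_total = 20000, n_both = 10,
                    n_a_only = 10, n_b_only = 10, n_neither = 100)
  expect_error(build_dataset(df, dup), "do not sum")

  # baseline rows are excluded by default, kept on request
  df3 <- rbind(df, transform(df[df$time_nominal_h == 0, ],
                             time_nominal_h = -3, time_actual_h = -3))
  expect_equal(nrow(build_dataset(df3)$monoplex), 54)
  expect_equal(nrow(build_dataset(df3, include_baseline = TRUE)$monoplex), 60)
})

test_that("decay fit recovers generating parameters on one marker", {
  ds <- single_marker_dataset(seed = 101)
  fit <- decay_fit(ds, "biphasic", mcmc = quick_mcmc(), seed = 101)
  l1 <- enadecay:::par_draws(fit, "Cytb_eDNA.lambda1")
  l2 <- enadecay:::par_draws(fit, "Cytb_eDNA.lambda2")
  tx <- enadecay:::par_draws(fit, "Cytb_eDNA.t_x")
  expect_true(stats::quantile(l1, 0.025) < 0.15 &&
                stats::quantile(l1, 0.975) > 0.15)
  expect_true(stats::quantile(l2, 0.025) < 0.03 &&
                stats::quantile(l2, 0.975) > 0.03)
  expect_true(stats::quantile(tx, 0.025) < 36 &&
                stats::quantile(tx, 0.975) > 36)
})

test_that("pointwise log-likelihood matches direct binomial evaluation", {
  fit <- fixture_fit()
  ll <- loglik_matrix(fit, thin_to = 200)
  S_full <- prod(dim(fit$draws)[1:2])
  step <- max(1L, floor(S_full / 200))
  idx <- seq(1, S_full, by = step)
  m <- fit$dataset$monoplex
  m <- m[m$comp %in% fit$components$comp[fit$components$effective_model != "none"], ]
  set.seed(61)
  for (w in sample(nrow(m), 10)) {
    comp <- m$comp[w]
    eff <- fit$components$effective_model[fit$components$comp == comp]
    lC0 <- enadecay:::par_draws(fit,
      sprintf("%s.lC0[%d]", comp, fit$dataset$carboys[m$cb[w]]))[idx]
    l1 <- enadecay:::par_draws(fit, sprintf("%s.lambda1", comp))[idx]
    t <- m$time_actual_h[w]
    logC <- if (eff == "biphasic") {
      l2 <- enadecay:::par_draws(fit, sprintf("%s.lambda2", comp))[idx]
      tx <- enadecay:::par_draws(fit, sprintf("%s.t_x", comp))[idx]
      lC0 - l1 * pmin(t, tx) - l2 * pmax(t - tx, 0)
    } else lC0 - l1 * t
    p <- 1 - exp(-exp(logC) * m$k[w])
    direct <- stats::dbinom(m$droplets_positive[w], m$droplets_total[w], p,
                            log = TRUE)
    expect_equal(unname(ll[, paste0("m", w)]), direct, tolerance = 1e-10)
  }
})

test_that("more droplets and replicates sharpen the posterior", {
  tr <- single_marker_truth()
  des_small <- experiment_design(control_carboy = NA, droplets_per_well = 5000,
                                 tech_reps = 1)
  des_big <- experiment_design(control_carboy = NA, droplets_per_well = 20000,
                               tech_reps = 2)
  sim_s <- simulate_experiment(tr, des_small, seed = 7)
  sim_b <- simulate_experiment(tr, des_big, seed = 7)
  f_s <- decay_fit(build_dataset(sim_s$monoplex), "biphasic",
                   mcmc = quick_mcmc(), seed = 7)
  f_b <- decay_fit(build_dataset(sim_b$monoplex), "biphasic",
                   mcmc = quick_mcmc(), seed = 7)
  sd_s <- stats::sd(enadecay:::par_draws(f_s, "Cytb_eDNA.lambda1"))
  sd_b <- stats::sd(enadecay:::par_draws(f_b, "Cytb_eDNA.lambda1"))
  expect_lt(sd_b, sd_s)
})

test_that("duplex block recovers the Bridge rate when free pools vanish", {
  tr <- truth_params(components = data.frame(
    marker = c("16S", "Dloop", "Bridge"), component = "eDNA",
    assay = c("duplex_a", "duplex_b", "duplex_linked"),
    C0 = c(1e-9, 1e-9, 2e5),
    lambda1 = c(0.1, 0.1, 0.19), lambda2 = c(0.02, 0.02, 0.044),
    t_x = c(30, 30, 28)), carboy_sd = 0.1)
  sim <- simulate_experiment(tr, experiment_design(control_carboy = NA),
                             seed = 71)
  fit <- decay_fit(build_dataset(sim$monoplex, sim$duplex), "biphasic",
                   mcmc = quick_mcmc(), seed = 71)
  l1 <- enadecay:::par_draws(fit, "Bridge_eDNA.lambda1")
  expect_true(stats::quantile(l1, 0.025) < 0.19 &&
                stats::quantile(l1, 0.975) > 0.19)
})

test_that("fit methods expose the posterior coherently", {
  fit <- fixture_fit()
  s <- summary(fit)
  expect_equal(nrow(s), 6)
  expect_true(all(s$lambda1_2.5 <= s$lambda1 & s$lambda1 <= s$lambda1_97.5,
                  na.rm = TRUE))
  # single-detection component: rate reported, changepoint NA
  em <- s[s$component == "emRNA", ]
  expect_true(is.na(em$t_x) && is.na(em$lambda2))
  expect_false(is.na(em$lambda1))

  cf <- coef(fit)
  expect_true(all(is.finite(cf)))
  expect_true("Cytb_eDNA.lambda1" %in% names(cf))

  pr <- predict(fit, times = c(0, 10, 50), components = "Cytb_eDNA")
  expect_equal(nrow(pr), 9)  # 3 carboys x 3 times
  expect_true(all(pr$lower <= pr$median & pr$median <= pr$upper))
  # biphasic posterior trajectories decline
  pr2 <- predict(fit, times = seq(0, 100, 10), components = "16S_eDNA",
                 carboys = 1)
  expect_true(all(diff(pr2$median) < 0))

  res <- residuals(fit)
  expect_true(all(is.finite(res)))
  expect_lt(abs(mean(res)), 1)

  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_true(all(sim$W_sim >= 0))
  expect_equal(sort(unique(sim$sim)), 1:2)
  # posterior-predictive counts correlate with the observed ones
  expect_gt(stats::cor(sim$W_obs, sim$W_sim), 0.95)

  expect_output(print(fit), "decay fit")
})
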