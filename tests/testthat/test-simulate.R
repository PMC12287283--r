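test_that("true-concentration simulation honours the decay truth", {
  # no carboy effect: identical trajectories across carboys
  tr <- truth_params(carboy_sd = 0, jitter_h = 0)
  conc <- simulate_true_concentrations(tr, experiment_design(), seed = 2)
  cytb <- conc[conc$marker == "Cytb" & conc$component == "eDNA" &
                 conc$carboy <= 3, ]
  byc <- split(cytb$C_true, cytb$carboy)
  expect_equal(byc[[1]], byc[[2]])
  expect_equal(byc[[1]], byc[[3]])

  # closed-form check of the biphasic ratio C(48)/C(0)
  tr2 <- truth_params(components = data.frame(
    marker = "X", component = "eDNA", assay = "monoplex",
    C0 = 1e6, lambda1 = 0.15, lambda2 = 0.03, t_x = 36),
    carboy_sd = 0, jitter_h = 0)
  c2 <- simulate_true_concentrations(tr2, experiment_design(), seed = 1)
  c2 <- c2[c2$carboy == 1, ]
  ratio <- c2$C_true[c2$time_nominal_h == 48] / c2$C_true[c2$time_nominal_h == 0]
  expect_equal(ratio, exp(-0.15 * 36) * exp(-0.03 * 12), tolerance = 1e-12)
  expect_equal(ratio, 0.00315, tolerance = 0.01)

  # lambda1 = lambda2 collapses to a single exponential
  tr3 <- truth_params(components = data.frame(
    marker = "X", component = "eDNA", assay = "monoplex",
    C0 = 1e5, lambda1 = 0.1, lambda2 = 0.1, t_x = 36),
    carboy_sd = 0, jitter_h = 0)
  c3 <- simulate_true_concentrations(tr3, experiment_design(), seed = 1)
  c3 <- c3[c3$carboy == 1 & c3$time_nominal_h >= 0, ]
  expect_equal(c3$C_true, 1e5 * exp(-0.1 * c3$time_nominal_h),
               tolerance = 1e-12)

  # control carboy is identically zero
  ctl <- conc[conc$carboy == 4, ]
  expect_true(all(ctl$C_true == 0))
})

test_that("droplet-count simulation matches the occupancy law", {
  # zero concentration yields zero positives everywhere
  sim <- simulate_experiment(seed = 3)
  ctl <- sim$monoplex[sim$monoplex$carboy == 4, ]
  expect_true(all(ctl$droplets_positive == 0))
  ctd <- sim$duplex[sim$duplex$carboy == 4, ]
  expect_true(all(ctd$n_both + ctd$n_a_only + ctd$n_b_only == 0))

  # large well: observed positive fraction within 3 SE of 1 - exp(-mu)
  tr <- truth_params(components = data.frame(
    marker = "X", component = "eDNA", assay = "monoplex",
    C0 = 5e5, lambda1 = 0.1, lambda2 = 0.02, t_x = 30),
    carboy_sd = 0, jitter_h = 0, nort_rate = 0)
  des <- experiment_design(n_carboys = 1, control_carboy = NA,
                           timepoints = 0, tech_reps = 1,
                           droplets_per_well = 1e6)
  sim2 <- simulate_experiment(tr, des, seed = 4)
  k <- with(volume_chain(), dvol * tvol * filt_vol / (rvol * evol))
  p <- 1 - exp(-5e5 * k)
  w0 <- sim2$monoplex[sim2$monoplex$time_nominal_h == 0, ]
  obs <- w0$droplets_positive / w0$droplets_total
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 1e6))

  # fully linked duplex pool: no single positives
  trl <- truth_params(components = data.frame(
    marker = c("A", "B", "L"), component = "eDNA",
    assay = c("duplex_a", "duplex_b", "duplex_linked"),
    C0 = c(1e-9, 1e-9, 2e5), lambda1 = 0.1, lambda2 = 0.02, t_x = 30),
    carboy_sd = 0, jitter_h = 0)
  sim3 <- simulate_experiment(trl, experiment_design(control_carboy = NA),
                              seed = 5)
  expect_true(all(sim3$duplex$n_a_only == 0))
  expect_true(all(sim3$duplex$n_b_only == 0))
})

test_that("fixture generation is deterministic and correctly shaped", {
  d1 <- tempfile("fxa")
  d2 <- tempfile("fxb")
  f1 <- generate_fixture(d1, seed = 9)
  f2 <- generate_fixture(d2, seed = 9)
  expect_identical(readLines(f1$wells), readLines(f2$wells))
  expect_identical(readLines(f1$truth), readLines(f2$truth))
  f3 <- generate_fixture(tempfile("fxc"), seed = 10)
  expect_false(identical(readLines(f1$wells), readLines(f3$wells)))

  # row accounting: (3 + 1 control) carboys x (9 + baseline) timepoints x
  # 2 reps x (3 monoplex + 2 NoRT) wells, plus pore-screen extras at the
  # first chamber timepoint; one duplex well per sample
  wells <- utils::read.csv(f1$wells)
  design <- experiment_design()
  n_samples <- 4 * (9 + 1) * 2
  expect_equal(sum(wells$assay == "duplex"), n_samples)
  expect_equal(sum(wells$assay == "monoplex"), n_samples * 5)

  # round trip through the reader: no validation warnings
  tabs <- read_ddpcr_table(f1$wells)
  expect_length(tabs$validation$errors, 0)
  expect_length(tabs$validation$warnings, 0)
})

test_that("generated Bridge:Cytb ratio declines when the Bridge decays faster", {
  conc <- simulate_true_concentrations(truth_params(carboy_sd = 0.3),
                                       experiment_design(), seed = 11)
  conc <- conc[conc$carboy == 2 & conc$time_nominal_h >= 0 &
                 conc$time_nominal_h <= 24, ]
  r <- conc$C_true[conc$marker == "Bridge"] /
    conc$C_true[conc$marker == "Cytb" & conc$component == "eDNA"]
  expect_true(all(diff(r) < 0))
})
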