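# Shared, lazily-computed fixtures: the default synthetic experiment and two
# fits of it (test-scale and full-scale sampler settings). Memoised so the
# expensive MCMC runs happen at most once per test session.

.fit_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fit_cache))
    assign(key, force(expr), envir = .fit_cache)
  get(key, envir = .fit_cache)
}

fixture_tables <- function() memo("tables", {
  fx <- generate_fixture(tempfile("fx"), seed = 1)
  read_ddpcr_table(fx$wells)
})

fixture_dataset <- function() memo("dataset", {
  tabs <- fixture_tables()
  build_dataset(apply_no_rt_subtraction(tabs$monoplex), tabs$duplex)
})

# test-scale fit of the default fixture
fixture_fit <- function() memo("fit_small", {
  decay_fit(fixture_dataset(), model = "biphasic",
            mcmc = mcmc_control(chains = 4, adapt = 500, warmup = 500,
                                iter = 1000),
            seed = 1)
})

# full-scale sampler settings (4 chains, 5000 warmup, 10000 iterations)
fixture_fit_full <- function() memo("fit_full", {
  decay_fit(fixture_dataset(), model = "biphasic",
            mcmc = mcmc_control(chains = 4, adapt = 1000, warmup = 5000,
                                iter = 10000),
            seed = 1)
})

# one-marker monoplex experiment for recovery / calibration / selection runs
single_marker_truth <- function(C0 = 1e6, lambda1 = 0.15, lambda2 = 0.03,
                                t_x = 36) {
  truth_params(components = data.frame(
    marker = "Cytb", component = "eDNA", assay = "monoplex",
    C0 = C0, lambda1 = lambda1, lambda2 = lambda2, t_x = t_x))
}

single_marker_dataset <- function(truth = single_marker_truth(), seed = 1) {
  sim <- simulate_experiment(truth, experiment_design(control_carboy = NA),
                             seed = seed)
  build_dataset(sim$monoplex, sim$duplex)
}

quick_mcmc <- function() mcmc_control(chains = 2, adapt = 300, warmup = 400,
                                      iter = 800)

# hand-built minimal decay_fit (two single-exponential components with known
# draws) for closed-form clock checks
fake_clock_fit <- function(lam_a = 0.2, lam_b = 0.1, lC0_a = 10, lC0_b = 10,
                           S = 200) {
  pars <- c("A_eDNA.lC0[1]", "A_eDNA.lambda1", "B_eDNA.lC0[1]",
            "B_eDNA.lambda1")
  draws <- array(0, dim = c(S, 2, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  draws[, , 1] <- lC0_a
  draws[, , 2] <- lam_a
  draws[, , 3] <- lC0_b
  draws[, , 4] <- lam_b
  structure(list(
    model = "single_exp",
    dataset = list(carboys = 1L, monoplex = NULL, duplex = NULL),
    components = data.frame(
      comp = c("A_eDNA", "B_eDNA"), marker = c("A", "B"),
      component = "eDNA", type = "monoplex", duplex_role = NA,
      effective_model = "single_exp", na_reason = NA),
    draws = draws, mcmc = NULL, seed = 1),
    class = "decay_fit")
}
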