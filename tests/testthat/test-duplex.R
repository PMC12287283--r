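test_that("duplex category probabilities match closed form and simulation", {
  expect_equal(unname(duplex_category_probs(0, 0, 0)), c(0, 0, 0, 1))

  p <- duplex_category_probs(0.5, 0.3, 0.2)
  expect_equal(sum(p), 1, tolerance = 1e-14)
  expect_equal(unname(p["neither"]), exp(-1), tolerance = 1e-14)
  # brute-force droplet simulation: independent Poisson loads per pool
  set.seed(5)
  n <- 1e6
  a <- stats::rpois(n, 0.5) > 0
  b <- stats::rpois(n, 0.3) > 0
  l <- stats::rpois(n, 0.2) > 0
  sim <- c(both = mean((a | l) & (b | l)), a_only = mean((a & !b & !l)),
           b_only = mean((b & !a & !l)), neither = mean(!a & !b & !l))
  for (cat in names(p))
    expect_lt(abs(p[cat] - sim[cat]),
              3 * sqrt(p[cat] * (1 - p[cat]) / n) + 1e-12)

  # fully linked pool: no single positives
  fl <- duplex_category_probs(0, 0, 0.7)
  expect_equal(unname(fl[c("a_only", "b_only")]), c(0, 0))
  expect_equal(unname(fl["both"]), 1 - exp(-0.7), tolerance = 1e-14)

  expect_error(duplex_category_probs(-0.1, 0, 0), ">= 0")
})

test_that("closed-form estimator exactly inverts the category probabilities", {
  grid <- c(0, 0.05, 0.4, 1.5, 3)
  for (la in grid) for (lb in grid) for (lL in grid) {
    pr <- duplex_category_probs(la, lb, lL)
    U <- 20000
    est <- estimate_linked_closed_form(U * pr[["both"]], U * pr[["a_only"]],
                                       U * pr[["b_only"]], U * pr[["neither"]])
    expect_equal(est$lambda_a_free, la, tolerance = 1e-12)
    expect_equal(est$lambda_b_free, lb, tolerance = 1e-12)
    expect_equal(est$lambda_linked, lL, tolerance = 1e-12)
  }
})

test_that("linkage estimator handles canonical special cases", {
  # exact independence: q00 = qA * qB
  est <- estimate_linked_closed_form(2500, 2500, 2500, 2500)
  expect_equal(est$lambda_linked, 0, tolerance = 1e-12)

  # fully linked pool: half the droplets double-positive
  est <- estimate_linked_closed_form(5000, 0, 0, 5000)
  expect_equal(est$lambda_linked, log(2), tolerance = 1e-12)
  expect_equal(est$lambda_a_free, 0)
  expect_equal(est$lambda_b_free, 0)

  expect_error(estimate_linked_closed_form(9999, 1, 0, 0), "saturated")
})

test_that("simulated droplet wells recover the linked rate", {
  set.seed(17)
  U <- 2e6
  pr <- duplex_category_probs(0.1, 0.2, 0.05)
  z <- as.vector(stats::rmultinom(1, U, pr))
  est <- estimate_linked_closed_form(z[1], z[2], z[3], z[4])
  # Monte-Carlo standard error from 30 replicate wells
  reps <- stats::rmultinom(30, U, pr)
  ests <- apply(reps, 2, function(w)
    estimate_linked_closed_form(w[1], w[2], w[3], w[4])$lambda_linked)
  expect_lt(abs(est$lambda_linked - 0.05), 3 * stats::sd(ests))
})

test_that("subtraction heuristic agrees at low occupancy, biased when loaded", {
  U <- 1e6
  low <- duplex_category_probs(0.05, 0.03, 0.02)
  s <- expected_double_positives(U * low[["both"]], U * low[["a_only"]],
                                 U * low[["b_only"]], U * low[["neither"]])
  expect_lt(abs(s$lambda_linked_subtraction - 0.02) / 0.02, 0.15)

  high <- duplex_category_probs(0.5, 0.3, 0.2)
  sh <- expected_double_positives(U * high[["both"]], U * high[["a_only"]],
                                  U * high[["b_only"]], U * high[["neither"]])
  # documented downward bias of the subtraction heuristic at high occupancy
  expect_lt(sh$lambda_linked_subtraction, 0.5 * 0.2)
  expect_equal(sh$lambda_linked_subtraction, 0.067, tolerance = 0.02)

  # independence-exact counts give zero excess
  ind <- expected_double_positives(2500, 2500, 2500, 2500)
  expect_equal(ind$excess, 0, tolerance = 1e-9)
})

test_that("closed-form estimator is consistent across replicate wells", {
  set.seed(23)
  for (lL in c(0.01, 0.1, 0.5)) {
    pr <- duplex_category_probs(0.1, 0.1, lL)
    reps <- stats::rmultinom(200, 20000, pr)
    ests <- apply(reps, 2, function(w)
      estimate_linked_closed_form(w[1], w[2], w[3], w[4])$lambda_linked)
    expect_lt(abs(mean(ests) - lL) / lL, 0.02)
  }
})

test_that("linked load monotonically shifts the double-positive balance", {
  lLs <- seq(0, 2, by = 0.25)
  pb <- vapply(lLs, function(l) duplex_category_probs(0.3, 0.2, l)[["both"]], 0)
  p0 <- vapply(lLs, function(l) duplex_category_probs(0.3, 0.2, l)[["neither"]], 0)
  expect_true(all(diff(pb) > 0))
  expect_true(all(diff(p0) < 0))
})

test_that("bridge metadata reports the assay's genomic span", {
  b <- bridge_length_bounds()
  expect_equal(unname(b), c(2746, 16390))
  expect_lt(b[["min_bp"]], b[["max_bp"]])
})
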