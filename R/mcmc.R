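# JAGS model assembly and execution for the droplet-level decay model.
#
# Likelihood, monoplex wells:  W ~ Binomial(U, p),  p = 1 - exp(-mu),
# i.e. cloglog(p) = log(mu), with mu = C(t) * k where k is the per-well
# volume-chain factor mapping copies/L to copies/droplet. Duplex wells use
# the four-category multinomial with per-droplet rates for the two free
# pools and the linked pool, each decaying under the chosen model.

# map between JAGS node stems and user-facing parameter names
jags_par_names <- c(l1 = "lambda1", l2 = "lambda2", tx = "t_x",
                    fr = "resid_frac", k = "shape", a = "alpha",
                    tau = "tau", wgt = "weight")

#' Prior configuration for the decay model
#'
#' Defaults: per-carboy log initial concentration is Normal, centred on a
#' method-of-moments estimate from that carboy's earliest positive timepoint
#' with standard deviation `lnC0_sd`; decay rates are half-Normal(0,
#' `lambda_sd`); the changepoint is Uniform(`tx_lower`, `tx_upper`). No
#' ordering `lambda2 < lambda1` is imposed unless `order_constraint = TRUE`,
#' so a biphasic shape must emerge from the data rather than the prior.
#'
#' @param lnC0_sd prior sd on log C0 (default 3).
#' @param lambda_sd half-Normal scale for decay rates, 1/h (default 1).
#' @param tx_lower,tx_upper Uniform prior bounds on the transition time, h
#'   (defaults 12 and 96).
#' @param order_constraint logical; truncate `lambda2` at `lambda1`.
#' @return object of class `prior_config`.
#' @export
prior_config <- function(lnC0_sd = 3, lambda_sd = 1,
                         tx_lower = 12, tx_upper = 96,
                         order_constraint = FALSE) {
  stopifnot(lnC0_sd > 0, lambda_sd > 0, tx_lower > 0, tx_upper > tx_lower)
  structure(list(lnC0_sd = lnC0_sd, lambda_sd = lambda_sd,
                 tx_lower = tx_lower, tx_upper = tx_upper,
                 order_constraint = isTRUE(order_constraint)),
            class = "prior_config")
}

#' MCMC sampler settings
#'
#' Test-scale defaults; `mcmc_control(warmup = 5000, iter = 10000)` gives the
#' full-scale configuration (4 chains, 5000 warmup, 10,000 sampling
#' iterations).
#'
#' @param chains number of independent chains (default 4).
#' @param adapt adaptation iterations before warmup (default 1000).
#' @param warmup burn-in iterations discarded (default 1000).
#' @param iter retained sampling iterations per chain (default 2000).
#' @param thin thinning interval (default 1).
#' @return object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, adapt = 1000, warmup = 1000,
                         iter = 2000, thin = 1) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1, thin >= 1, adapt >= 100)
  structure(list(chains = chains, adapt = adapt, warmup = warmup,
                 iter = iter, thin = thin), class = "mcmc_control")
}

# substitute a component suffix into a menu template; suffix is "" for a
# scalar (monoplex) model or "[j]" inside the duplex component loop
fill_template <- function(tmpl, suffix, priors) {
  s <- gsub("%S%", suffix, tmpl, fixed = TRUE)
  ord <- if (priors$order_constraint) gsub("%S%", suffix, "l1%S%", fixed = TRUE) else ""
  gsub("%ORD%", ord, s, fixed = TRUE)
}

# model-string for one monoplex component
monoplex_model_string <- function(model_id, priors) {
  m <- model_menu[[model_id]]
  expr <- fill_template(m$jags, "", priors)
  expr <- gsub("LC0", "lC0[cb[w]]", expr, fixed = TRUE)
  expr <- gsub("\\bT\\b", "t[w]", expr)
  paste0(
    "model {\n",
    "  for (w in 1:N) {\n",
    "    logC[w] <- ", expr, "\n",
    "    mu[w] <- exp(logC[w]) * k[w]\n",
    "    p[w] <- max(1.0E-12, min(1 - exp(-mu[w]), 1 - 1.0E-12))\n",
    "    W[w] ~ dbin(p[w], U[w])\n",
    "  }\n",
    "  for (c in 1:NC) { lC0[c] ~ dnorm(m0[c], prec_c0) }\n",
    "  ", fill_template(m$jags_priors, "", priors),
    "}\n")
}

# model-string for the joint duplex block: components j = 1 (free A),
# 2 (free B), 3 (linked); category order (both, a_only, b_only, neither)
duplex_model_string <- function(model_id, priors) {
  m <- model_menu[[model_id]]
  expr <- fill_template(m$jags, "[j]", priors)
  expr <- gsub("LC0", "lC0[cb[w], j]", expr, fixed = TRUE)
  expr <- gsub("\\bT\\b", "t[w]", expr)
  paste0(
    "model {\n",
    "  for (w in 1:N) {\n",
    "    for (j in 1:3) {\n",
    "      logC[w, j] <- ", expr, "\n",
    "      lam[w, j] <- exp(logC[w, j]) * k[w]\n",
    "    }\n",
    "    pr[w, 4] <- exp(-(lam[w, 1] + lam[w, 2] + lam[w, 3]))\n",
    "    pr[w, 2] <- exp(-(lam[w, 2] + lam[w, 3])) - pr[w, 4]\n",
    "    pr[w, 3] <- exp(-(lam[w, 1] + lam[w, 3])) - pr[w, 4]\n",
    "    pr[w, 1] <- 1 - pr[w, 2] - pr[w, 3] - pr[w, 4]\n",
    "    Z[w, 1:4] ~ dmulti(pr[w, 1:4], U[w])\n",
    "  }\n",
    "  for (c in 1:NC) { for (j in 1:3) { lC0[c, j] ~ dnorm(m0[c, j], prec_c0) } }\n",
    "  for (j in 1:3) {\n",
    "  ", fill_template(m$jags_priors, "[j]", priors),
    "  }\n",
    "}\n")
}

# monitored node stems for a model (besides lC0)
model_nodes <- function(model_id) {
  lines <- strsplit(model_menu[[model_id]]$jags_priors, "\n")[[1]]
  stems <- sub("%S%.*$", "", trimws(lines))
  unique(stems[nzchar(stems)])
}

# run one JAGS model; returns draws as [iter, chain, param] array with JAGS
# variable names
run_jags <- function(model_string, data, monitor, control, chain_seeds,
                     quiet = TRUE) {
  inits <- lapply(chain_seeds, function(s)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s))
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = control$chains,
                          n.adapt = control$adapt, quiet = quiet)
  if (control$warmup > 0)
    stats::update(jm, control$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitor,
                              n.iter = control$iter * control$thin,
                              thin = control$thin, progress.bar = "none")
  pars <- colnames(samp[[1]])
  arr <- array(NA_real_, dim = c(nrow(samp[[1]]), length(samp), length(pars)),
               dimnames = list(NULL, NULL, pars))
  for (ch in seq_along(samp)) arr[, ch, ] <- as.matrix(samp[[ch]])
  arr
}
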