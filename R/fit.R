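#' Fit a Bayesian decay model to ddPCR droplet counts
#'
#' The workhorse of the package. Monoplex wells enter the joint posterior
#' through a binomial likelihood with complementary log-log link: the
#' probability that a droplet is positive is \eqn{p = 1 - e^{-\mu}} where the
#' per-droplet mean copy number \eqn{\mu} follows deterministically from the
#' water-column concentration through the volume chain. Duplex wells enter
#' through the four-category multinomial of [duplex_category_probs()], tying
#' the linked (Bridge) pool and the two free pools to their own decay curves.
#' Within each marker-component, initial concentration is carboy-specific
#' while the decay parameters are shared across carboys; marker-components
#' are fitted independently (monoplex) or jointly within the duplex block.
#'
#' Identifiability: a component with no detections at all is not fitted and
#' is reported all-`NA`; a component whose detections stop after its first
#' detected timepoint cannot inform a changepoint and is automatically
#' reduced to a single-exponential fit, with `t_x` and `lambda2` reported
#' `NA` (reason `"single_detection"`). The rule is detection-based, not a
#' posterior heuristic.
#'
#' @param dataset a [build_dataset()] object.
#' @param model decay-model id from the menu (see [decay_model()]); default
#'   `"biphasic"`.
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_control()].
#' @param seed integer seed governing all chains.
#' @param quiet suppress JAGS progress output.
#' @return object of class `decay_fit` with posterior draws (iterations x
#'   chains x parameters), the component table with effective models and NA
#'   reasons, and everything needed for diagnostics, prediction, and LOO.
#' @seealso [summary.decay_fit()], [convergence_diagnostics()],
#'   [decay_loo()], [ratio_trajectory()]
#' @export
decay_fit <- function(dataset, model = "biphasic", priors = prior_config(),
                      mcmc = mcmc_control(), seed = 1, quiet = TRUE) {
  stopifnot(inherits(dataset, "model_dataset"))
  if (!model %in% names(model_menu))
    stop("unknown decay model '", model, "'", call. = FALSE)
  stopifnot(inherits(priors, "prior_config"), inherits(mcmc, "mcmc_control"))

  comps <- dataset$components
  det <- detection_table(dataset)
  comps$effective_model <- model
  comps$na_reason <- NA_character_
  for (i in seq_len(nrow(comps))) {
    tp <- det[[comps$comp[i]]]
    if (is.null(tp) || length(tp) == 0) {
      comps$effective_model[i] <- "none"
      comps$na_reason[i] <- "no_detections"
    } else if (length(tp) == 1 && length(model_menu[[model]]$pars) > 1) {
      comps$effective_model[i] <- "single_exp"
      comps$na_reason[i] <- "single_detection"
    }
  }
  # the duplex block is one joint model; it is reduced only if every linked
  # component requires reduction
  dix <- which(comps$type == "duplex")
  if (length(dix)) {
    eff <- comps$effective_model[dix]
    if (any(eff != "none") && !all(eff == "single_exp")) {
      red <- eff == "single_exp"
      comps$effective_model[dix][red] <- model
      # na_reason kept: summary still reports t_x/lambda2 NA for those
    }
  }

  set.seed(seed)
  n_runs <- sum(comps$type == "monoplex" & comps$effective_model != "none") +
    as.integer(any(comps$type == "duplex" & comps$effective_model != "none"))
  seeds <- matrix(sample.int(2^31 - 2, max(n_runs, 1) * mcmc$chains),
                  ncol = mcmc$chains)
  run <- 0L

  draws <- NULL
  m0_list <- list()
  add_draws <- function(draws, arr, comp_names) {
    # rename JAGS nodes to "<comp>.<par>" labels
    pars <- dimnames(arr)[[3]]
    lab <- character(length(pars))
    for (p in seq_along(pars)) {
      nm <- pars[p]
      if (grepl("^lC0", nm)) {
        idx <- as.integer(strsplit(gsub("lC0\\[|\\]", "", nm), ",")[[1]])
        if (length(idx) == 2) {  # duplex: lC0[carboy, j]
          lab[p] <- sprintf("%s.lC0[%d]", comp_names[idx[2]],
                            dataset$carboys[idx[1]])
        } else {
          lab[p] <- sprintf("%s.lC0[%d]", comp_names[1], dataset$carboys[idx[1]])
        }
      } else {
        stem <- sub("\\[.*$", "", nm)
        j <- if (grepl("\\[", nm)) as.integer(gsub(".*\\[|\\]", "", nm)) else 1L
        lab[p] <- sprintf("%s.%s", comp_names[j], jags_par_names[[stem]])
      }
    }
    dimnames(arr)[[3]] <- lab
    if (is.null(draws)) arr else {
      out <- array(NA_real_, dim = c(dim(arr)[1], dim(arr)[2],
                                     dim(draws)[3] + dim(arr)[3]),
                   dimnames = list(NULL, NULL, c(dimnames(draws)[[3]], lab)))
      out[, , seq_len(dim(draws)[3])] <- draws
      out[, , dim(draws)[3] + seq_len(dim(arr)[3])] <- arr
      out
    }
  }

  t0 <- Sys.time()
  ncb <- length(dataset$carboys)
  # ---- monoplex components ----
  mono_comps <- comps$comp[comps$type == "monoplex"]
  for (cp in mono_comps) {
    i <- which(comps$comp == cp)
    if (comps$effective_model[i] == "none") next
    mid <- comps$effective_model[i]
    d <- dataset$monoplex[dataset$monoplex$comp == cp, ]
    m0 <- mono_m0(d, ncb)
    m0_list[[cp]] <- m0
    data <- list(N = nrow(d), cb = d$cb, t = d$time_actual_h, k = d$k,
                 U = d$droplets_total, W = round(d$droplets_positive),
                 NC = ncb, m0 = m0, prec_c0 = 1 / priors$lnC0_sd^2,
                 prec_lam = 1 / priors$lambda_sd^2)
    if (grepl("tx_lo", model_menu[[mid]]$jags_priors)) {
      data$tx_lo <- priors$tx_lower
      data$tx_hi <- min(priors$tx_upper, max(d$time_actual_h))
    }
    run <- run + 1L
    arr <- run_jags(monoplex_model_string(mid, priors), data,
                    c("lC0", model_nodes(mid)), mcmc, seeds[run, ], quiet)
    draws <- add_draws(draws, arr, cp)
  }
  # ---- duplex block ----
  dup_comps <- comps[comps$type == "duplex", ]
  if (nrow(dup_comps) && any(dup_comps$effective_model != "none")) {
    mid <- dup_comps$effective_model[1]
    d <- dataset$duplex
    m0 <- duplex_m0(d, ncb)
    for (j in 1:3) m0_list[[dup_comps$comp[j]]] <- m0[, j]
    data <- list(N = nrow(d), cb = d$cb, t = d$time_actual_h, k = d$k,
                 U = d$droplets_total,
                 Z = cbind(d$n_both, d$n_a_only, d$n_b_only, d$n_neither),
                 NC = ncb, m0 = m0, prec_c0 = 1 / priors$lnC0_sd^2,
                 prec_lam = 1 / priors$lambda_sd^2)
    if (grepl("tx_lo", model_menu[[mid]]$jags_priors)) {
      data$tx_lo <- priors$tx_lower
      data$tx_hi <- min(priors$tx_upper, max(d$time_actual_h))
    }
    run <- run + 1L
    arr <- run_jags(duplex_model_string(mid, priors), data,
                    c("lC0", model_nodes(mid)), mcmc, seeds[run, ], quiet)
    draws <- add_draws(draws, arr, dup_comps$comp)
  }
  if (is.null(draws))
    stop("no component had any detections; nothing to fit", call. = FALSE)

  structure(list(model = model, dataset = dataset, priors = priors,
                 mcmc = mcmc, seed = seed, components = comps,
                 draws = draws, m0 = m0_list,
                 runtime_s = as.numeric(Sys.time() - t0, units = "secs")),
            class = "decay_fit")
}

# method-of-moments prior centre for log C0, per carboy, from the earliest
# timepoint wells (0.5-droplet continuity correction keeps it finite)
mono_m0 <- function(d, ncb) {
  m0 <- rep(NA_real_, ncb)
  for (c in unique(d$cb)) {
    dc <- d[d$cb == c, ]
    dc <- dc[dc$time_nominal_h == min(dc$time_nominal_h), ]
    p <- (sum(dc$droplets_positive) + 0.5) / (sum(dc$droplets_total) + 1)
    m0[c] <- log(-log1p(-p) / mean(dc$k))
  }
  m0[is.na(m0)] <- mean(m0, na.rm = TRUE)
  m0
}

duplex_m0 <- function(d, ncb) {
  m0 <- matrix(NA_real_, ncb, 3)
  for (c in unique(d$cb)) {
    dc <- d[d$cb == c, ]
    dc <- dc[dc$time_nominal_h == min(dc$time_nominal_h), ]
    U <- sum(dc$droplets_total)
    qA <- (sum(dc$n_b_only) + sum(dc$n_neither) + 0.5) / (U + 1)
    qB <- (sum(dc$n_a_only) + sum(dc$n_neither) + 0.5) / (U + 1)
    q00 <- (sum(dc$n_neither) + 0.5) / (U + 1)
    lamL <- max(log(q00) - log(qA) - log(qB), 0.25 / U)
    lama <- max(-log(qA) - lamL, 0.25 / U)
    lamb <- max(-log(qB) - lamL, 0.25 / U)
    m0[c, ] <- log(c(lama, lamb, lamL) / mean(dc$k))
  }
  for (j in 1:3) m0[is.na(m0[, j]), j] <- mean(m0[, j], na.rm = TRUE)
  m0
}

# ---- draw access helpers ---------------------------------------------------

# flatten [iter, chain] to a single vector for one parameter
par_draws <- function(fit, label) {
  if (!label %in% dimnames(fit$draws)[[3]])
    stop("no parameter '", label, "' in fit", call. = FALSE)
  as.vector(fit$draws[, , label])
}

par_labels <- function(fit) dimnames(fit$draws)[[3]]

# S x length(t) concentration draws for one component and carboy
conc_draws <- function(fit, comp, t, carboy, iter_idx = NULL) {
  cc <- fit$components
  i <- which(cc$comp == comp)
  if (!length(i)) stop("unknown component '", comp, "'", call. = FALSE)
  mid <- cc$effective_model[i]
  if (mid == "none") stop("component '", comp, "' was not fitted", call. = FALSE)
  spec <- model_menu[[mid]]
  pars <- list(C0 = exp(par_draws(fit, sprintf("%s.lC0[%d]", comp, carboy))))
  for (p in spec$pars)
    pars[[p]] <- par_draws(fit, sprintf("%s.%s", comp, p))
  if (!is.null(iter_idx)) pars <- lapply(pars, function(v) v[iter_idx])
  out <- matrix(NA_real_, length(pars$C0), length(t))
  for (j in seq_along(t)) out[, j] <- spec$eval(pars, t[j])
  out
}

# ---- standard S3 methods ---------------------------------------------------

#' @export
print.decay_fit <- function(x, ...) {
  cat("Bayesian eNA decay fit (", x$model, " model)\n", sep = "")
  nm <- if (is.null(x$dataset$monoplex)) 0 else nrow(x$dataset$monoplex)
  nd <- if (is.null(x$dataset$duplex)) 0 else nrow(x$dataset$duplex)
  cat(sprintf("  %d monoplex + %d duplex wells, %d carboys | %d chains x %d draws | %.1f s\n",
              nm, nd, length(x$dataset$carboys), dim(x$draws)[2],
              dim(x$draws)[1], x$runtime_s))
  s <- summary(x)
  print(s, digits = 3)
  invisible(x)
}

#' Posterior summary of decay parameters
#'
#' One row per marker-component: posterior mean and central 95% interval of
#' the first-phase decay rate, the posterior median transition time, and the
#' posterior mean second-phase rate. Components reduced by the
#' identifiability rule carry `NA` with a reason code.
#'
#' @param object a [decay_fit()] object.
#' @param ... unused.
#' @return data frame of class `summary.decay_fit`.
#' @export
summary.decay_fit <- function(object, ...) {
  cc <- object$components
  rows <- lapply(seq_len(nrow(cc)), function(i) {
    out <- data.frame(marker = cc$marker[i], component = cc$component[i],
                      lambda1 = NA_real_, lambda1_2.5 = NA_real_,
                      lambda1_97.5 = NA_real_, t_x = NA_real_,
                      lambda2 = NA_real_, na_reason = cc$na_reason[i])
    if (cc$effective_model[i] == "none") return(out)
    comp <- cc$comp[i]
    if (sprintf("%s.lambda1", comp) %in% par_labels(object)) {
      l1 <- par_draws(object, sprintf("%s.lambda1", comp))
      out$lambda1 <- mean(l1)
      out$lambda1_2.5 <- unname(stats::quantile(l1, 0.025))
      out$lambda1_97.5 <- unname(stats::quantile(l1, 0.975))
    }
    if (is.na(cc$na_reason[i]) &&
        sprintf("%s.t_x", comp) %in% par_labels(object)) {
      out$t_x <- stats::median(par_draws(object, sprintf("%s.t_x", comp)))
      out$lambda2 <- mean(par_draws(object, sprintf("%s.lambda2", comp)))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.decay_fit", "data.frame")
  out
}

#' @export
print.summary.decay_fit <- function(x, digits = 3, ...) {
  cat("Posterior decay-rate summary (1/h; 95% credible intervals):\n")
  df <- x
  class(df) <- "data.frame"
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  apply(object$draws, 3, mean)
}

#' Posterior concentration trajectories
#'
#' @param object a [decay_fit()].
#' @param times hours at which to evaluate (default: 0 to the last observed
#'   time, 101 points).
#' @param components subset of component keys (default all fitted).
#' @param carboys subset of carboy ids (default all).
#' @param level credible level for the interval.
#' @param ... unused.
#' @return data frame: component, carboy, time_h, mean, median, lower, upper.
#' @export
predict.decay_fit <- function(object, times = NULL, components = NULL,
                              carboys = NULL, level = 0.95, ...) {
  cc <- object$components[object$components$effective_model != "none", ]
  components <- components %||% cc$comp
  carboys <- carboys %||% object$dataset$carboys
  if (is.null(times)) {
    tmax <- max(c(object$dataset$monoplex$time_actual_h,
                  object$dataset$duplex$time_actual_h))
    times <- seq(0, tmax, length.out = 101)
  }
  a <- (1 - level) / 2
  out <- list()
  for (cp in components) for (cb in carboys) {
    m <- conc_draws(object, cp, times, cb)
    out[[length(out) + 1L]] <- data.frame(
      component = cp, carboy = cb, time_h = times,
      mean = colMeans(m),
      median = apply(m, 2, stats::median),
      lower = apply(m, 2, stats::quantile, a),
      upper = apply(m, 2, stats::quantile, 1 - a))
  }
  do.call(rbind, out)
}

#' Posterior-predictive droplet counts
#'
#' Draws `nsim` parameter vectors from the posterior and simulates new
#' droplet counts for every well of the fitted dataset.
#'
#' @param object a [decay_fit()].
#' @param nsim number of posterior-predictive replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data frame with columns `sim`, `well`, `type`, observed count
#'   columns and simulated counts.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- prod(dim(object$draws)[1:2])
  picks <- sample.int(S, nsim, replace = nsim > S)
  out <- list()
  m <- object$dataset$monoplex
  d <- object$dataset$duplex
  cc <- object$components
  for (s in seq_len(nsim)) {
    i <- picks[s]
    if (!is.null(m) && nrow(m)) {
      fitted_m <- m[m$comp %in% cc$comp[cc$effective_model != "none"], ]
      mu <- vapply(seq_len(nrow(fitted_m)), function(w)
        conc_draws(object, fitted_m$comp[w], fitted_m$time_actual_h[w],
                   object$dataset$carboys[fitted_m$cb[w]], iter_idx = i)[1, 1] *
          fitted_m$k[w], 0)
      out[[length(out) + 1L]] <- data.frame(
        sim = s, type = "monoplex", comp = fitted_m$comp,
        W_obs = fitted_m$droplets_positive,
        W_sim = stats::rbinom(nrow(fitted_m), fitted_m$droplets_total,
                              1 - exp(-mu)))
    }
    if (!is.null(d) && nrow(d)) {
      dup <- cc[cc$type == "duplex", ]
      lam <- sapply(dup$comp, function(cp)
        vapply(seq_len(nrow(d)), function(w)
          conc_draws(object, cp, d$time_actual_h[w],
                     object$dataset$carboys[d$cb[w]], iter_idx = i)[1, 1] *
            d$k[w], 0))
      z <- t(vapply(seq_len(nrow(d)), function(w) {
        pr <- duplex_category_probs(lam[w, 1], lam[w, 2], lam[w, 3])
        as.vector(stats::rmultinom(1, d$droplets_total[w], pr))
      }, numeric(4)))
      out[[length(out) + 1L]] <- data.frame(
        sim = s, type = "duplex", comp = "duplex",
        W_obs = d$n_both, W_sim = z[, 1])
    }
  }
  do.call(rbind, out)
}

#' Pearson residuals of monoplex wells at the posterior mean
#'
#' @param object a [decay_fit()].
#' @param ... unused.
#' @return numeric vector, one per fitted monoplex well.
#' @export
residuals.decay_fit <- function(object, ...) {
  m <- object$dataset$monoplex
  cc <- object$components
  if (is.null(m) || !nrow(m)) return(numeric(0))
  m <- m[m$comp %in% cc$comp[cc$effective_model != "none"], ]
  p <- vapply(seq_len(nrow(m)), function(w) {
    mu <- mean(conc_draws(object, m$comp[w], m$time_actual_h[w],
                          object$dataset$carboys[m$cb[w]])[, 1]) * m$k[w]
    1 - exp(-mu)
  }, 0)
  p <- pmax(p, 1e-300)   # keep the ratio finite when occupancy underflows
  (m$droplets_positive - m$droplets_total * p) /
    sqrt(m$droplets_total * p * (1 - p))
}

#' Plot posterior decay trajectories with observed concentrations
#'
#' Observed monoplex wells are converted to point concentrations through the
#' Poisson occupancy relation and the volume chain; duplex wells through the
#' closed-form linkage estimator. Curves are posterior medians with a shaded
#' credible band; the y axis is log-scaled.
#'
#' @param x a [decay_fit()].
#' @param components subset of component keys (default all fitted).
#' @param level credible level for the band.
#' @param ... passed to [graphics::plot()].
#' @export
plot.decay_fit <- function(x, components = NULL, level = 0.95, ...) {
  cc <- x$components[x$components$effective_model != "none", ]
  components <- components %||% cc$comp
  n <- length(components)
  op <- graphics::par(mfrow = c(ceiling(n / 2), min(n, 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cp in components) {
    pr <- predict(x, components = cp, level = level)
    obs <- observed_concentrations(x, cp)
    ylim <- range(c(pr$lower[pr$lower > 0], pr$upper, obs$conc[obs$conc > 0]))
    graphics::plot(NA, xlim = range(pr$time_h), ylim = ylim, log = "y",
                   xlab = "time (h)", ylab = "copies / L", main = cp, ...)
    for (cb in unique(pr$carboy)) {
      pc <- pr[pr$carboy == cb, ]
      graphics::polygon(c(pc$time_h, rev(pc$time_h)),
                        pmax(c(pc$lower, rev(pc$upper)), ylim[1]),
                        col = grDevices::adjustcolor(cb, alpha.f = 0.15),
                        border = NA)
      graphics::lines(pc$time_h, pc$median, col = cb)
    }
    graphics::points(obs$t, pmax(obs$conc, ylim[1]), pch = 19, cex = 0.6,
                     col = obs$carboy)
  }
  invisible(x)
}

# point concentrations of observed wells for one component
observed_concentrations <- function(fit, comp) {
  cc <- fit$components
  i <- which(cc$comp == comp)
  if (cc$type[i] == "monoplex") {
    m <- fit$dataset$monoplex
    m <- m[m$comp == comp, ]
    p <- pmin(m$droplets_positive / m$droplets_total, 1 - 1e-12)
    data.frame(t = m$time_actual_h, conc = -log1p(-p) / m$k,
               carboy = m$carboy)
  } else {
    d <- fit$dataset$duplex
    lam <- vapply(seq_len(nrow(d)), function(w) {
      est <- tryCatch(estimate_linked_closed_form(
        d$n_both[w], d$n_a_only[w], d$n_b_only[w], d$n_neither[w]),
        error = function(e) NULL)
      if (is.null(est)) return(NA_real_)
      switch(cc$duplex_role[i],
             a_free = est$lambda_a_free, b_free = est$lambda_b_free,
             linked = est$lambda_linked)
    }, 0)
    data.frame(t = d$time_actual_h, conc = lam / d$k, carboy = d$carboy)
  }
}
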