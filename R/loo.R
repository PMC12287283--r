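# Pareto-smoothed importance-sampling leave-one-out cross-validation.
#
# For each well, the importance ratios 1/p(y_i | theta_s) are tail-smoothed
# by replacing the largest ratios with expected order statistics of a
# generalized Pareto distribution fitted to them, then truncated; the
# smoothed weights give a stable estimate of the leave-one-out predictive
# density. The tail-shape estimate k-hat diagnoses reliability (k > 0.7 is
# flagged).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# generalized Pareto fit (profile-likelihood quadrature with a weak prior
# pulling k toward 1/2), on exceedances x > 0
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(floor(n / 4 + 0.5), 1)]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  kj <- vapply(theta, function(th) -mean(log1p(-th * x)), 0)
  lj <- n * (log(theta / kj) + kj - 1)
  wj <- 1 / vapply(jj, function(j) sum(exp(lj - lj[j])), 0)
  theta_hat <- sum(theta * wj)
  k <- mean(log1p(-theta_hat * x))   # tail shape (positive = heavy tail)
  sigma <- -k / theta_hat
  # regularize k-hat toward 0.5 with 10 prior pseudo-observations
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# smooth one vector of log-weights; returns list(log_weights, pareto_k)
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || length(unique(lw)) < 5)
    return(list(log_weights = lw, pareto_k = -Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_ids]) - cut
  if (all(exceed <= 0)) return(list(log_weights = lw, pareto_k = -Inf))
  fit <- gpd_fit(exceed[exceed > 0])
  qq <- qgpd((seq_len(M) - 0.5) / M, fit$k, fit$sigma) + cut
  lw[tail_ids[order(exceed)]] <- log(pmin(qq, exp(max(lw))))
  list(log_weights = lw - logsumexp(lw), pareto_k = fit$k)
}

#' Pointwise log-likelihood matrix of a decay fit
#'
#' Evaluates the binomial (monoplex) or multinomial (duplex) log mass of
#' every well at (a thinned subset of) the posterior draws.
#'
#' @param fit a [decay_fit()].
#' @param thin_to approximate number of draws to retain (default 4000).
#' @return matrix, draws x wells; column names identify the wells.
#' @export
loglik_matrix <- function(fit, thin_to = 4000) {
  S_full <- prod(dim(fit$draws)[1:2])
  step <- max(1L, floor(S_full / thin_to))
  iter_idx <- seq(1, S_full, by = step)
  cols <- list()
  cc <- fit$components
  m <- fit$dataset$monoplex
  if (!is.null(m) && nrow(m)) {
    m <- m[m$comp %in% cc$comp[cc$effective_model != "none"], ]
    for (w in seq_len(nrow(m))) {
      mu <- conc_draws(fit, m$comp[w], m$time_actual_h[w],
                       fit$dataset$carboys[m$cb[w]], iter_idx)[, 1] * m$k[w]
      p <- pmin(1 - exp(-mu), 1 - 1e-12)
      cols[[paste0("m", w)]] <-
        stats::dbinom(round(m$droplets_positive[w]), m$droplets_total[w], p,
                      log = TRUE)
    }
  }
  d <- fit$dataset$duplex
  if (!is.null(d) && nrow(d) && any(cc$type == "duplex" &
                                    cc$effective_model != "none")) {
    dup <- cc[cc$type == "duplex", ]
    lam <- lapply(dup$comp, function(cp)
      sapply(seq_len(nrow(d)), function(w)
        conc_draws(fit, cp, d$time_actual_h[w],
                   fit$dataset$carboys[d$cb[w]], iter_idx)[, 1] * d$k[w]))
    for (w in seq_len(nrow(d))) {
      la <- lam[[1]][, w]; lb <- lam[[2]][, w]; lL <- lam[[3]][, w]
      p00 <- exp(-(la + lb + lL))
      pa <- exp(-(lb + lL)) - p00
      pb <- exp(-(la + lL)) - p00
      pboth <- pmax(1 - p00 - pa - pb, 1e-300)
      pa <- pmax(pa, 1e-300); pb <- pmax(pb, 1e-300)
      z <- c(d$n_both[w], d$n_a_only[w], d$n_b_only[w], d$n_neither[w])
      const <- lgamma(d$droplets_total[w] + 1) - sum(lgamma(z + 1))
      cols[[paste0("d", w)]] <- const + z[1] * log(pboth) + z[2] * log(pa) +
        z[3] * log(pb) + z[4] * log(p00)
    }
  }
  do.call(cbind, cols)
}

#' PSIS leave-one-out cross-validation estimate
#'
#' @param fit a [decay_fit()], or a draws x wells pointwise log-likelihood
#'   matrix.
#' @param thin_to passed to [loglik_matrix()] when `fit` is a decay fit.
#' @return object of class `decay_loo`: `elpd_loo`, `se_elpd_loo`, pointwise
#'   contributions, and Pareto k diagnostics.
#' @export
decay_loo <- function(fit, thin_to = 4000) {
  ll <- if (inherits(fit, "decay_fit")) loglik_matrix(fit, thin_to) else fit
  N <- ncol(ll)
  elpd_i <- numeric(N)
  k_i <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-ll[, i])
    elpd_i[i] <- logsumexp(sm$log_weights + ll[, i])
    k_i[i] <- sm$pareto_k
  }
  structure(list(
    elpd_loo = sum(elpd_i), se_elpd_loo = sqrt(N * stats::var(elpd_i)),
    pointwise = elpd_i, pareto_k = k_i, n_wells = N,
    n_high_k = sum(k_i > 0.7),
    model = if (inherits(fit, "decay_fit")) fit$model else NA_character_,
    well_ids = colnames(ll)),
    class = "decay_loo")
}

#' @export
print.decay_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO (%s): elpd_loo = %.1f (SE %.1f) over %d wells",
              x$model, x$elpd_loo, x$se_elpd_loo, x$n_wells))
  if (x$n_high_k > 0)
    cat(sprintf("; %d wells with Pareto k > 0.7", x$n_high_k))
  cat("\n")
  invisible(x)
}

#' Compare candidate decay models by PSIS-LOO
#'
#' @param ... two or more [decay_fit()] objects (fitted to the same wells) or
#'   [decay_loo()] objects; a single list is also accepted.
#' @param thin_to passed to [loglik_matrix()].
#' @return data frame of class `loo_comparison`, ranked by `elpd_loo`, with
#'   pairwise differences to the best model and their standard errors.
#' @export
compare_models_loo <- function(..., thin_to = 4000) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], c("decay_fit", "decay_loo")))
    fits <- fits[[1]]
  if (length(fits) < 2) stop("need at least two models", call. = FALSE)
  loos <- lapply(fits, function(f)
    if (inherits(f, "decay_loo")) f else decay_loo(f, thin_to))
  ids <- lapply(loos, `[[`, "well_ids")
  for (i in seq_along(loos)[-1])
    if (!identical(ids[[i]], ids[[1]]))
      stop("models were fitted to different well sets; LOO comparison invalid",
           call. = FALSE)
  nm <- vapply(loos, function(l) l$model %||% "model", "")
  nm[is.na(nm)] <- paste0("model", which(is.na(nm)))
  nm <- make.unique(nm)
  ord <- order(vapply(loos, `[[`, 0, "elpd_loo"), decreasing = TRUE)
  best <- loos[[ord[1]]]
  rows <- lapply(ord, function(i) {
    di <- loos[[i]]$pointwise - best$pointwise
    data.frame(model = nm[i],
               elpd_loo = loos[[i]]$elpd_loo,
               se_elpd_loo = loos[[i]]$se_elpd_loo,
               elpd_diff = sum(di),
               se_diff = sqrt(length(di) * stats::var(di)),
               n_high_k = loos[[i]]$n_high_k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("loo_comparison", "data.frame")
  out
}

#' @export
print.loo_comparison <- function(x, ...) {
  cat("Model comparison by PSIS-LOO (best first):\n")
  df <- x
  class(df) <- "data.frame"
  print(format(df, digits = 4), row.names = FALSE)
  invisible(x)
}
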