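# Rank-normalized split-chain convergence diagnostics.
#
# Both statistics follow the modern recipe: draws are replaced by their
# normal scores (rank-normalization makes the diagnostics insensitive to
# heavy tails), each chain is split in half (detecting within-chain trends),
# and the classic between/within variance ratio or the autocorrelation-based
# effective sample size is computed on the result.

z_scale <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

# draws: iterations x chains matrix -> split-halved matrix (n/2 x 2m)
split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rhat_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' @param x iterations x chains matrix of posterior draws for one parameter.
#' @return the potential scale reduction factor; values near 1 indicate the
#'   chains agree.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2)
    stop("R-hat is undefined for a single chain", call. = FALSE)
  xs <- split_chains(x)
  z <- matrix(z_scale(as.vector(xs)), nrow(xs), ncol(xs))
  # folded version catches scale (not just location) differences
  xf <- abs(xs - stats::median(xs))
  zf <- matrix(z_scale(as.vector(xf)), nrow(xs), ncol(xs))
  max(rhat_basic(z), rhat_basic(zf))
}

# chain autocovariance by FFT: acov[h+1] = (1/n) sum (y_i - mean)(y_{i+h} - mean)
autocov_fft <- function(y) {
  n <- length(y)
  y <- y - mean(y)
  M <- stats::nextn(2 * n)
  f <- stats::fft(c(y, rep(0, M - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (M * n)
}

#' Bulk effective sample size (rank-normalized, split chains)
#'
#' Combines within-chain autocorrelations across split chains with Geyer's
#' initial monotone positive sequence truncation.
#'
#' @param x iterations x chains matrix of posterior draws for one parameter.
#' @return effective number of independent draws.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  xs <- split_chains(x)
  z <- matrix(z_scale(as.vector(xs)), nrow(xs), ncol(xs))
  n <- nrow(z)
  m <- ncol(z)
  if (n < 4 || stats::var(as.vector(z)) == 0) return(NA_real_)
  acov <- apply(z, 2, autocov_fft)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  mu <- colMeans(z)
  var_plus <- mean_var * (n - 1) / n + (if (m > 1) stats::var(mu) else 0)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer pairs: sum consecutive lag pairs, keep while positive, enforce
  # monotone decrease
  maxpair <- floor(n / 2) - 1
  P <- numeric(0)
  for (k in 0:maxpair) {
    p <- rho[2 * k + 1] + (if (2 * k + 2 <= length(rho)) rho[2 * k + 2] else 0)
    if (k > 0 && p < 0) break
    P <- c(P, max(p, 0))
  }
  for (k in seq_along(P)) if (k > 1) P[k] <- min(P[k], P[k - 1])
  tau <- -1 + 2 * sum(P)
  max(m * n / tau, 0)
}

#' Convergence diagnostics for a decay fit
#'
#' Computes rank-normalized split R-hat and bulk effective sample size for
#' every monitored parameter and checks them against thresholds.
#'
#' @param fit a [decay_fit()] object (or a 3-d draws array iterations x
#'   chains x parameters).
#' @param rhat_threshold maximum acceptable R-hat (default 1.005).
#' @param ess_threshold minimum acceptable bulk ESS (default 500).
#' @return data frame of class `convergence_diagnostics` with one row per
#'   parameter: `rhat`, `ess_bulk`, `pass`; attribute `"pass"` gives the
#'   overall verdict.
#' @export
convergence_diagnostics <- function(fit, rhat_threshold = 1.005,
                                    ess_threshold = 500) {
  draws <- if (inherits(fit, "decay_fit")) fit$draws else fit
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2)
    stop("R-hat is undefined for a single chain", call. = FALSE)
  pars <- dimnames(draws)[[3]]
  out <- data.frame(
    parameter = pars,
    rhat = vapply(pars, function(p) rhat(draws[, , p]), 0),
    ess_bulk = vapply(pars, function(p) ess_bulk(draws[, , p]), 0))
  out$pass <- out$rhat < rhat_threshold & out$ess_bulk > ess_threshold
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$pass)
  attr(out, "thresholds") <- c(rhat = rhat_threshold, ess = ess_threshold)
  class(out) <- c("convergence_diagnostics", "data.frame")
  out
}

#' @export
print.convergence_diagnostics <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("Convergence: max R-hat %.4f (< %.3f), min bulk ESS %.0f (> %.0f) -> %s\n",
              max(x$rhat), th["rhat"], min(x$ess_bulk), th["ess"],
              if (attr(x, "pass")) "PASS" else "FAIL"))
  if (!attr(x, "pass")) {
    df <- x[!x$pass, ]
    class(df) <- "data.frame"
    print(df, row.names = FALSE)
  }
  invisible(x)
}
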