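#' Poisson occupancy estimate from droplet counts
#'
#' In droplet digital PCR the reaction is partitioned into roughly 20,000
#' droplets and target molecules distribute among them at random, so the
#' number of copies in a droplet is Poisson with mean \eqn{\mu} and the
#' probability that a droplet lights up is \eqn{p = 1 - e^{-\mu}}. Given
#' \code{W} positive droplets out of \code{U}, the occupancy is estimated as
#' \eqn{\hat p = W/U} with an exact (Clopper--Pearson) binomial confidence
#' interval, and the per-droplet mean copy number is recovered through the
#' complementary log-log relation \eqn{\mu = -\ln(1 - \hat p)}.
#'
#' A well with every droplet positive (\code{W == U}) carries no finite point
#' estimate of \eqn{\mu}; it is returned with \code{mu = Inf} and
#' \code{saturated = TRUE} so downstream point-estimate tables can exclude it
#' while likelihood-based fits retain the underlying counts.
#'
#' @param W integer vector, positive droplets per well.
#' @param U integer vector, total droplets per well (recycled against `W`).
#' @param conf confidence level for the exact binomial interval.
#' @return A data frame with one row per well: `W`, `U`, `p_hat`, `mu`,
#'   `ci_low`, `ci_high` (occupancy scale), `mu_low`, `mu_high` (copy scale)
#'   and `saturated`.
#' @examples
#' estimate_occupancy(10000, 20000)   # p = 0.5, mu = log(2)
#' @export
estimate_occupancy <- function(W, U, conf = 0.95) {
  if (length(U) == 1L) U <- rep(U, length(W))
  if (length(W) != length(U))
    stop("W and U must have equal length (or U scalar)", call. = FALSE)
  if (any(!is.finite(W)) || any(!is.finite(U)))
    stop("droplet counts must be finite", call. = FALSE)
  if (any(U <= 0)) stop("total droplet count U must be positive", call. = FALSE)
  if (any(W < 0) || any(W > U))
    stop("positive droplets W must satisfy 0 <= W <= U", call. = FALSE)

  p_hat <- W / U
  alpha <- 1 - conf
  # Clopper-Pearson via beta quantiles; closed at the boundaries
  ci_low <- ifelse(W == 0, 0, stats::qbeta(alpha / 2, W, U - W + 1))
  ci_high <- ifelse(W == U, 1, stats::qbeta(1 - alpha / 2, W + 1, U - W))
  saturated <- W == U
  mu <- ifelse(saturated, Inf, -log1p(-p_hat))
  data.frame(
    W = W, U = U, p_hat = p_hat, mu = mu,
    ci_low = ci_low, ci_high = ci_high,
    mu_low = -log1p(-ci_low),
    mu_high = ifelse(ci_high < 1, -log1p(-ci_high), Inf),
    saturated = saturated
  )
}

#' Volume chain linking droplet copies to water-column concentration
#'
#' Holds the deterministic volume bookkeeping of the assay: a water sample of
#' `filt_vol` litres is filtered, nucleic acids are eluted in `evol`
#' microlitres, `tvol` microlitres of (possibly `dilution_d`-fold diluted)
#' template enter a `rvol`-microlitre ddPCR reaction that is partitioned into
#' droplets of `dvol` microlitres each.
#'
#' @param rvol ddPCR reaction volume, uL (default 22).
#' @param tvol template volume added to the reaction, uL (default 2).
#' @param evol extraction elution volume, uL (default 50).
#' @param dvol single-droplet volume, uL (default 8.5e-4, i.e. ~0.85 nL).
#' @param filt_vol filtered water volume, litres (default 2).
#' @param dilution_d template dilution factor >= 1 (e.g. from the reverse
#'   transcription reaction); a diluted template lowers per-droplet occupancy,
#'   so inferred source concentrations scale up by this factor.
#' @return An object of class `volume_chain`.
#' @export
volume_chain <- function(rvol = 22, tvol = 2, evol = 50, dvol = 8.5e-4,
                         filt_vol = 2, dilution_d = 1) {
  v <- list(rvol = rvol, tvol = tvol, evol = evol, dvol = dvol,
            filt_vol = filt_vol, dilution_d = dilution_d)
  bad <- names(v)[!vapply(v, function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0), TRUE)]
  if (length(bad))
    stop("volume chain entries must be positive and finite: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(v$dilution_d < 1))
    stop("dilution_d must be >= 1", call. = FALSE)
  if (any(v$dvol >= v$rvol))
    stop("droplet volume must be much smaller than the reaction volume", call. = FALSE)
  structure(v, class = "volume_chain")
}

#' @export
print.volume_chain <- function(x, ...) {
  cat("ddPCR volume chain:\n")
  cat(sprintf("  reaction %g uL | template %g uL | elution %g uL | droplet %g uL\n",
              x$rvol, x$tvol, x$evol, x$dvol))
  cat(sprintf("  filtered %g L | template dilution x%g\n", x$filt_vol, x$dilution_d))
  invisible(x)
}

# copies/L of source water per unit of per-droplet mean copy number; the
# whole chain is linear, so a single factor carries the conversion both ways.
conc_per_mu <- function(chain) {
  with(unclass(chain), rvol * evol * dilution_d / (dvol * tvol * filt_vol))
}

#' Convert per-droplet mean copies to source-water concentration
#'
#' Walks the volume chain step by step: copies per uL of reaction
#' (`mu / dvol`), copies in the reaction (`x rvol`), copies per uL of
#' template (`/ tvol`), undiluted (`x dilution_d`), copies in the extract
#' (`x evol`) and finally copies per litre of filtered water (`/ filt_vol`).
#' The inverse, [concentration_to_mean_copies()], is exact.
#'
#' @param mu per-droplet mean copy number (>= 0), vectorised.
#' @param chain a [volume_chain()].
#' @return concentration in copies per litre of source water.
#' @export
mean_copies_to_concentration <- function(mu, chain = volume_chain()) {
  stopifnot(inherits(chain, "volume_chain"))
  if (any(mu < 0, na.rm = TRUE)) stop("mu must be >= 0", call. = FALSE)
  mu * conc_per_mu(chain)
}

#' Convert source-water concentration to per-droplet mean copies
#' @param conc copies per litre of source water (>= 0), vectorised.
#' @inheritParams mean_copies_to_concentration
#' @return per-droplet mean copy number.
#' @export
concentration_to_mean_copies <- function(conc, chain = volume_chain()) {
  stopifnot(inherits(chain, "volume_chain"))
  if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0", call. = FALSE)
  conc / conc_per_mu(chain)
}

#' Subtract No-RT control droplet counts from eRNA wells
#'
#' The No-RT control (a reverse-transcription reaction without the enzyme)
#' quantifies residual DNA carryover in RNA extracts; its positive-droplet
#' count is subtracted from the paired eRNA well count, floored at zero
#' because droplet counts are physical.
#'
#' @param W_erna positive droplets in the eRNA well(s).
#' @param W_nort positive droplets in the paired No-RT control well(s).
#' @return adjusted counts, with an `"adjusted"` attribute marking wells that
#'   were changed.
#' @export
subtract_no_rt <- function(W_erna, W_nort) {
  if (length(W_nort) == 1L) W_nort <- rep(W_nort, length(W_erna))
  if (length(W_erna) != length(W_nort))
    stop("eRNA and No-RT counts must be paired 1:1", call. = FALSE)
  if (any(W_erna < 0) || any(W_nort < 0))
    stop("droplet counts must be >= 0", call. = FALSE)
  out <- pmax(W_erna - W_nort, 0)
  attr(out, "adjusted") <- W_nort > 0
  out
}

#' Particle-size distribution of signal across filter pore sizes
#'
#' Summarises how a marker's concentration partitions across the stages of a
#' serial filtration (e.g. 5, 1.0 and 0.45 um) and reports whether the
#' dominant fraction passes a screening threshold, supporting the decision to
#' restrict downstream analysis to a single size fraction.
#'
#' @param pore_size_um numeric vector of pore sizes.
#' @param concentration matching concentrations (copies/L, >= 0).
#' @param threshold screening threshold on the dominant fraction (default
#'   0.95).
#' @return list with `fractions` (named, summing to 1), `dominant` (pore
#'   size), `dominant_fraction`, `passes_screen`, and `verdict` text; when all
#'   concentrations are zero, fractions are `NA` and `undefined = TRUE`.
#' @export
size_fraction_profile <- function(pore_size_um, concentration, threshold = 0.95) {
  if (length(pore_size_um) != length(concentration))
    stop("pore sizes and concentrations must match", call. = FALSE)
  if (any(concentration < 0)) stop("concentrations must be >= 0", call. = FALSE)
  tot <- tapply(concentration, pore_size_um, sum)
  total <- sum(tot)
  if (total == 0) {
    return(list(fractions = stats::setNames(rep(NA_real_, length(tot)), names(tot)),
                dominant = NA, dominant_fraction = NA_real_,
                passes_screen = FALSE, undefined = TRUE,
                verdict = "no signal in any size fraction"))
  }
  fr <- tot / total
  dom <- which.max(fr)
  passes <- unname(fr[dom]) >= threshold
  list(
    fractions = stats::setNames(as.numeric(fr), names(fr)),
    dominant = as.numeric(names(fr)[dom]),
    dominant_fraction = unname(fr[dom]),
    passes_screen = passes,
    undefined = FALSE,
    verdict = if (passes)
      sprintf("restrict analysis to the %g um fraction (%.1f%% of signal)",
              as.numeric(names(fr)[dom]), 100 * fr[dom])
    else
      sprintf("signal spread across fractions; dominant %g um holds %.1f%% (< %.0f%% screen)",
              as.numeric(names(fr)[dom]), 100 * fr[dom], 100 * threshold)
  )
}
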