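#' Specification of a molecular-clock ratio
#'
#' A "molecular clock" is a ratio of a fast-decaying numerator component to
#' one or more slower components; because shedding magnitude cancels, the
#' ratio indexes time since release rather than amount. Two canonical specs:
#' the proportion of long (Bridge) versus short (Cytb) mitochondrial
#' fragments, and the proportion of ribosomal eRNA relative to total 16S
#' nucleic acids.
#'
#' @param numerator component key (e.g. `"Bridge_eDNA"`).
#' @param denominator character vector of component keys whose concentrations
#'   are summed; whether the numerator itself belongs in the denominator is
#'   the caller's explicit choice (include its key to get a proportion in
#'   \[0, 1\]).
#' @param label display label.
#' @return object of class `ratio_spec`.
#' @export
ratio_spec <- function(numerator, denominator, label = NULL) {
  stopifnot(is.character(numerator), length(numerator) == 1,
            is.character(denominator), length(denominator) >= 1)
  structure(list(numerator = numerator, denominator = denominator,
                 label = label %||% paste0(numerator, ":",
                                           paste(denominator, collapse = "+")),
                 proportion = numerator %in% denominator),
            class = "ratio_spec")
}

#' Built-in clock specifications
#'
#' `clock_bridge_cytb()` is the long:short mitochondrial fragment ratio
#' (Bridge concentration over Cytb eDNA concentration; set
#' `include_numerator = TRUE` for the bounded proportion variant).
#' `clock_rna_fraction()` is the ribosomal eRNA share of total 16S nucleic
#' acids.
#'
#' @param include_numerator add the numerator to the denominator sum.
#' @return a [ratio_spec()].
#' @export
clock_bridge_cytb <- function(include_numerator = FALSE) {
  den <- if (include_numerator) c("Bridge_eDNA", "Cytb_eDNA") else "Cytb_eDNA"
  ratio_spec("Bridge_eDNA", den, label = "Bridge:Cytb")
}

#' @rdname clock_bridge_cytb
#' @export
clock_rna_fraction <- function() {
  ratio_spec("16S_erRNA", c("16S_erRNA", "16S_eDNA"),
             label = "erRNA:(erRNA+eDNA) 16S")
}

#' Posterior ratio trajectory of a molecular clock
#'
#' For every posterior draw the component concentrations are evaluated on the
#' time grid (per carboy), the ratio is formed draw-wise, and only then are
#' the median and credible quantiles taken -- never a ratio of summaries.
#' Draws with a zero denominator at a grid point are excluded there and
#' counted.
#'
#' @param fit a [decay_fit()] containing all components of the spec.
#' @param spec a [ratio_spec()].
#' @param grid time grid in hours (default 0 to 24 in 0.5 h steps).
#' @param level credible level (default 0.95).
#' @return data frame of class `ratio_trajectory`: carboy, time_h, median,
#'   lower, upper; attributes `spec`, `n_excluded`.
#' @export
ratio_trajectory <- function(fit, spec, grid = seq(0, 24, by = 0.5),
                             level = 0.95) {
  stopifnot(inherits(fit, "decay_fit"), inherits(spec, "ratio_spec"))
  have <- fit$components$comp[fit$components$effective_model != "none"]
  need <- unique(c(spec$numerator, spec$denominator))
  if (!all(need %in% have))
    stop("fit lacks clock components: ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  a <- (1 - level) / 2
  n_excluded <- 0L
  out <- list()
  for (cb in fit$dataset$carboys) {
    num <- conc_draws(fit, spec$numerator, grid, cb)
    den <- 0
    for (cp in spec$denominator) den <- den + conc_draws(fit, cp, grid, cb)
    bad <- den == 0
    n_excluded <- n_excluded + sum(bad)
    r <- num / den
    r[bad] <- NA
    out[[length(out) + 1L]] <- data.frame(
      carboy = cb, time_h = grid,
      median = apply(r, 2, stats::median, na.rm = TRUE),
      lower = apply(r, 2, stats::quantile, a, na.rm = TRUE),
      upper = apply(r, 2, stats::quantile, 1 - a, na.rm = TRUE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  attr(out, "n_excluded") <- n_excluded
  attr(out, "level") <- level
  class(out) <- c("ratio_trajectory", "data.frame")
  out
}

#' Linear trend of a clock trajectory
#'
#' Ordinary least-squares fit of the pooled (all carboys stacked) posterior
#' median trajectory against time: a heuristic summary of clock direction
#' and magnitude. Grid points are autocorrelated, so the p-value is reported
#' as a descriptive index only.
#'
#' @param traj a [ratio_trajectory()].
#' @return list of class `clock_slope`: `slope` (per hour), `intercept`,
#'   `r_squared`, `p_value`, `zero_variance` flag.
#' @export
clock_slope <- function(traj) {
  stopifnot(inherits(traj, "ratio_trajectory"))
  if (length(unique(traj$time_h)) < 3)
    stop("at least 3 grid points are required", call. = FALSE)
  if (stats::var(traj$median) < .Machine$double.eps) {
    out <- list(slope = 0, intercept = traj$median[1], r_squared = NA_real_,
                p_value = NA_real_, zero_variance = TRUE,
                label = attr(traj, "spec")$label)
    class(out) <- "clock_slope"
    return(out)
  }
  f <- stats::lm(median ~ time_h, data = traj)
  sm <- suppressWarnings(summary(f))  # noiseless trajectories fit exactly
  out <- list(slope = unname(stats::coef(f)[2]),
              intercept = unname(stats::coef(f)[1]),
              r_squared = sm$r.squared,
              p_value = sm$coefficients[2, 4],
              zero_variance = FALSE,
              label = attr(traj, "spec")$label)
  class(out) <- "clock_slope"
  out
}

#' @export
print.clock_slope <- function(x, ...) {
  cat(sprintf("Clock %s: slope %.5f per h (R2 %.3f, heuristic p %.2g)%s\n",
              x$label, x$slope, x$r_squared %||% NA, x$p_value %||% NA,
              if (x$zero_variance) " [constant trajectory]" else ""))
  invisible(x)
}
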