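# Synthetic mesocosm experiment: forward simulation from known decay truth
# down to droplet counts, in the exact CSV dialect the readers consume.

#' Mesocosm experiment design
#'
#' Defaults reproduce the study layout: three seawater carboys plus a
#' deionized-water control, nine sampling timepoints over 188 h, two ddPCR
#' technical replicates per extract, ~20,000 droplets per well, 2 L filtered
#' per sample, and a pre-transport baseline sample 3 h before chamber time
#' zero.
#'
#' @param n_carboys biological replicate carboys (default 3).
#' @param control_carboy index of the DI-water control, `NA` for none
#'   (default `n_carboys + 1`).
#' @param timepoints nominal sampling times, hours.
#' @param tech_reps technical ddPCR replicates per sample.
#' @param droplets_per_well total droplets per well.
#' @param chain default [volume_chain()].
#' @param erna_dilution template dilution factor applied to eRNA wells by the
#'   reverse-transcription reaction (default 2).
#' @param pore_sizes filter pore sizes in um; the first is the primary
#'   fraction. With more than one, a serial-filtration screen of Cytb eDNA is
#'   simulated at the first timepoint.
#' @param baseline_offset_h nominal time of the pre-transport baseline sample
#'   (default -3).
#' @param include_baseline simulate baseline rows (default TRUE; they are
#'   tagged and excluded from fits by [build_dataset()] unless requested).
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(n_carboys = 3, control_carboy = n_carboys + 1,
                              timepoints = c(0, 4, 8, 12, 24, 48, 96, 140, 188),
                              tech_reps = 2, droplets_per_well = 20000,
                              chain = volume_chain(), erna_dilution = 2,
                              pore_sizes = 5, baseline_offset_h = -3,
                              include_baseline = TRUE) {
  stopifnot(n_carboys >= 1, tech_reps >= 1, droplets_per_well > 0,
            all(diff(timepoints) > 0))
  structure(list(n_carboys = n_carboys, control_carboy = control_carboy,
                 timepoints = timepoints, tech_reps = tech_reps,
                 droplets_per_well = droplets_per_well, chain = chain,
                 erna_dilution = erna_dilution, pore_sizes = pore_sizes,
                 baseline_offset_h = baseline_offset_h,
                 include_baseline = include_baseline),
            class = "experiment_design")
}

#' Default generating truth of the synthetic mesocosm
#'
#' Decay rates and changepoints are the mesocosm study conditions per
#' marker-component; initial concentrations fix the two clock proportions at
#' time zero (Bridge:Cytb concentration ratio 0.1082464 and ribosomal-RNA
#' share 0.8551342 of 16S nucleic acids -- solved in closed form from the
#' phase-1 rates so the 0-24 h ratio trajectories decline at -0.0036 and
#' -0.0142 per hour). Cytb emRNA decays in a single phase and is gone after
#' the first sample.
#'
#' @return data frame of per-component decay truth.
#' @export
default_truth_table <- function() {
  data.frame(
    marker = c("Cytb", "Cytb", "16S", "16S", "Dloop", "Bridge"),
    component = c("eDNA", "emRNA", "erRNA", "eDNA", "eDNA", "eDNA"),
    assay = c("monoplex", "monoplex", "monoplex",
              "duplex_a", "duplex_b", "duplex_linked"),
    C0 = c(1e6, 200,
           0.8551342 / (1 - 0.8551342) * 1.5e5,  # erRNA share 0.8551342
           1.5e5, 1.2e5,
           0.1082464 * 1e6),                     # Bridge:Cytb ratio 0.1082464
    lambda1 = c(0.114, 1.615, 0.236, 0.165, 0.166, 0.190),
    lambda2 = c(0.026, 1.615, 0.054, 0.028, 0.021, 0.044),
    t_x = c(41, 24, 29, 33, 36, 28),
    stringsAsFactors = FALSE)
}

#' Generating truth for the synthetic experiment
#'
#' @param components data frame with columns `marker`, `component`, `assay`
#'   (`monoplex`, `duplex_a`, `duplex_b`, `duplex_linked`), `C0`, `lambda1`,
#'   `lambda2`, `t_x`; defaults to the mesocosm study conditions (see
#'   [default_truth_table()] source for the calibration of the initial
#'   proportions).
#' @param carboy_sd lognormal standard deviation of carboy-level multipliers
#'   on C0 (default 0.2); rates are shared across carboys unless
#'   `carboy_specific_rates` (a robustness / mis-specification mode) is set.
#' @param carboy_specific_rates lognormal sd applied to each carboy's decay
#'   rates (default 0 = shared rates, matching the inference model).
#' @param nort_rate expected positive droplets per No-RT control well
#'   (residual DNA carryover; default 0.5).
#' @param jitter_h filtration-time jitter: actual time = nominal +
#'   Uniform(0, `jitter_h`) (default 0.25 h).
#' @param pore_allocation named fractions of signal captured per pore size
#'   for the serial-filtration screen.
#' @return object of class `truth_params`.
#' @export
truth_params <- function(components = default_truth_table(), carboy_sd = 0.2,
                         carboy_specific_rates = 0, nort_rate = 0.5,
                         jitter_h = 0.25,
                         pore_allocation = c("5" = 0.96, "1" = 0.025,
                                             "0.45" = 0.015)) {
  stopifnot(all(c("marker", "component", "assay", "C0", "lambda1", "lambda2",
                  "t_x") %in% names(components)),
            carboy_sd >= 0, nort_rate >= 0, jitter_h >= 0,
            abs(sum(pore_allocation) - 1) < 1e-9)
  structure(list(components = components, carboy_sd = carboy_sd,
                 carboy_specific_rates = carboy_specific_rates,
                 nort_rate = nort_rate, jitter_h = jitter_h,
                 pore_allocation = pore_allocation),
            class = "truth_params")
}

#' Simulate true per-sample concentrations
#'
#' Applies the biphasic (or effectively single-phase) decay curve of each
#' component per carboy, with lognormal carboy-level multipliers on the
#' initial concentration, uniform filtration-time jitter on the actual
#' sampling times, zero concentration in the control carboy, and tagged
#' baseline rows at the pre-transport offset (concentration extrapolated
#' backwards along phase 1).
#'
#' @param truth a [truth_params()].
#' @param design an [experiment_design()].
#' @param seed RNG seed.
#' @return data frame: marker, component, assay, carboy, time_nominal_h,
#'   time_actual_h, baseline, C_true.
#' @export
simulate_true_concentrations <- function(truth = truth_params(),
                                         design = experiment_design(),
                                         seed = 1) {
  set.seed(seed)
  tc <- truth$components
  carboys <- seq_len(design$n_carboys)
  all_cb <- c(carboys, if (!is.na(design$control_carboy)) design$control_carboy)
  tps <- c(if (design$include_baseline) design$baseline_offset_h,
           design$timepoints)
  # carboy multipliers and per-sample jitter drawn up front, in fixed order.
  # The C0 multiplier is shared across components within a carboy: all
  # components ride in the same water parcel, so fill-level and handling
  # effects scale them jointly (component ratios stay carboy-invariant).
  mult <- matrix(rep(exp(stats::rnorm(length(carboys), 0, truth$carboy_sd)),
                     nrow(tc)),
                 length(carboys), nrow(tc))
  rmult1 <- matrix(exp(stats::rnorm(length(carboys) * nrow(tc), 0,
                                    truth$carboy_specific_rates)),
                   length(carboys), nrow(tc))
  rmult2 <- matrix(exp(stats::rnorm(length(carboys) * nrow(tc), 0,
                                    truth$carboy_specific_rates)),
                   length(carboys), nrow(tc))
  jit <- matrix(stats::runif(length(all_cb) * length(tps), 0, truth$jitter_h),
                length(all_cb), length(tps))
  out <- list()
  for (ci in seq_along(all_cb)) {
    cb <- all_cb[ci]
    is_ctrl <- !is.na(design$control_carboy) && cb == design$control_carboy
    for (ti in seq_along(tps)) {
      t <- tps[ti]
      t_act <- t + jit[ci, ti]   # decay continues until actual filtration
      base <- t < 0
      C <- vapply(seq_len(nrow(tc)), function(i) {
        if (is_ctrl) return(0)
        l1 <- tc$lambda1[i] * rmult1[cb, i]
        l2 <- tc$lambda2[i] * rmult2[cb, i]
        C0 <- tc$C0[i] * mult[cb, i]
        if (t_act < 0) C0 * exp(-l1 * t_act)  # phase 1 extrapolated backwards
        else C0 * exp(-l1 * min(t_act, tc$t_x[i]) -
                        l2 * max(t_act - tc$t_x[i], 0))
      }, 0)
      out[[length(out) + 1L]] <- data.frame(
        marker = tc$marker, component = tc$component, assay = tc$assay,
        carboy = cb, time_nominal_h = t,
        time_actual_h = t_act, baseline = base, C_true = C)
    }
  }
  do.call(rbind, out)
}

#' Simulate droplet counts from true concentrations
#'
#' Monoplex wells draw `W ~ Binomial(U, 1 - exp(-mu))` with `mu` from the
#' volume chain (eRNA wells carry the reverse-transcription dilution);
#' duplex wells draw the four categories from the linkage multinomial; each
#' eRNA well gets a paired No-RT control well with Poisson residual
#' carryover (zero in the control carboy). With several pore sizes, a serial
#' filtration of Cytb eDNA is simulated at the first timepoint, splitting
#' the signal by the truth's allocation fractions.
#'
#' @param conc output of [simulate_true_concentrations()].
#' @param truth a [truth_params()].
#' @param design an [experiment_design()].
#' @param seed RNG seed.
#' @return list with `monoplex` and `duplex` well tables.
#' @export
simulate_droplet_counts <- function(conc, truth = truth_params(),
                                    design = experiment_design(), seed = 1) {
  set.seed(seed + 1)
  U <- design$droplets_per_well
  chain <- design$chain
  primary_pore <- design$pore_sizes[1]
  mono <- list()
  dup <- list()
  samples <- unique(conc[c("carboy", "time_nominal_h", "time_actual_h",
                           "baseline")])
  well_id <- 0L
  for (si in seq_len(nrow(samples))) {
    s <- samples[si, ]
    cs <- conc[conc$carboy == s$carboy &
                 conc$time_nominal_h == s$time_nominal_h, ]
    is_ctrl <- !is.na(design$control_carboy) &&
      s$carboy == design$control_carboy
    for (r in seq_len(design$tech_reps)) {
      # monoplex wells
      cm <- cs[cs$assay == "monoplex", ]
      for (i in seq_len(nrow(cm))) {
        is_rna <- cm$component[i] %in% c("emRNA", "erRNA")
        d <- if (is_rna) design$erna_dilution else 1
        k <- (chain$dvol * chain$tvol * chain$filt_vol) /
          (chain$rvol * chain$evol * d)
        pores <- if (length(design$pore_sizes) > 1 &&
                     s$time_nominal_h == design$timepoints[1] &&
                     cm$marker[i] == "Cytb" && cm$component[i] == "eDNA")
          design$pore_sizes else primary_pore
        for (ps in pores) {
          frac <- if (length(pores) > 1)
            truth$pore_allocation[[as.character(ps)]] else 1
          mu <- cm$C_true[i] * frac * k
          well_id <- well_id + 1L
          W <- stats::rbinom(1, U, 1 - exp(-mu))
          mono[[length(mono) + 1L]] <- data.frame(
            sample_id = sprintf("S%03d", well_id), marker = cm$marker[i],
            component = cm$component[i], carboy = s$carboy,
            time_nominal_h = s$time_nominal_h,
            time_actual_h = s$time_actual_h, tech_rep = r,
            pore_size_um = ps, droplets_total = U, droplets_positive = W,
            filt_vol_L = chain$filt_vol, dilution_d = d,
            baseline = s$baseline)
          if (is_rna) {  # paired No-RT control well
            well_id <- well_id + 1L
            Wn <- if (is_ctrl) 0L else
              min(stats::rpois(1, truth$nort_rate), U)
            mono[[length(mono) + 1L]] <- data.frame(
              sample_id = sprintf("S%03d", well_id), marker = cm$marker[i],
              component = "NoRT", carboy = s$carboy,
              time_nominal_h = s$time_nominal_h,
              time_actual_h = s$time_actual_h, tech_rep = r,
              pore_size_um = ps, droplets_total = U, droplets_positive = Wn,
              filt_vol_L = chain$filt_vol, dilution_d = d,
              baseline = s$baseline)
          }
        }
      }
      # duplex well
      ca <- cs[cs$assay == "duplex_a", ]
      cb_ <- cs[cs$assay == "duplex_b", ]
      cl <- cs[cs$assay == "duplex_linked", ]
      if (nrow(ca) && nrow(cb_) && nrow(cl)) {
        k <- (chain$dvol * chain$tvol * chain$filt_vol) /
          (chain$rvol * chain$evol)
        pr <- duplex_category_probs(ca$C_true[1] * k, cb_$C_true[1] * k,
                                    cl$C_true[1] * k)
        z <- as.vector(stats::rmultinom(1, U, pr))
        well_id <- well_id + 1L
        dup[[length(dup) + 1L]] <- data.frame(
          sample_id = sprintf("S%03d", well_id),
          marker = paste0(ca$marker[1], "-", cb_$marker[1]),
          component = "eDNA", carboy = s$carboy,
          time_nominal_h = s$time_nominal_h,
          time_actual_h = s$time_actual_h, tech_rep = r,
          pore_size_um = primary_pore, droplets_total = U,
          n_both = z[1], n_a_only = z[2], n_b_only = z[3], n_neither = z[4],
          filt_vol_L = chain$filt_vol, dilution_d = 1,
          baseline = s$baseline)
      }
    }
  }
  list(monoplex = do.call(rbind, mono),
       duplex = if (length(dup)) do.call(rbind, dup) else NULL)
}

#' Simulate a full experiment in memory
#'
#' Convenience wrapper chaining [simulate_true_concentrations()] and
#' [simulate_droplet_counts()].
#'
#' @inheritParams simulate_droplet_counts
#' @param truth a [truth_params()].
#' @param design an [experiment_design()].
#' @param seed RNG seed.
#' @return list with `monoplex`, `duplex`, `conc` (the true concentrations),
#'   `truth` and `design`.
#' @export
simulate_experiment <- function(truth = truth_params(),
                                design = experiment_design(), seed = 1) {
  conc <- simulate_true_concentrations(truth, design, seed)
  counts <- simulate_droplet_counts(conc, truth, design, seed)
  c(counts, list(conc = conc, truth = truth, design = design))
}

#' Write a synthetic fixture to disk
#'
#' Writes a single long-format CSV of all wells (monoplex, duplex, No-RT,
#' control carboy, baseline rows) plus a JSON file of the generating truth.
#' Byte-identical for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param truth a [truth_params()].
#' @param design an [experiment_design()].
#' @return invisibly, list with paths `wells` and `truth` and the simulated
#'   tables.
#' @export
generate_fixture <- function(dir = tempfile("fixture"), seed = 1,
                             truth = truth_params(),
                             design = experiment_design()) {
  sim <- simulate_experiment(truth, design, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mono <- sim$monoplex
  mono$assay <- "monoplex"
  mono$n_both <- mono$n_a_only <- mono$n_b_only <- mono$n_neither <- NA
  dup <- sim$duplex
  if (!is.null(dup)) {
    dup$assay <- "duplex"
    dup$droplets_positive <- NA
  }
  cols <- c("sample_id", "assay", "marker", "component", "carboy",
            "time_nominal_h", "time_actual_h", "tech_rep", "pore_size_um",
            "droplets_total", "droplets_positive", "n_both", "n_a_only",
            "n_b_only", "n_neither", "filt_vol_L", "dilution_d", "baseline")
  wells <- rbind(mono[cols], if (!is.null(dup)) dup[cols])
  wells_path <- file.path(dir, "ddpcr_wells.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(wells, wells_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = seed, components = truth$components,
         carboy_sd = truth$carboy_sd, nort_rate = truth$nort_rate,
         jitter_h = truth$jitter_h,
         pore_allocation = as.list(truth$pore_allocation)),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(wells = wells_path, truth = truth_path,
                 monoplex = sim$monoplex, duplex = sim$duplex,
                 conc = sim$conc))
}
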