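# Readers, validation, configuration and the end-to-end pipeline.

canonical_cols <- c("sample_id", "assay", "marker", "component", "carboy",
                    "time_nominal_h", "time_actual_h", "tech_rep",
                    "pore_size_um", "droplets_total", "droplets_positive",
                    "n_both", "n_a_only", "n_b_only", "n_neither",
                    "filt_vol_L", "dilution_d", "baseline")

#' Read and validate a long-format ddPCR well table
#'
#' One row per well. Monoplex wells carry `droplets_positive`; duplex wells
#' carry the four category counts `n_both`, `n_a_only`, `n_b_only`,
#' `n_neither` (their sum must equal `droplets_total`). An `assay` column
#' (`monoplex` / `duplex`) or, failing that, non-missing category counts
#' decide the routing. Validation rejects rows violating count invariants
#' (with row numbers) and reports warnings (control-carboy positives, missing
#' volume metadata filled from defaults).
#'
#' @param path CSV file path.
#' @param mapping optional named character vector renaming file columns to
#'   the canonical schema, e.g. `c(pos_droplets = "droplets_positive")`.
#' @param control_carboy carboy index of the negative control (default 4).
#' @return object of class `ddpcr_tables`: `monoplex`, `duplex`,
#'   `validation` (list of `errors` and `warnings`).
#' @export
read_ddpcr_table <- function(path, mapping = NULL, control_carboy = 4) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    hit <- names(df) %in% names(mapping)
    names(df)[hit] <- unname(mapping[names(df)[hit]])
  }
  required <- c("marker", "component", "carboy", "time_nominal_h",
                "tech_rep", "droplets_total")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("input schema mismatch; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"time_actual_h" %in% names(df)) df$time_actual_h <- df$time_nominal_h
  if (!"baseline" %in% names(df)) df$baseline <- df$time_nominal_h < 0
  if (!"assay" %in% names(df))
    df$assay <- ifelse(!is.na(df$n_both %||% NA), "duplex", "monoplex")

  errors <- character(0)
  warns <- character(0)
  row_ids <- seq_len(nrow(df))
  is_dup <- df$assay == "duplex"

  if (any(!is_dup)) {
    m <- df[!is_dup, ]
    bad <- which(is.na(m$droplets_positive) | m$droplets_positive < 0 |
                   m$droplets_positive > m$droplets_total)
    if (length(bad))
      errors <- c(errors, paste0("monoplex row ", row_ids[!is_dup][bad],
                                 ": droplets_positive outside [0, droplets_total]"))
  }
  if (any(is_dup)) {
    d <- df[is_dup, ]
    cats <- c("n_both", "n_a_only", "n_b_only", "n_neither")
    miss_cat <- setdiff(cats, names(d))
    if (length(miss_cat)) {
      errors <- c(errors, paste("duplex rows lack columns:",
                                paste(miss_cat, collapse = ", ")))
    } else {
      tot <- d$n_both + d$n_a_only + d$n_b_only + d$n_neither
      bad <- which(is.na(tot) | tot != d$droplets_total |
                     d$n_both < 0 | d$n_a_only < 0 | d$n_b_only < 0 |
                     d$n_neither < 0)
      if (length(bad))
        errors <- c(errors, paste0("duplex row ", row_ids[is_dup][bad],
                                   ": category counts do not sum to droplets_total"))
    }
  }
  bad_tot <- which(is.na(df$droplets_total) | df$droplets_total <= 0)
  if (length(bad_tot))
    errors <- c(errors, paste0("row ", bad_tot, ": droplets_total must be > 0"))
  if (length(errors))
    stop("input validation failed:\n  ",
         paste(utils::head(errors, 20), collapse = "\n  "), call. = FALSE)

  for (vcol in c("filt_vol_L", "dilution_d")) {
    if (!vcol %in% names(df)) {
      df[[vcol]] <- NA_real_
      warns <- c(warns, paste("column", vcol, "absent; volume-chain defaults used"))
    } else if (anyNA(df[[vcol]])) {
      warns <- c(warns, paste0(sum(is.na(df[[vcol]])), " wells missing ",
                               vcol, "; defaults used"))
    }
  }
  ctl <- df$carboy == control_carboy
  if (any(ctl)) {
    pos <- sum(df$droplets_positive[ctl & !is_dup], na.rm = TRUE) +
      sum((df$n_both + df$n_a_only + df$n_b_only)[ctl & is_dup], na.rm = TRUE)
    if (pos > 0)
      warns <- c(warns, paste0("control carboy ", control_carboy, " shows ",
                               pos, " positive droplets"))
  }
  structure(list(monoplex = df[!is_dup, setdiff(names(df), c("n_both",
                   "n_a_only", "n_b_only", "n_neither"))],
                 duplex = if (any(is_dup)) df[is_dup, setdiff(names(df),
                   "droplets_positive")] else NULL,
                 validation = list(errors = errors, warnings = warns,
                                   n_rows = nrow(df))),
            class = "ddpcr_tables")
}

#' @export
print.ddpcr_tables <- function(x, ...) {
  cat("ddPCR well tables:", nrow(x$monoplex), "monoplex rows,",
      if (is.null(x$duplex)) 0 else nrow(x$duplex), "duplex rows\n")
  if (length(x$validation$warnings))
    cat("warnings:\n ", paste(x$validation$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Per-sample concentration table with intervals
#'
#' Point concentrations (copies/L) for every monoplex well from the exact
#' binomial occupancy interval pushed through the volume chain; saturated
#' wells are flagged and carry an infinite upper point estimate.
#'
#' @param tables a `ddpcr_tables` object or monoplex data frame.
#' @param chain default [volume_chain()] for wells without overrides.
#' @return tidy data frame with `conc`, `conc_low`, `conc_high`, `saturated`.
#' @export
concentration_table <- function(tables, chain = volume_chain()) {
  m <- if (inherits(tables, "ddpcr_tables")) tables$monoplex else tables
  occ <- estimate_occupancy(m$droplets_positive, m$droplets_total)
  k <- well_factor(m, chain)
  out <- m[intersect(canonical_cols, names(m))]
  out$conc <- occ$mu / k
  out$conc_low <- occ$mu_low / k
  out$conc_high <- occ$mu_high / k
  out$saturated <- occ$saturated
  out
}

# tiny stable config fingerprint (polynomial rolling hash of the deparse)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

default_config <- function() {
  list(input = NULL, output_dir = NULL, models = c("biphasic", "single_exp"),
       priors = list(), mcmc = list(), seed = 1,
       thresholds = list(rhat = 1.005, ess = 500, pore_screen = 0.95),
       control_carboy = 4, include_baseline = FALSE, pore_size_um = 5,
       clock = list(grid_max = 24, grid_step = 0.5))
}

#' Run the full analysis pipeline
#'
#' Stages: read and validate the well CSV; subtract No-RT controls from eRNA
#' wells; screen the pore-size fractions (when several are present) and
#' restrict to the dominant one; assemble the model dataset; fit every model
#' in the menu; compare them by PSIS-LOO (when more than one); summarize the
#' biphasic (or best) fit; compute the two built-in molecular clocks when
#' their components are present; write all outputs.
#'
#' @param config a configuration list or the path to a YAML file. Recognised
#'   entries: `input` (CSV path, required), `output_dir` (required),
#'   `models`, `priors`, `mcmc`, `seed`, `thresholds`, `control_carboy`,
#'   `include_baseline`, `pore_size_um`, `clock`.
#' @return invisibly, list with `summary`, `fits`, `loo`, `clocks`,
#'   `diagnostics`, `status` (0 = converged, 1 = convergence failure) and
#'   output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$input) || is.null(cfg$output_dir))
    stop("config must provide 'input' and 'output_dir'", call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("stage %-10s done in %.1f s", name,
        as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  say("run config hash %s, seed %d", hash, cfg$seed)
  tables <- stage("read", read_ddpcr_table(cfg$input,
                                           control_carboy = cfg$control_carboy))
  for (w in tables$validation$warnings) say("validation: %s", w)

  mono <- stage("no_rt", apply_no_rt_subtraction(tables$monoplex))
  nlog <- attr(mono, "no_rt_log")
  if (!is.null(nlog) && nrow(nlog))
    say("No-RT subtraction adjusted %d wells", nrow(nlog))

  # pore-size screen on the earliest timepoint of the reference marker
  screen <- NULL
  if (length(unique(mono$pore_size_um %||% cfg$pore_size_um)) > 1) {
    first_tp <- min(mono$time_nominal_h[mono$time_nominal_h >= 0])
    sc <- mono[mono$time_nominal_h == first_tp & mono$component == "eDNA" &
                 mono$carboy != cfg$control_carboy, ]
    multi <- names(which(tapply(sc$pore_size_um, sc$marker,
                                function(p) length(unique(p))) > 1))
    sc <- sc[sc$marker %in% multi, ]
    ct <- concentration_table(sc)
    screen <- size_fraction_profile(ct$pore_size_um, ct$conc,
                                    threshold = cfg$thresholds$pore_screen)
    say("pore screen: %s", screen$verdict)
    if (screen$passes_screen) cfg$pore_size_um <- screen$dominant
  }

  dataset <- stage("dataset", build_dataset(
    mono, tables$duplex, control_carboy = cfg$control_carboy,
    include_baseline = cfg$include_baseline,
    pore_size_um = cfg$pore_size_um))
  say("dataset: %d monoplex wells, %d duplex wells, components %s",
      if (is.null(dataset$monoplex)) 0 else nrow(dataset$monoplex),
      if (is.null(dataset$duplex)) 0 else nrow(dataset$duplex),
      paste(dataset$components$comp, collapse = ", "))

  priors <- do.call(prior_config, cfg$priors)
  mcmc <- do.call(mcmc_control, cfg$mcmc)
  fits <- list()
  for (mid in cfg$models)
    fits[[mid]] <- stage(mid, decay_fit(dataset, model = mid, priors = priors,
                                        mcmc = mcmc, seed = cfg$seed))

  loo_tab <- NULL
  if (length(fits) > 1) {
    loo_tab <- stage("loo", compare_models_loo(fits))
  } else {
    say("single-model menu: skipping LOO comparison")
  }

  main <- fits[[if ("biphasic" %in% names(fits)) "biphasic" else 1L]]
  fit_summary <- summary(main)
  diag <- convergence_diagnostics(main, cfg$thresholds$rhat,
                                  cfg$thresholds$ess)
  status <- if (attr(diag, "pass")) 0L else 1L
  if (status != 0L) say("WARNING: convergence diagnostics failed")

  clocks <- list()
  have <- main$components$comp[main$components$effective_model != "none"]
  grid <- seq(0, cfg$clock$grid_max, by = cfg$clock$grid_step)
  for (spec in list(clock_bridge_cytb(), clock_rna_fraction())) {
    need <- unique(c(spec$numerator, spec$denominator))
    if (all(need %in% have)) {
      traj <- ratio_trajectory(main, spec, grid = grid)
      clocks[[spec$label]] <- list(trajectory = traj,
                                   slope = clock_slope(traj))
      say("clock %s: slope %.5f / h", spec$label,
          clocks[[spec$label]]$slope$slope)
    }
  }

  paths <- list(
    fit_summary = file.path(cfg$output_dir, "fit_summary.csv"),
    diagnostics = file.path(cfg$output_dir, "diagnostics.json"),
    log = file.path(cfg$output_dir, "run_log.txt"))
  fs <- fit_summary
  class(fs) <- "data.frame"
  fs$config_hash <- hash
  fs$seed <- cfg$seed
  utils::write.csv(fs, paths$fit_summary, row.names = FALSE)
  if (!is.null(loo_tab)) {
    paths$loo <- file.path(cfg$output_dir, "loo.csv")
    lt <- loo_tab
    class(lt) <- "data.frame"
    lt$config_hash <- hash
    utils::write.csv(lt, paths$loo, row.names = FALSE)
  }
  for (lbl in names(clocks)) {
    fn <- file.path(cfg$output_dir,
                    paste0("clock_", gsub("[^A-Za-z0-9]+", "_", lbl), ".csv"))
    paths[[paste0("clock_", lbl)]] <- fn
    tr <- clocks[[lbl]]$trajectory
    class(tr) <- "data.frame"
    utils::write.csv(tr, fn, row.names = FALSE)
  }
  jsonlite::write_json(list(
    config_hash = hash, seed = cfg$seed, status = status,
    max_rhat = max(diag$rhat), min_ess = min(diag$ess_bulk),
    thresholds = cfg$thresholds,
    pore_screen = if (!is.null(screen))
      list(dominant = screen$dominant, fraction = screen$dominant_fraction,
           passes = screen$passes_screen),
    clock_slopes = lapply(clocks, function(cl) cl$slope$slope)),
    paths$diagnostics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, paths$log)

  invisible(list(summary = fit_summary, fits = fits, loo = loo_tab,
                 clocks = clocks, diagnostics = diag, screen = screen,
                 status = status, config = cfg, paths = paths))
}
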