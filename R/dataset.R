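# Assembly of validated well tables into the structure the sampler consumes.

mono_required <- c("marker", "component", "carboy", "time_nominal_h",
                   "time_actual_h", "tech_rep", "droplets_total",
                   "droplets_positive")
duplex_required <- c("carboy", "time_nominal_h", "time_actual_h", "tech_rep",
                     "droplets_total", "n_both", "n_a_only", "n_b_only",
                     "n_neither")

comp_key <- function(marker, component) paste(marker, component, sep = "_")

# per-well factor mapping copies/L to per-droplet mean copies
well_factor <- function(df, chain) {
  filt <- if ("filt_vol_L" %in% names(df)) df$filt_vol_L else chain$filt_vol
  d <- if ("dilution_d" %in% names(df)) df$dilution_d else chain$dilution_d
  filt[is.na(filt)] <- chain$filt_vol
  d[is.na(d)] <- chain$dilution_d
  (chain$dvol * chain$tvol * filt) / (chain$rvol * chain$evol * d)
}

#' Subtract paired No-RT controls from eRNA wells of a droplet table
#'
#' Pairs every eRNA well (components `emRNA`, `erRNA`) with the No-RT control
#' well of the same marker, carboy, timepoint and technical replicate, and
#' subtracts the control's positive-droplet count (floored at zero). No-RT
#' rows are removed from the returned table.
#'
#' @param monoplex monoplex well table (see [read_ddpcr_table()]).
#' @return the table with adjusted eRNA counts; attribute `"no_rt_log"` lists
#'   each adjusted well.
#' @export
apply_no_rt_subtraction <- function(monoplex) {
  is_nort <- monoplex$component == "NoRT"
  nort <- monoplex[is_nort, ]
  out <- monoplex[!is_nort, ]
  is_rna <- out$component %in% c("emRNA", "erRNA")
  if (!any(is_rna)) {
    attr(out, "no_rt_log") <- data.frame()
    return(out)
  }
  keys <- function(d) paste(d$marker, d$carboy, d$time_nominal_h, d$tech_rep,
                            d$pore_size_um %||% 5)
  rna_keys <- keys(out[is_rna, ])
  idx <- match(rna_keys, keys(nort))
  if (anyNA(idx)) {
    missing <- out[is_rna, ][is.na(idx), ]
    stop("eRNA wells without a paired No-RT control: ",
         paste(utils::head(missing$sample_id %||% rna_keys[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  }
  w <- subtract_no_rt(out$droplets_positive[is_rna],
                      nort$droplets_positive[idx])
  log <- data.frame(sample_id = out$sample_id[is_rna] %||% rna_keys,
                    W_before = out$droplets_positive[is_rna],
                    W_nort = nort$droplets_positive[idx],
                    W_after = as.numeric(w))
  out$droplets_positive[is_rna] <- as.numeric(w)
  attr(out, "no_rt_log") <- log[log$W_nort > 0, ]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a model dataset from validated well tables
#'
#' Groups wells by marker-component, excludes the control carboy from decay
#' fitting (validating that it carries no signal), drops pre-transport
#' baseline rows unless requested, restricts to one filter pore size, and
#' precomputes the per-well volume-chain factor. No-RT subtraction is assumed
#' to have been applied already (see [apply_no_rt_subtraction()]).
#'
#' @param monoplex monoplex well table; `NULL` if none.
#' @param duplex duplex well table (four category counts); `NULL` if none.
#' @param chain default [volume_chain()]; per-well `filt_vol_L` and
#'   `dilution_d` columns override its entries.
#' @param control_carboy carboy index of the negative control (default 4).
#' @param include_baseline keep rows with negative nominal time (pre-transport
#'   baseline)? Default `FALSE`; when kept, their (negative) actual times
#'   enter the decay fit, anchoring extrapolation before chamber time zero.
#' @param pore_size_um restrict to this pore size when a `pore_size_um`
#'   column is present (default 5).
#' @param duplex_markers names of the two duplex loci and the linked class.
#' @return object of class `model_dataset`.
#' @export
build_dataset <- function(monoplex = NULL, duplex = NULL,
                          chain = volume_chain(), control_carboy = 4,
                          include_baseline = FALSE, pore_size_um = 5,
                          duplex_markers = c(a = "16S", b = "Dloop",
                                             linked = "Bridge")) {
  if (inherits(monoplex, "ddpcr_tables")) {
    duplex <- monoplex$duplex
    monoplex <- monoplex$monoplex
  }
  if (is.null(monoplex) && is.null(duplex))
    stop("at least one of monoplex/duplex tables is required", call. = FALSE)

  prep <- function(df, required) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
    if (!"pore_size_um" %in% names(df)) df$pore_size_um <- pore_size_um
    df <- df[df$pore_size_um == pore_size_um, ]
    if (!include_baseline) df <- df[df$time_nominal_h >= 0, ]
    df
  }
  monoplex <- prep(monoplex, mono_required)
  duplex <- prep(duplex, duplex_required)

  # control carboy: excluded from fitting, checked for signal
  control_positives <- 0
  strip_control <- function(df, pos) {
    if (is.null(df)) return(list(df = NULL, pos = 0))
    ctl <- df$carboy == control_carboy
    list(df = df[!ctl, ], pos = sum(pos(df[ctl, , drop = FALSE])))
  }
  m <- strip_control(monoplex, function(d) sum(d$droplets_positive))
  d <- strip_control(duplex, function(d) sum(d$n_both + d$n_a_only + d$n_b_only))
  control_positives <- m$pos + d$pos
  if (control_positives > 0)
    warning("control carboy ", control_carboy, " shows ", control_positives,
            " positive droplets; possible cross-contamination", call. = FALSE)
  monoplex <- m$df
  duplex <- d$df

  carboys <- sort(unique(c(monoplex$carboy, duplex$carboy)))
  if (!length(carboys)) stop("no wells left after filtering", call. = FALSE)

  comps <- data.frame(comp = character(), marker = character(),
                      component = character(), type = character(),
                      duplex_role = character(), stringsAsFactors = FALSE)
  if (!is.null(monoplex) && nrow(monoplex)) {
    monoplex <- monoplex[monoplex$component != "NoRT", ]
    monoplex$comp <- comp_key(monoplex$marker, monoplex$component)
    monoplex$cb <- match(monoplex$carboy, carboys)
    monoplex$k <- well_factor(monoplex, chain)
    u <- unique(monoplex[c("comp", "marker", "component")])
    comps <- rbind(comps, data.frame(u, type = "monoplex",
                                     duplex_role = NA_character_))
  }
  if (!is.null(duplex) && nrow(duplex)) {
    duplex$cb <- match(duplex$carboy, carboys)
    duplex$k <- well_factor(duplex, chain)
    bad <- with(duplex, n_both + n_a_only + n_b_only + n_neither != droplets_total)
    if (any(bad))
      stop("duplex category counts do not sum to droplets_total in rows: ",
           paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
    comps <- rbind(comps, data.frame(
      comp = comp_key(c(duplex_markers[["a"]], duplex_markers[["b"]],
                        duplex_markers[["linked"]]), "eDNA"),
      marker = unname(duplex_markers),
      component = "eDNA", type = "duplex",
      duplex_role = c("a_free", "b_free", "linked")))
  }
  rownames(comps) <- NULL
  structure(list(monoplex = monoplex, duplex = duplex, components = comps,
                 carboys = carboys, chain = chain,
                 control_carboy = control_carboy,
                 control_positives = control_positives,
                 include_baseline = include_baseline,
                 pore_size_um = pore_size_um),
            class = "model_dataset")
}

#' @export
print.model_dataset <- function(x, ...) {
  nm <- if (is.null(x$monoplex)) 0 else nrow(x$monoplex)
  nd <- if (is.null(x$duplex)) 0 else nrow(x$duplex)
  cat("ddPCR model dataset:", nm, "monoplex wells,", nd, "duplex wells,",
      length(x$carboys), "carboys\n")
  cat("components:", paste(x$components$comp, collapse = ", "), "\n")
  if (x$control_positives > 0)
    cat("WARNING: control carboy carries", x$control_positives, "positive droplets\n")
  invisible(x)
}

# per-component detection pattern over nominal timepoints; used by the
# identifiability rule (a component whose only detections are at its first
# detected timepoint cannot inform a changepoint or second-phase rate)
detection_table <- function(dataset) {
  out <- list()
  m <- dataset$monoplex
  if (!is.null(m) && nrow(m)) {
    for (cp in unique(m$comp)) {
      d <- m[m$comp == cp, ]
      det <- tapply(d$droplets_positive > 0, d$time_nominal_h, any)
      out[[cp]] <- sort(as.numeric(names(det))[det])
    }
  }
  d <- dataset$duplex
  if (!is.null(d) && nrow(d)) {
    cc <- dataset$components[dataset$components$type == "duplex", ]
    sig <- list(
      a_free = d$n_both + d$n_a_only > 0,
      b_free = d$n_both + d$n_b_only > 0,
      linked = vapply(seq_len(nrow(d)), function(i)
        expected_double_positives(d$n_both[i], d$n_a_only[i], d$n_b_only[i],
                                  d$n_neither[i])$excess > 0, TRUE))
    for (i in seq_len(nrow(cc))) {
      det <- tapply(sig[[cc$duplex_role[i]]], d$time_nominal_h, any)
      out[[cc$comp[i]]] <- sort(as.numeric(names(det))[det])
    }
  }
  out
}
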