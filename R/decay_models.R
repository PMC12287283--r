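#' Biphasic decay parameters
#'
#' Container for the two-phase exponential decay model: concentration falls
#' from `C0` at rate `lambda1` (per hour) until the transition time `t_x`,
#' then at rate `lambda2`. The curve is continuous at the changepoint.
#'
#' @param C0 initial concentration at t = 0, copies/L (> 0).
#' @param lambda1 first-phase decay rate, 1/h (>= 0).
#' @param lambda2 second-phase decay rate, 1/h (>= 0).
#' @param t_x transition time, h (> 0).
#' @return object of class `biphasic_params`.
#' @export
biphasic_params <- function(C0, lambda1, lambda2, t_x) {
  if (!is.numeric(C0) || C0 <= 0) stop("C0 must be > 0", call. = FALSE)
  if (lambda1 < 0 || lambda2 < 0) stop("decay rates must be >= 0", call. = FALSE)
  if (t_x <= 0) stop("transition time t_x must be > 0", call. = FALSE)
  structure(list(C0 = C0, lambda1 = lambda1, lambda2 = lambda2, t_x = t_x),
            class = "biphasic_params")
}

#' Biphasic exponential concentration curve
#'
#' \deqn{C(t) = C_0 e^{-\lambda_1 t} \quad (t < t_x), \qquad
#'       C(t) = C_0 e^{-\lambda_1 t_x} e^{-\lambda_2 (t - t_x)} \quad (t \ge t_x).}
#'
#' @param params a [biphasic_params()] object (or plain list with the same
#'   fields).
#' @param t times in hours (>= 0), vectorised.
#' @return concentrations, copies/L.
#' @export
biphasic_concentration <- function(params, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  with(params, C0 * exp(-lambda1 * pmin(t, t_x) - lambda2 * pmax(t - t_x, 0)))
}

# ---- candidate decay-model menu -------------------------------------------
#
# Each entry is a closed-form survival-type curve C(t); all are non-increasing
# in t for non-negative rate/shape parameters. The `jags` element gives the
# log-concentration expression used inside the MCMC model templates ("LC0",
# "T" are placeholders for the component's log-C0 node and the time variable),
# and `jags_priors` the matching prior block; parameters other than C0 are
# scalars shared across carboys within a component.

model_menu <- list(
  single_exp = list(
    pars = c("lambda1"),
    eval = function(p, t) p$C0 * exp(-p$lambda1 * t),
    jags = "LC0 - l1%S% * T",
    jags_priors = "l1%S% ~ dnorm(0, prec_lam) T(0,)\n"
  ),
  biphasic = list(
    pars = c("lambda1", "lambda2", "t_x"),
    eval = function(p, t) biphasic_concentration(p, t),
    jags = "LC0 - l1%S% * min(T, tx%S%) - l2%S% * max(T - tx%S%, 0)",
    jags_priors = paste0(
      "l1%S% ~ dnorm(0, prec_lam) T(0,)\n",
      "l2%S% ~ dnorm(0, prec_lam) T(0,%ORD%)\n",
      "tx%S% ~ dunif(tx_lo, tx_hi)\n")
  ),
  exp_plateau = list(
    # exponential decay toward a persistent residual fraction of C0
    pars = c("lambda1", "resid_frac"),
    eval = function(p, t) p$C0 * (p$resid_frac + (1 - p$resid_frac) * exp(-p$lambda1 * t)),
    jags = "LC0 + log(fr%S% + (1 - fr%S%) * exp(-l1%S% * T))",
    jags_priors = paste0(
      "l1%S% ~ dnorm(0, prec_lam) T(0,)\n",
      "fr%S% ~ dbeta(1, 9)\n")
  ),
  weibull = list(
    # stretched exponential: shape < 1 gives a fast start and heavy tail
    pars = c("lambda1", "shape"),
    eval = function(p, t) p$C0 * exp(-(p$lambda1 * t)^p$shape),
    jags = "LC0 - pow(l1%S% * T + 1.0E-12, k%S%)",
    jags_priors = paste0(
      "l1%S% ~ dnorm(0, prec_lam) T(0,)\n",
      "k%S% ~ dlnorm(0, 4)\n")
  ),
  power_law = list(
    # Hill-type algebraic tail
    pars = c("alpha", "tau"),
    eval = function(p, t) p$C0 * (1 + t / p$tau)^(-p$alpha),
    jags = "LC0 - a%S% * log(1 + T / tau%S%)",
    jags_priors = paste0(
      "a%S% ~ dnorm(0, 0.04) T(0,)\n",
      "tau%S% ~ dlnorm(log(24), 1)\n")
  ),
  double_exp = list(
    # mixture of two exponential sub-pools
    pars = c("lambda1", "lambda2", "weight"),
    eval = function(p, t) p$C0 * (p$weight * exp(-p$lambda1 * t) +
                                    (1 - p$weight) * exp(-p$lambda2 * t)),
    jags = "LC0 + log(wgt%S% * exp(-l1%S% * T) + (1 - wgt%S%) * exp(-l2%S% * T))",
    jags_priors = paste0(
      "l1%S% ~ dnorm(0, prec_lam) T(0,)\n",
      "l2%S% ~ dnorm(0, prec_lam) T(0,)\n",
      "wgt%S% ~ dbeta(1, 1)\n")
  )
)

#' Candidate decay-model specification
#'
#' Returns the closed-form specification of one member of the decay-model
#' menu: single exponential, biphasic exponential (changepoint), exponential
#' decay to a plateau, Weibull (stretched exponential), power-law tail, and a
#' double-exponential mixture. All evaluate to a positive, non-increasing
#' concentration for non-negative rate parameters.
#'
#' @param model_id one of `"single_exp"`, `"biphasic"`, `"exp_plateau"`,
#'   `"weibull"`, `"power_law"`, `"double_exp"`.
#' @return object of class `decay_model_spec` with elements `model_id`,
#'   `pars` (parameter names beyond `C0`) and `eval(params, t)`.
#' @export
decay_model <- function(model_id) {
  if (!model_id %in% names(model_menu))
    stop("unknown decay model '", model_id, "'; available: ",
         paste(names(model_menu), collapse = ", "), call. = FALSE)
  m <- model_menu[[model_id]]
  structure(list(model_id = model_id, pars = m$pars, eval = m$eval),
            class = "decay_model_spec")
}

#' Evaluate a candidate decay model
#'
#' @param spec a [decay_model()] specification or a model id string.
#' @param params named list with `C0` and the model's parameters.
#' @param t times in hours (>= 0), vectorised.
#' @return concentrations, copies/L.
#' @export
evaluate_model <- function(spec, params, t) {
  if (is.character(spec)) spec <- decay_model(spec)
  stopifnot(inherits(spec, "decay_model_spec"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  missing <- setdiff(c("C0", spec$pars), names(params))
  if (length(missing))
    stop("missing parameters for model '", spec$model_id, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  spec$eval(params, t)
}
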