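---
title: "Models and methods for ddPCR-based eNA decay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for ddPCR-based eNA decay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
droplet-level observation model, the decay-curve family, the duplex linkage
estimators, priors and identifiability rules, model comparison, what the
synthetic generator does and does not emulate, and the numerical choices
that matter.

## Observation model: from droplets to concentrations

A ddPCR well partitions a reaction into `U` droplets (around 20,000).
Target molecules distribute over droplets at random, so the copy number in
one droplet is Poisson with mean `omega` and a droplet is positive with
probability `p = 1 - exp(-omega)`; equivalently `cloglog(p) = ln(omega)`.
The positive-droplet count is binomial,

    W ~ Binomial(U, 1 - exp(-omega)),

and this binomial likelihood — not a plug-in point estimate — is what the
sampler sees for every monoplex well, so wells with very few (or very many)
positives contribute exactly the information they carry. Saturated wells
(`W = U`) have no finite point estimate of `omega`; they stay in the
likelihood, which is well behaved as `p -> 1`, but are flagged and excluded
from point-estimate tables.

The volume chain converts per-droplet copies to copies per litre of sampled
water:

    C = omega * rvol * evol * d / (dvol * tvol * filt)

with reaction volume `rvol` (22 uL), droplet volume `dvol` (8.5e-4 uL),
template volume `tvol` (2 uL), elution volume `evol` (50 uL), filtered
volume `filt` (litres) and template dilution factor `d >= 1`. The chain is
implemented as this single dimensionally consistent product — each factor
enters on the side dimensional analysis dictates — and is verified in the
tests by a step-by-step unit-chain oracle and by an exact round-trip
identity (`C -> omega -> C` to 1e-10 relative). Doubling `d` doubles the
inferred `C`: a diluted template must have come from a richer extract.

Reverse transcription converts RNA to cDNA before quantification, so all
"eRNA" concentrations are conditional on 100% RT efficiency; this is a
known limitation, not a modelling choice. The residual-DNA ("No-RT")
control is subtracted at the droplet-count level, floored at zero, before
any fitting.

## Decay model family

The central model is the biphasic exponential with changepoint `t_x`:

    C(t) = C0 * exp(-lambda1 * t)                      t <  t_x
    C(t) = C(t_x) * exp(-lambda2 * (t - t_x))          t >= t_x

continuous at `t_x`, with `lambda1, lambda2` in 1/h. Time is the actual
filtration time of each sample; nominal timepoints are labels. The
pre-transport baseline sample (nominal −3 h) is stored with its negative
time and excluded from fits by default (`include_baseline = FALSE`),
because the transport period is not part of the controlled chamber
conditions; a switch re-includes it.

The candidate menu spans the standard possibilities for eNA decay: single
exponential (the usual null), biphasic exponential, exponential decay to a
plateau (a persistent bound fraction), Weibull / stretched exponential,
power-law (algebraic tail), and a double-exponential mixture (two pools
with distinct turnover). All are non-increasing for non-negative rate
parameters and all reduce to the single exponential in the appropriate
limit, which the tests assert. The menu is deliberately open: each entry is
a closed-form evaluator plus a matching sampler template, so adding a
candidate touches one table.

Within a marker-component, `C0` is carboy-specific while `lambda1`,
`lambda2` and `t_x` are shared across carboys: biological replicates see
the same water chemistry, so decay kinetics are common property while
initial loads are not.

## Duplex linkage ("Bridge") quantification

The duplex assay targets two loci that are physically linked on intact
mitochondrial DNA (minimum span 2746 bp). Three independent Poisson pools
load each droplet — free fragments of locus A, free fragments of locus B,
and linked molecules carrying both — giving the four category
probabilities in `duplex_category_probs()`. Two estimators are provided:

* the **closed form** `lambda_linked = ln q00 - ln qA - ln qB` (from the
  double-negative and single-locus-negative fractions), which inverts the
  category probabilities exactly and is the default; and
* the **subtraction heuristic** (observed double positives minus the count
  expected under independence, divided by `U`), retained because it is the
  transparent textbook calculation. It is accurate at low occupancy and
  biased low when wells are heavily loaded (at rates (0.5, 0.3, 0.2) per
  droplet it returns about 0.067 for a true 0.2); the tests document both
  regimes.

For inference the duplex wells enter the joint model as a four-category
multinomial parameterized by the three pools, each decaying under its own
curve, so Bridge decay rates carry droplet-level uncertainty exactly as the
monoplex components do. Negative closed-form estimates (sampling noise) are
floored at zero and flagged — concentrations are physical.

## Priors, sampling, identifiability

Priors (all overridable via `prior_config()`):

* `ln C0` per carboy: Normal, centred on a method-of-moments estimate from
  that carboy's earliest timepoint (a 0.5-droplet continuity correction
  keeps it finite), sd 3 — weakly informative about scale only;
* `lambda1`, `lambda2`: half-Normal(0, 1 /h) — decay rates of this
  magnitude span everything from minutes-scale RNA loss to week-scale DNA
  persistence;
* `t_x`: Uniform(12 h, 96 h), truncated above by the last observed time.
  The changepoint is only weakly identified when no samples fall between
  consecutive timepoints, so the posterior honestly widens there; no
  ordering `lambda2 < lambda1` is imposed (a biphasic shape must come from
  the data, not the prior), though `order_constraint = TRUE` is available.

Sampling uses JAGS (slice/Gibbs updates) with fixed per-chain seeds derived
from one user seed, 4 chains by default; `mcmc_control()` defaults to
1000 warmup + 2000 draws for interactive work and
`mcmc_control(warmup = 5000, iter = 10000)` is the full-scale setting used
by the acceptance script. The binomial changepoint model mixes well under
slice sampling — at full-scale settings the synthetic experiment fit
reaches maximum split R-hat about 1.001–1.002 and minimum bulk ESS in the
thousands — so a gradient-based sampler is not required for this likelihood.

Convergence is judged with rank-normalized split R-hat (including the
folded variant, so scale disagreements are caught) and rank-normalized bulk
ESS with Geyer initial-monotone truncation, implemented in the package and
cross-checked in the tests against `coda` estimators and an AR(1)
closed form. Thresholds default to R-hat < 1.005 and ESS > 500.

**Identifiability rule.** A component with no detections is not fitted; a
component whose detections stop after its first detected timepoint (one
detection, then zeros — the typical fate of messenger RNA) cannot inform a
changepoint, so it is reduced to a single-exponential fit and its `t_x` and
`lambda2` are reported `NA` with reason `single_detection`. The rule is
based on the detection pattern of the data, never on a posterior heuristic,
so it is reproducible before any sampling.

## Model comparison

`decay_loo()` computes pointwise log-likelihoods per well (binomial or
multinomial) on a thinned draw set (default about 4000 draws) and applies
Pareto-smoothed importance sampling: the largest importance ratios are
replaced by expected order statistics of a generalized Pareto distribution
fitted to the tail (profile-likelihood fit with a weak prior pulling the
shape toward 0.5), then normalized. The tail-shape diagnostic `k` is
reported; wells with `k > 0.7` are counted and printed. PSIS-LOO, R-hat and
ESS are implemented in-package from the published algorithms; the test
suite validates PSIS-LOO against an exact closed-form leave-one-out
predictive density in a conjugate normal model.

`compare_models_loo()` requires identical well sets, ranks models by
`elpd_loo`, and reports pairwise differences with standard errors. Two
cautions built into the tests: the difference SE is unstable when the
pointwise differences are near zero (ties are asserted over replicate
datasets with the |diff| < 4 practical-equivalence scale), and model
selection consistency is asserted as a frequency (biphasic chosen first in
at least 18 of 20 biphasic-generated datasets), not as a certainty.

## Molecular clocks

A clock is a ratio of a fast-decaying numerator to one or more slower
components. `ratio_trajectory()` evaluates the ratio **per posterior draw**
on a time grid (default 0–24 h in 0.5 h steps, per carboy) and only then
summarizes median and 95% interval — never a ratio of summaries, which
would be biased. Draws with a zero denominator are excluded and counted.
`clock_slope()` fits unweighted OLS to the pooled (carboys stacked)
posterior-median trajectory; the p-value is labelled heuristic because grid
points are autocorrelated by construction. The two built-in specs are the
long:short fragment ratio (Bridge over Cytb, numerator excluded from the
denominator; a flag switches to the bounded proportion) and the
ribosomal-RNA share of 16S nucleic acids. Because shedding magnitude
cancels, any common rescaling of concentrations leaves every ratio
unchanged (tested exactly). Turning ratios into explicit age estimates is
out of scope: under ongoing or multi-pulse shedding the inversion is
confounded.

## The synthetic mesocosm generator

`simulate_experiment()` emulates the study conditions end to end: 3
carboys plus a deionized-water control, timepoints 0, 4, 8, 12, 24, 48, 96,
140, 188 h plus a tagged −3 h baseline, 2 technical replicates, 20,000
droplets per well, 2 L filtered, the full volume chain, No-RT control wells
with Poisson(0.5) residual positives, and an optional 3-stage serial
filtration (5 / 1 / 0.45 um) of the short-fragment marker at the first
timepoint with allocation 96 / 2.5 / 1.5%.

Default generating truth per component (rate in 1/h, changepoint in h):

| component    | C0 (copies/L) | lambda1 | t_x | lambda2 |
|--------------|---------------|---------|-----|---------|
| Cytb eDNA    | 1.0e6         | 0.114   | 41  | 0.026   |
| Cytb emRNA   | 200           | 1.615   | —   | (single phase) |
| 16S eDNA     | 1.5e5         | 0.165   | 33  | 0.028   |
| 16S erRNA    | 8.85e5        | 0.236   | 29  | 0.054   |
| Dloop eDNA   | 1.2e5         | 0.166   | 36  | 0.021   |
| Bridge eDNA  | 1.08e5        | 0.190   | 28  | 0.044   |

The decay parameters are the study conditions; the initial concentrations
are the package's own calibration, fixed once before any fitting: the
Bridge:Cytb concentration ratio at t = 0 (0.1082) and the ribosomal share
of 16S nucleic acids (0.8551) are solved in closed form from the phase-1
rates so that the two 0–24 h clock trajectories decline at −0.0036 and
−0.0142 per hour. The messenger-RNA C0 (200 copies/L) guarantees a strong
detection at t = 0 (about 35 expected positive droplets per well) and, with
its fast single-phase decay, near-certain non-detection afterwards — the
single-detection pattern the identifiability rule exists for.

Design choices worth stating explicitly:

* **Carboy multiplier shared across components.** Each carboy gets one
  lognormal C0 multiplier (sd 0.2 on the log scale) applied to all
  components, because all components ride in the same water parcel —
  fill-level and handling effects scale them jointly. This is also what
  makes ratio clocks comparable across carboys. A mis-specification mode
  (`carboy_specific_rates`) perturbs each carboy's rates for robustness
  studies.
* **Decay runs to the actual filtration time.** Actual times are nominal
  plus Uniform(0, 0.25 h) filtration jitter, and the true concentration is
  evaluated at the actual time — the inference consumes actual times, so
  generator and model agree about what "time" means.
* **eRNA dilution.** The RT reaction dilutes template; the generator uses
  `d = 2` for eRNA wells and records it per well, and the inference reads
  the recorded value, so the specific choice cancels in recovery. Absolute
  eRNA concentrations inherit this convention.

What the generator does **not** emulate: PCR inhibition or amplification
efficiency, droplet "rain"/threshold calling (inputs are called counts),
plate effects, RT efficiency below 1, tank-wall adsorption, or
non-stationary water chemistry. Passing tests therefore demonstrate that
the inference machinery is correct and calibrated under its own assumptions
— not that those assumptions hold in any particular field sample.

## Numerical choices and problem sizes

* Droplet positivity is clamped to at most 1 − 1e−12 inside the sampler so
  a wandering chain cannot produce an exact zero likelihood; pointwise
  log-likelihoods for LOO use the unclamped binomial mass (verified against
  direct evaluation to 1e−10).
* All lambda estimates and the closed-form linkage estimates floor at 0
  with flags rather than going negative.
* Quantile summaries use type-7 quantiles of pooled chains; `t_x` is
  summarized by its posterior median (the marginal can be skewed within
  the sampling gap).
* Every stochastic step — generator, chain initialisation — derives from a
  single user seed; chain seeds are drawn once up front so adding a
  component does not reshuffle another component's chains.
* Test problem sizes: recovery and calibration runs use one monoplex marker
  (54 wells) with 2 chains × (400 warmup + 800 draws) or 50 replicates at
  2 × (300 + 600); model selection uses 20 + 10 replicate datasets; the
  convergence and study-condition checks run the full 216-well experiment
  at 4 × (5000 + 10,000). These sizes give Monte-Carlo margins comfortably
  inside the asserted tolerances.

## Known limitations

Absolute eRNA levels are conditional on RT efficiency 1; plate effects are
validated upstream but not modelled; the changepoint is prior-sensitive
wherever the sampling design leaves a gap (report intervals, not points);
clock p-values are descriptive; and the carryover-eDNA component enum value
exists for forward compatibility but no carryover analysis is implemented.
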