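# enadecay

Bayesian decay analysis of environmental nucleic acids (eNA) from droplet
digital PCR (ddPCR) well counts.

When an animal sheds DNA and RNA into water, the different molecular
components degrade at very different speeds: long DNA fragments and RNA
disappear within hours to days, short DNA fragments persist for a week or
more. Quantifying those decay rates — and the ratios of fast- to
slow-decaying components, which act as coarse "molecular clocks" for the age
of a detection — requires propagating uncertainty from the raw droplet
counts of the ddPCR instrument all the way to the decay-curve parameters.
`enadecay` implements that chain for mesocosm-style decay experiments
(replicate carboys sampled over a timecourse), for eDNA/eRNA researchers and
biostatisticians working with ddPCR timecourse data.

## The model

Each ddPCR well partitions a reaction into roughly 20,000 droplets. With
`W` positive droplets out of `U`, occupancy follows Poisson statistics:

```
W_irt ~ Binomial(U_irt, p_it),      cloglog(p_it) = ln(omega_it)
```

where `omega` is the mean copy number per droplet. The volume chain maps
`omega` to the concentration `C` (copies/L) in the sampled water:

```
C = omega * rvol * evol * d / (dvol * tvol * filt)
```

(reaction volume 22 uL, droplet volume ~0.85 nL, template 2 uL, elution
50 uL, filtered volume in litres, template dilution `d`). Decay of each
marker-component `i` is biphasic exponential with a changepoint:

```
C_i(t) = C0_i * exp(-lambda1_i * t)                          t <  tx_i
C_i(t) = C_i(tx_i) * exp(-lambda2_i * (t - tx_i))            t >= tx_i
```

with carboy-specific `C0` and shared rates, fitted jointly by MCMC against
the droplet-level likelihood. Duplex wells (two loci on the same
mitochondrial genome) contribute a four-category multinomial whose
double-positive excess identifies intact "Bridge" molecules spanning both
loci (>= 2746 bp); their load has a closed-form estimator

```
lambda_linked = ln q00 - ln qA - ln qB
```

from the fractions of double-negative (`q00`) and single-locus-negative
(`qA`, `qB`) droplets. Candidate decay curves (single exponential, biphasic,
plateau, Weibull, power-law, double exponential) are compared by
Pareto-smoothed importance-sampling leave-one-out cross-validation
(PSIS-LOO); convergence is judged by rank-normalized split R-hat and bulk
effective sample size.

## Worked example

Simulate the default mesocosm experiment (3 seawater carboys + a control,
9 timepoints over 188 h, 2 technical replicates, 6 marker-components), fit
the biphasic model, and summarize:

```r
library(enadecay)

fx   <- generate_fixture(tempdir(), seed = 1)          # wells CSV + truth JSON
tabs <- read_ddpcr_table(fx$wells)                     # validated well tables
mono <- apply_no_rt_subtraction(tabs$monoplex)         # No-RT carryover control
ds   <- build_dataset(mono, tabs$duplex)

fit <- decay_fit(ds, model = "biphasic",
                 mcmc = mcmc_control(chains = 4, warmup = 1000, iter = 2000),
                 seed = 1)
summary(fit)
#> Posterior decay-rate summary (1/h; 95% credible intervals):
#>  marker component lambda1 lambda1_2.5 lambda1_97.5  t_x lambda2        na_reason
#>    Cytb      eDNA   0.114       0.114        0.115 40.6  0.0268               NA
#>    Cytb     emRNA   1.431       0.683        2.647   NA      NA single_detection
#>     16S     erRNA   0.237       0.235        0.238 29.0  0.0644               NA
#>     16S      eDNA   0.164       0.163        0.166 32.5  0.0260               NA
#>   Dloop      eDNA   0.167       0.165        0.168 37.5  0.0183               NA
#>  Bridge      eDNA   0.190       0.188        0.192 28.3  0.0424               NA
```

Each row is one eNA component: the first-phase decay rate `lambda1` (per
hour, with its 95% credible interval), the changepoint `t_x` (hours) and the
slower second-phase rate `lambda2`. The messenger-RNA component was detected
only at the first timepoint, so its changepoint and tail rate are
unidentifiable and reported `NA` by the detection-based rule. Convergence
and a molecular clock:

```r
convergence_diagnostics(fit, rhat_threshold = 1.01, ess_threshold = 400)
#> Convergence: max R-hat 1.0091 (< 1.010), min bulk ESS 578 (> 400) -> PASS

clock_slope(ratio_trajectory(fit, clock_rna_fraction()))
#> Clock erRNA:(erRNA+eDNA) 16S: slope -0.01455 per h (R2 0.991, heuristic p 7.2e-152)
```

(The strict defaults, R-hat < 1.005 and ESS > 500, are intended for
full-scale runs, `mcmc_control(warmup = 5000, iter = 10000)`.) The declining
ribosomal-RNA share of 16S nucleic acids — about 1.5 percentage points per
hour over the first day — is what makes the ratio usable as a coarse age
indicator. Duplex wells can also be inspected directly:

```r
estimate_linked_closed_form(2300, 4000, 1500, 12200)
#> Duplex linkage estimate (per-droplet mean copies):
#>   free A: 0.2836   free B: 0.116   linked: 0.09476
#>   double positives: 1197.0 expected under independence, excess 1103.0 (subtraction lambda 0.05515)
```

The whole chain (read, screen, fit, compare, clocks, outputs) is also
available as `run_pipeline(config)` with a YAML or list configuration.

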