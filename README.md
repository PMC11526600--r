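# seqphase2

Bayesian sequential monitoring designs for single-arm phase II oncology
trials, with a Monte Carlo engine for their operating characteristics.

## The problem

Phase II trials of immunotherapy combinations face long efficacy windows
(objective response within 180 days) next to short toxicity windows
(unacceptable toxicity within 42 days) and brisk accrual (about one
patient every 6 days). Waiting for complete data at every interim look
forces accrual suspensions and long trials; analysing only complete
observations throws information away. This package is for biostatisticians
planning such trials: it implements five candidate monitoring strategies
for a 90-patient study whose efficacy is assessed in the biomarker-negative
majority (81 of 90 expected) and whose toxicity is assessed in everyone,
and simulates their frequentist behaviour under correlated
efficacy/toxicity scenarios.

## The designs

All rules are conjugate-Bayesian. With a Beta prior and data `D_n` at a
look with `n` of `N` patients, futility stops when
`Pr(p_eff <= phi | D_n) > C_n` and toxicity monitoring stops when
`Pr(p_tox > phi_tox | D_n)` exceeds a fixed 0.95 (stand-alone rule,
cutoff 0.25) or the same adaptive threshold (joint designs, cutoff 0.30),
where

```
C_n = 1 - lambda * (n / N)^gamma .
```

The time-to-event variant (TOP) analyses at the moment of enrollment,
weighting each pending patient by the elapsed fraction of their window, so
accrual never stops; binary designs (Simon's two-stage, BOP2) suspend
accrual until all windows complete. The five comparison designs —
`top_pp`, `simon_pp`, `bop_pp`, `top_joint`, `itop_joint` (joint TOP with
an informative toxicity prior borrowed from biomarker-positive patients) —
ship with the calibrated hyperparameters of the underlying design study;
an efficacy-only `top_eff` variant is included.

## Worked example

```r
library(seqphase2)

# the alternative-hypothesis scenario at the "slight positive" correlation
sc <- outcome_scenario(0.30, 0.20, "pos1")
#> Outcome scenario
#>   p_eff = 0.300, p_tox = 0.200, r = 0.255
#>   joint cells: pi11 = 0.1067, pi10 = 0.1933, pi01 = 0.0933, pi00 = 0.6067

design <- make_design("top_pp")
boundary_table(design)$efficacy
#>    n        cn min_resp_to_continue
#> 1 30 0.6496718                    4
#> 2 81 0.1350000                   17

operating_characteristics(design, sc, reps = 2000, seed = 1)
#> Operating characteristics: TOP_eff + PP_tox (2000 reps)
#>   scenario: p_eff = 0.30, p_tox = 0.20, r = 0.25
#>   positive: 87.65% (SE 0.74), early stop: 10.65%
#>   mean N: 83.3, mean duration: 654 days
```

Reading: under the alternative (30% response, 20% toxicity), the combined
design concludes "promising and acceptably safe" in about 88% of trials,
stops early in about 11% (mostly the toxicity rule), enrolls 83 patients
on average, and runs about 21 months. `simon_two_stage()` prints the
exact-binomial Simon boundaries used by `simon_pp` (stop stage 1 at <= 4
responders of 30; positive beyond 18 of 81; exact alpha 0.0274, power
0.9066, EN(p0) 54.3).

Full factorial studies run from a config file:

```r
run_from_config(system.file("extdata", "default_run.yaml",
                            package = "seqphase2"))
```

or from the thin CLI in `inst/cli/seqphase2.R`
(`boundaries | simulate | sweep | calibrate | report` subcommands).

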