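# msabm

An on-lattice, stochastic agent-based model of multiple sclerosis (MS)
lesion formation, built for exploring how disease-modifying therapies
(DMTs) and oligodendrocyte-targeted remyelination therapies shape the
course of demyelination.

## The model in brief

A 108 x 300 square lattice (10 µm spacing, 20-minute steps, 300 simulated
days) is split into peripheral blood, perivascular space (PVS) and a 3 mm²
strip of myelinated parenchyma. Primed T cells appear in the blood in
relapse-driven pulses (onsets every 100 days, four weeks each), cross the
blood–brain barrier with permeability *b<sub>R</sub>*, and are reactivated
by perivascular macrophages. Reactivated T cells perform a biased random
walk toward the nearest healthy myelin — bias strength
*s* = *β* e<sup>−kD</sup> at Euclidean distance *D* — and degrade the
myelin site they occupy one state per step, from fully intact (*S* = 5)
down to fully degraded (state 1).

Each oligodendrocyte maintains a 5 x 5 block of 25 myelin sites and feels
stress *σ* equal to its count of fully degraded sites. Its integrated
stress response is threshold-governed: at *σ* ≥ *ω* it stops remyelinating;
at *σ* ≥ *λ* it undergoes apoptosis and its whole block is lost for good.
Repair of a damaged, unoccupied site in a myelinating block advances one
state per *W* = 12 quiet steps.

Treatments are atomic parameter changes at an intervention day (default
Day 80): reduced *b<sub>R</sub>* (DMT), raised (*ω*, *λ*) (ISR-targeting
resilience), and full or fractional restoration of the oligodendrocyte
population (stem-cell therapy), in any combination.

## A worked example

```r
library(msabm)

cfg <- ms_config()                    # untreated: b_R = 0.1, omega = 10, lambda = 14
sim <- run_simulation(cfg, seed = 1)
sim
#> <ms_sim>
#>   21600 steps (300.0 days), seed 1
#>   final: intact myelin 4.3%, apoptotic oligodendrocytes 95.7%, 12 reactivated T cells
```

A single untreated replicate loses ~96% of its intact myelin by Day 300:
the first relapse drives a lesion out from the perivascular space, block
after block of oligodendrocytes crosses its stress tolerances, and the
damage becomes irreversible. The combined therapy — DMT plus restored,
resilient oligodendrocytes at Day 80 — almost completely prevents this:

```r
plan <- treatment_plan(new_b_R = 0.025, new_omega = 21, new_lambda = 24,
                       restore_fraction = 1)
run_simulation(cfg, plan, seed = 1)
#> <ms_sim>
#>   21600 steps (300.0 days), seed 1, treated
#>   final: intact myelin 97.1%, apoptotic oligodendrocytes 2.6%, 8 reactivated T cells
```

The later relapses still cause transient damage (~94.6% intact twenty days
into the third relapse, for this seed), but the resilient oligodendrocyte
population repairs it — the dynamic the combined-treatment hypothesis
predicts.

Higher-level experiment helpers average seeded replicates and run the
sensitivity analyses:

```r
reps  <- run_replicates(cfg, n = 10, base_seed = 1)     # mean + min/max envelope
sweep <- sweep_bR(c(0.005, 0.025, 0.1, 0.3), cfg, n = 10)   # BBB permeability sweep
tab   <- treatment_comparison(cfg, n = 10)              # Day-300 scenario ladder
```

A thin command-line interface wraps the same functions
(`inst/cli/msabm.R simulate --config FILE --seed N --out DIR`, plus
`sweep-bbb`, `sweep-thresholds` and `compare-treatments` subcommands), with
YAML configuration files read by `read_ms_config()`.

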