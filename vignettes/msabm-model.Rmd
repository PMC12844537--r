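---
title: "An on-lattice agent-based model of MS lesion formation and treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An on-lattice agent-based model of MS lesion formation and treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msabm)
```

## The model

`msabm` simulates the formation of a demyelinating lesion in a
two-dimensional section of central nervous system tissue, together with the
in-silico treatment strategies that act on it. The model is an on-lattice,
discrete-time agent-based model: space is a square lattice with spacing
$\Delta = 10\,\mu m$ (one immune-cell diameter), time advances in steps of
$\tau = 20$ minutes, and a standard run covers 21,600 steps — 300 days.

The default lattice is 108 columns by 300 rows and is split left to right
into three vertical subdomains:

* **peripheral blood** (columns 1–3): primed, autoreactive T cells appear
  here;
* **perivascular space, PVS** (columns 4–8): home of a fixed population of
  45 perivascular macrophages (PVMs), the antigen-presenting cells;
* **parenchyma** (columns 9–108): a 1 mm x 3 mm myelinated tissue strip of
  30,000 myelin sites, maintained by 1,200 oligodendrocytes.

Rows wrap (the blood vessel runs alongside the whole section), the left edge
reflects, and the right edge removes cells that wander deeper into the brain.
Between blood and PVS sits the blood–brain barrier (BBB): a rightward
crossing attempt succeeds with probability $b_R$ (default 0.1, reflecting a
barrier already disrupted by disease), a leftward attempt with probability
$b_L$ (default 0 — cells committed to the CNS stay there). A failed crossing
consumes the cell's movement event for that step.

### Immune cells

Three mobile populations are tracked.

* **Primed T cells** appear in the blood at per-site rate $\rho_R$ during a
  relapse and $\rho_{NR}$ otherwise. The defaults ($2.25/900$ and $0.18/900$
  per site per step) introduce on average 2.25 and 0.18 cells per step over
  the 900 blood sites. Relapses follow an explicit schedule: onsets at days
  0, 100 and 200, each lasting four weeks (half-open windows).
* **PVMs** random-walk inside the PVS and never die. When a primed T cell
  and a PVM occupy the same site, the primed cell is instantly converted
  into a **reactivated T cell** at that site (occupancy is not exclusive;
  every co-located primed cell converts).
* **Reactivated T cells** seek and destroy myelin. Primed and reactivated
  cells die with per-step probability $\rho_d = 0.0049$, the first-order
  discretisation of the 0.35/day decay implied by the 48-hour half-life of
  cytotoxic T lymphocytes.

All mobile cells perform one movement event per step over the Von Neumann
neighbourhood. Unbiased walkers pick each direction with probability 0.25.
After the first myelin damage anywhere on the lattice (a latch that never
resets), reactivated cells feel a chemotactic bias toward the nearest myelin
site that still has health (state $\ge 2$), with strength

$$ s_\text{bias} = \beta e^{-k D}, $$

where $D$ is the Euclidean distance to that site, $\beta = 0.5$ caps the
bias, and $k$ sets its range. The two directions pointing toward the target
gain $s_\text{bias} \cdot |\text{component}|/(|\Delta x| + |\Delta y|)$ and
the two opposite directions each lose $s_\text{bias}/2$; probabilities
always sum to one. Two conventions close the corner cases: on an
axis-aligned target the favoured direction of the zero component axis
(east when $\Delta x = 0$, south when $\Delta y = 0$) keeps its unbiased
0.25; and for $\beta > 0.5$, where the away-probabilities can go negative,
they are clamped at zero and the vector renormalised. Distance ties break
toward the lowest row, then the lowest column, and distances are planar
(the periodic rows do not shorten them).

### Myelin and oligodendrocytes

Each parenchyma site carries a myelin agent with an integer state from $S$
(fully intact, the initial condition) down to 1 (fully degraded). A
reactivated T cell stepping onto a site with state $\ge 2$ *engages*: it
stops moving and decrements the site one state per step until the site
reaches state 1, then disengages. Each occupied site loses exactly one state
per step no matter how many cells sit on it (a per-agent variant is
available via `damage_per_agent`).

Every oligodendrocyte maintains a 5 x 5 block of sites (2,500 $\mu m^2$ of
membrane, matching a density of 400 cells/mm²). Its stress $\sigma$ is the
number of its sites at state 1. The integrated stress response is modelled
by two tolerances:

* $\sigma \ge \omega$: the oligodendrocyte stops myelinating — repair halts
  in its block;
* $\sigma \ge \lambda$ (with $\omega \le \lambda \le 25$): apoptosis — all
  25 sites drop to state 1 permanently.

Transitions are one-way during a simulation; apoptosis is absorbing always.
Repair operates only in myelinating blocks: an unoccupied damaged site gains
one state after $W$ consecutive unoccupied steps (occupation or block
shutdown resets the counter — the stricter reading of "repair after $W$
steps of no occupation"). Fully repairing one site therefore takes
$(S-1)\,W\,\tau$ minutes, against $(S-1)\,\tau$ to destroy it.

### One step

The sub-step order is fixed (and isolated in one compiled routine):
spawning → synchronous movement of primed cells, PVMs and unengaged
reactivated cells (with BBB and boundary rules) → antigen presentation →
engagement and degradation → repair → stress recomputation and
threshold transitions → death → metrics. Newly converted reactivated cells
do not move in their creation step; engaged cells do not move but still die.
A single seeded RNG stream with stable (insertion-order) agent iteration
makes every run bit-reproducible.

## Parameters and calibration

| parameter | meaning | default | provenance |
|---|---|---|---|
| $\Delta$ | lattice spacing | 10 µm | immune-cell diameter |
| $\tau$ | step length | 20 min | published untreated course |
| $b_R$ | BBB permeability (rightward) | 0.1 | untreated disease value |
| $\rho_R, \rho_{NR}$ | spawn rates | 2.25/900, 0.18/900 | printed per-step means |
| $\rho_d$ | T-cell death | 0.0049 | 48 h half-life |
| $\beta$ | maximum bias | 0.5 | "trial and error" chemotaxis |
| $\omega, \lambda$ | stress tolerances | 10, 14 | untreated disease values |
| $S$ | myelin states | 5 | calibrated (below) |
| $W$ | repair delay | 12 steps | calibrated (below) |
| $k$ | bias decay | 0.02 per unit | calibrated (below) |

Three constants are not pinned by published values and were calibrated once
against the untreated disease course — a ~96% loss of intact myelin by Day
300 and an average of 90–120 reactivated T cells in the parenchyma during
relapses (30–40 cells/mm²) — and then frozen:

* **$W = 12$.** With $W = 1$ remyelination is as fast as demyelination and
  no lesion ever forms: block stress cannot reach $\omega$ against repair at
  damage speed. $W = 12$ makes one repair increment take 4 hours (16 hours
  for a full site), squarely between the minutes-scale of cell-mediated
  damage and the days-to-weeks scale of biological remyelination, and
  reproduces the published course.
* **$k = 0.02$.** The bias range (where $s_\text{bias}$ exceeds half its
  maximum) is then ~35 lattice units (350 µm). Smaller $k$ lets T cells
  march arbitrarily deep and consume 100% of the strip; larger $k$ strands
  them near the PVS. $k = 0.02$ caps the untreated lesion near the observed
  96%.
* **$S = 5$.** Intermediate states are transitory in the observed dynamics;
  varying $S$ with $W$ rescaled accordingly changed outcomes little, and 5
  keeps full degradation at 80 minutes of sustained attack.

With these values the treatment scenarios (applied at Day 80, after the
first relapse) reproduce the published ladder to within a few percentage
points: delayed DMT ($b_R \to 0.025$), oligodendrocyte restoration,
resilience enhancement ($\omega \to 21$, $\lambda \to 24$), their
combination, and the combined therapy with DMT. The residual deviations are
largest for the immediate-DMT arm (our quarter-influx lesion stalls a few
points lower) and the combined therapy's apoptotic tally (ours loses ~3% of
oligodendrocytes against the published 0.7%): in this implementation the
distribution of block stress under attack appears somewhat wider than in the
original, so quarter-strength attacks cross $\omega = 10$ slightly too
rarely and full-strength relapses cross $\omega = 21$ slightly too often.
These deviations are reported as measured by `scripts/acceptance.R`.

## Treatments

A `treatment_plan()` changes the live parameters atomically at one
intervention day and/or re-establishes oligodendrocytes: each block is
independently restored with probability $f$ (all 25 sites intact, stress
zero, myelinating; engaged T cells on restored sites are released). Two
interpretation toggles are exposed because the sources are silent:

* restoration scope — by default all blocks are eligible (restoring a
  myelinating block refreshes its myelin); `restore_scope = "impaired"`
  limits restoration to non-myelinating and apoptotic blocks;
* when tolerances rise, non-myelinating blocks whose stress is below the
  new $\omega$ resume myelinating by default
  (`relatch_nonmyelinating = TRUE` keeps them shut). Both choices give
  indistinguishable outcomes at the default intervention day because nearly
  all shut blocks are already apoptotic by Day 80 — apoptosis stays
  absorbing under either toggle.

## What the simulations do and do not show

All experiments in this package are self-generated: the model is the data
generator, and the defaults *are* the study conditions (relapse schedule,
influx rates, tolerances). The stochastic replication machinery
(`run_replicates()`, seeded streams) quantifies run-to-run variability, not
biological variability between patients. Phenomena deliberately outside the
model: explicit chemokine fields (bias is a distance kernel), B cells and
further T-cell subsets, PVM phagocytosis, spontaneous OPC differentiation,
vascular geometry beyond one straight vessel, spatially varying BBB
permeability, and any mapping to MRI or clinical phenotype. Passing tests
therefore certify the mechanics and reproducibility of this model, not
predictions about real lesions.

## Numerical choices

* Degenerate inputs: `b_R = 0` is allowed and provably preserves all myelin
  (no cell can enter the CNS); `n_steps = 0` reports the initial state;
  an empty relapse schedule runs at baseline influx throughout.
* A block may pass both tolerances within one step (it stops myelinating
  and dies in the same update) — thresholds trigger at the earliest
  consistent moment.
* "Lost myelin %" is $100\,(1 - \text{intact fraction})$: partially damaged
  sites count as lost, matching the intact-population readout.
* Sweep AUCs are trapezoidal integrals of behaviour fractions divided by
  the horizon, i.e. each behaviour's share of oligodendrocyte-time; the
  three shares sum to one by construction.
* Relapse-window correlations use the relapse span plus a configurable
  7-day tail; windows with a degenerate permeability axis report `NA` with
  a warning.

## Problem sizes

The bundled tests exercise the full 108 x 300 lattice over 300 days with 10
replicates per scenario for the headline comparisons (a few minutes in
total), and small 28 x 40 domains with a few hundred steps for the
mechanistic unit and property tests. `scripts/acceptance.R` re-runs every
scenario at full size from scratch; `--reps` scales the replicate count.

## A worked example

```{r example, eval = FALSE}
cfg <- ms_config()                       # untreated disease course
sim <- run_simulation(cfg, seed = 1)
lost_myelin_pct(sim$metrics)             # ~96-99% loss by Day 300

plan <- treatment_plan(new_b_R = 0.025, new_omega = 21, new_lambda = 24,
                       restore_fraction = 1)
combo <- run_replicates(cfg, plan, n = 10, base_seed = 1)
100 * combo$mean$intact_frac[nrow(combo$mean)]   # ~96-99% intact
```
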