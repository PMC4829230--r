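---
title: "Modeling desynchronized quorum sensing: the Lsr and LuxIR simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling desynchronized quorum sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorsim)
```

# The scientific question

Clonal bacterial populations signaling through the Lsr (LuxS-regulated)
quorum-sensing system are repeatedly observed to split into activated and
unactivated subpopulations, even though every cell carries the same
circuit. quorsim exists to study one candidate mechanism: cell-to-cell
heterogeneity in autoinducer handling desynchronizes the timing of
autoinduction, and because Lsr activation *consumes* the shared
extracellular signal (AI-2), early activators can permanently deny the
signal to late ones. The same machinery, run with a LuxIR/AHL circuit in
which activation only *adds* signal, produces the opposite spatial
phenotype: a contiguous outward wave instead of dispersed speckles.

The package provides three layers:

1. **Single-cell circuit models** — a mechanistic ODE model of the Lsr
   system (`lsr_params()`, `lsr_rhs()`, `integrate_batch()`,
   `two_cell_shared_pool()`) and a deliberately heuristic LuxIR model
   (`lux_params()`, `lux_step()`).
2. **A 2D agent-based engine** (`run_config()`, `run_simulation()`) with a
   finite-difference extracellular field, swimming and colony-growth
   motility, per-cell parameter heterogeneity, and growth/division
   bookkeeping.
3. **Analysis statistics** (`activation_time()`, `fraction_activated()`,
   `median_nn_distance()`, `local_heterogeneity()`,
   `induction_center_bias()`, `first_activator_stats()`).

# The Lsr circuit model

## States and terms

Five states per cell: extracellular AI-2 local to the cell (`Ae`, uM),
free intracellular AI-2 (`Ai`), phospho-AI-2 (`Ap`), lsr transcript (`M`)
and Lsr transporter protein (`T`). The right-hand side is assembled from a
registry of named terms (`lsr_terms()`), one per biological influence, so
each is unit-testable in isolation:

| term | rate | meaning |
|---|---|---|
| synthesis | `K_synth` | AI-2 production by the activated methyl cycle (Lsr-independent) |
| export | `V_ydgG * Ai` | first-order export through YdgG/TqsA |
| basal_import | `basal * Ae / (K_basal + Ae)` | saturable low-affinity import (rbs/PTS routes) |
| induced_import | `V_ind * T * Ae / (K_ind + Ae)` | LsrACDB transporter import, proportional to transporter level |
| phosphorylation | `(k_phos + k_pK * T) * Ai` | LsrK kinase; capacity scales with operon expression |
| ap_turnover | `d_Ap * Ap` | LsrFG-mediated catabolism of phospho-AI-2 |
| transcription | `a0 + a_M * Ap^n / (k2^n + Ap^n)` | LsrR de-repression by phospho-AI-2 (Hill) |
| mrna_decay / translation / protein_turnover | first order | expression bookkeeping |

LsrR is not an explicit state: phospho-AI-2 sequesters the repressor, and
the composite effect is folded into the increasing Hill function of `Ap`.
An explicit-repressor variant would add one state and one binding constant
without changing the feedback topology; we document it as the road not
taken because the folded form has fewer unidentifiable constants.

## Why this structure produces desynchronized bimodality

Three structural features matter more than any individual rate value:

* **A closed cell cannot self-activate.** Phospho-AI-2 is bounded by total
  AI-2 throughput over its turnover, and with synthesis alone
  (`K_synth / d_Ap` at full trapping) the Hill threshold `k2` is reachable
  only when import adds substantially to throughput. The off state is
  therefore globally stable in the absence of extracellular signal, for
  any transporter level.
* **Commitment is a saddle-node near import saturation.** The positive
  loop (import and phosphorylation capacity both scale with expression)
  ignites only when the saturable basal route runs near its half-saturated
  regime. Near saturation, a small relative difference in `basal` maps to
  a large relative difference in the extracellular concentration — and
  hence the *time* — at which a given cell commits. This is the
  amplification that turns a 2-5% parameter spread into many minutes of
  activation-time spread.
* **Activated cells trap AI-2.** Induced kinase capacity (`k_pK * T`)
  means imported AI-2 is phosphorylated rather than re-exported, so the
  first activators crash the shared pool, and cells that have not yet
  passed the saddle-node relax back to the off state. Once fully
  committed, a cell is self-sustaining (the on state persists at zero
  extracellular AI-2), so the population latches into a stable mixture:
  bimodality.

## Parameter values

The exact kinetic constants are this package's own calibration; they were
fixed once, against the qualitative behaviors the system is known for,
before any population-scale experiment was run, and are not tuned
per-study. The calibration targets were: a batch culture inoculated at
OD600 0.03 (36 cells in the default 500 x 500 x 6 um domain) autoinduces
shortly after the four-hour mark with an abrupt mRNA rise, an
extracellular AI-2 peak-then-collapse, and a phospho-AI-2 surge; the
median basal import rate is 487.8 uM/min with the 0.052 coefficient of
variation convention at sigma = 0.0225; a two-cell shared pool with one
cell at `basal = 510` starves a sufficiently lower-basal partner; and
time-to-activation shifts in the expected direction for each of `basal`,
`K_synth`, `k_phos`, `V_ydgG`, `k2`.

Noteworthy choices, with units (all rates per minute, concentrations uM):

* `K_basal = 1` — the basal route saturates at a few uM extracellular
  AI-2; this is the sensitivity amplifier discussed above.
* `hill_n = 12`, `k2 = 2.8` — switch-like de-repression. The steepness
  stands in for the cooperativity of LsrR multimer release; milder Hill
  coefficients let expression leak ahead of the basal-route threshold and
  homogenize the population.
* `d_Ap = 8` — fast phospho-AI-2 turnover (LsrFG), which keeps `Ap` a
  responsive readout of current import flux.
* `d_T = 0.1` — transporter turnover well above the dilution rate, making
  the activation threshold a genuine bifurcation rather than an
  infinite-horizon integrator.
* `activation_fold = 5` — a cell is classified QS-positive when `T`
  exceeds five times its initial value; classification never feeds back
  into the dynamics.

The reference integrator for all deterministic solutions is the implicit
backward-differentiation solver (deSolve's `bdf`) at rtol 1e-8 /
atol 1e-10; autoinduction commitment is stiff enough to defeat
non-stiff adaptive integrators mid-blow-up.

# The LuxIR heuristic

LuxIR is modeled exactly as simply as its phenomenology requires: cells
synthesize AHL at a baseline rate (population mean 1 uM/min, lognormal
spread sigma = 0.0225 in base-10 logarithm); when intracellular AHL first
exceeds 2.9 uM the synthesis rate ramps linearly to 10 uM/min over 30
minutes (standing in for LuxR-mediated cooperativity and the
transcription/translation lag); AHL crosses the membrane with conductivity
0.6 per minute acting on the concentration difference. The threshold
crossing latches — the ramp never resets — encoding one-way commitment.
The crossing test uses the instantaneous concentration. No AHL
degradation is modeled (an optional rate is exposed, default zero). A
cell is classified active when its synthesis rate reaches five times its
own baseline, which happens 40/3 minutes into the ramp for an average
cell.

# The 2D agent-based engine

## Geometry, field and time stepping

The default domain is 500 x 500 um with an implied depth of 6 um,
discretized into 2 x 2 um elements (24 um^3 each) with a master step of
0.0667 s. The extracellular autoinducer field obeys the diffusion
equation, solved by the explicit forward-time centered-space (FTCS)
scheme with no-flux mirror boundaries. Stability demands
`lambda = D dt / dx^2 <= 1/4`; the engine sub-steps diffusion so that
lambda never exceeds 0.2 per sub-step — strictly inside the stability
bound because at exactly 1/4 the stencil's center weight vanishes and an
undamped checkerboard mode survives.

**The effective diffusion coefficient.** `wilke_chang_D()` implements the
Wilke-Chang correlation and estimates ~1.2e3 um^2/s for DPD-scale solutes
in water at 310 K; this is the documented default of `grid_spec()`. Note,
however, that the stated master step (0.0667 s) is stable on a 2-um grid
*without* sub-stepping only for D <= 15 um^2/s, and that at D ~ 1e3 um^2/s
autoinducer gradients across a sub-millimeter domain are far too small to
produce boundary-biased initiation or a spatially resolved activation
wave. The study configurations in this package therefore use
D = 15 um^2/s — the largest coefficient consistent with the literal
scheme — for swimming studies, and a strongly gradient-forming
D = 2 um^2/s for the colony pattern-contrast studies. D is always
explicit in the configuration.

## Per-cell dynamics and exchange

Each engine step, the cells in a grid element are integrated *jointly
with that element's autoinducer pool* by an adaptive explicit Heun scheme
(error-controlled sub-stepping; steps that would drive any state negative
are rejected and retried smaller, never clipped, so mole balance is exact
up to rounding). Coupling cells to their local pool makes import
supply-limited by construction: a cell cannot withdraw more than its
element holds. The explicit engine is validated against the implicit
reference solver — the activation time of the population-mean phospho-AI-2
trace agrees within 5% — and total autoinducer (field plus cell contents)
is conserved to a relative 1e-12 when synthesis and catabolism are
switched off.

## Motility, growth and division

*Swimming*: per step, each cell draws a speed from a normal distribution
(mean 20 um/s, cv 0.05) and a uniform direction. Projected positions
beyond a boundary are mirror-reflected (an overshoot of d lands d inside,
per axis). A move into an element already holding three cells is
rejected; the cell stays put.

*Colony growth*: cells occupy elements exclusively and move only through
division. A parent with a free neighboring element places its daughter
there at random; an interior parent pushes the chain of cells along the
shortest path (breadth-first, ties broken uniformly) to unoccupied space
one element outward and the daughter takes the vacated slot. Two
phrasings of the pushing rule circulate for this class of model (toward
the nearest colony edge vs. along the shortest path to unoccupied
space); the shortest-path form is implemented since the two coincide
except on ties, which are broken uniformly at random.

*Division*: the population growth rate is a supplied constant, converted
to per-cell doubling times that are normally distributed (cv 0.05,
truncated at 1 min). Daughters copy the parent's state variables, QS
flag and `T` reference verbatim; only the varied parameter (redrawn from
the heterogeneity distribution), the doubling time, and the position
differ. `T0_ref` is copied, not rescaled — protein partitioning noise at
division is outside scope.

Four independent RNG streams (placement, motility, heterogeneity,
division) are derived from the master seed so that, e.g., adding motility
noise does not perturb the heterogeneity draws; identical configurations
reproduce records exactly.

## Heterogeneity conventions

`heterogeneity_spec()` assigns one parameter per cell from a lognormal
distribution, parameterized by median (or log-mean) and the standard
deviation of the logarithm. The base of that logarithm is explicit
(`log_base`): sigma = 0.0225 in base 10 corresponds to a 5.2% coefficient
of variation, while the same number in base e gives 2.25%. Both
conventions appear in the literature this model engages with — sometimes
inconsistently within one source — so the package refuses to guess.
Assigned values persist for the cell's lifetime and daughters redraw.

# Study conditions at reduced scale

Population-scale properties are established on reduced domains so the
full suite runs on one CPU in minutes; the reductions are scientific
choices, stated here once:

* **Swim studies** (activated-fraction vs. sigma, motility comparison,
  explicit/implicit congruence): 100 x 100 um, 40 initial cells, 2-s
  engine step, D = 15 um^2/s, 200 simulated minutes, 3 replicates per
  condition. The 40-cell inoculum in the small domain is ~30x denser
  than OD 0.03, which advances autoinduction from ~4.5 h to ~1.6 h
  without changing its mechanism.
* **Colony contrast studies** (speckle vs. front, boundary bias, first
  activators): 120 x 120 um, 40-cell founding colony, doubling time 60
  min so the colony stays within the domain while autoinducer
  accumulates, D = 2 um^2/s to sustain gradients across the colony,
  sigma = 0.0225 (base 10) on `basal` (Lsr) or the baseline AHL rate
  (LuxIR).

Under these conditions the package reproduces, deterministically under
fixed seeds: terminal activated fraction decreasing in sigma (1.00 /
0.97 / 0.76 at sigma = 0, 0.0125, 0.025 on `basal`) with the broadest
distribution activating earliest; colony growth activating earlier and
plateauing lower than swimming at matched parameters (denser packing,
stronger local competition for AI-2); LuxIR activation spreading as a
contiguous front (discordant-pair score well below the spatially random
null) while Lsr activation stays interleaved at matched activated
fraction; LuxIR induction centers biased toward no-flux boundaries; and
first activators drawn from the upper tail of the assigned-parameter
distribution, extremely so for Lsr and noticeably blunted for LuxIR.

One honest caveat: under this calibration, heterogeneity in the AI-2
synthesis rate (`K_synth`) at sigma <= 0.025 leaves the terminal
activated fraction at 1.0 — its share of the threshold flux is small, so
the saturation amplifier that makes `basal` and `V_ydgG` heterogeneity
bite does not engage. The ordering property (non-increasing in sigma)
holds vacuously there. In the source system the synthesis route was
reported as a stronger axis than export; that difference is a consequence
of the calibration, not of the topology, and is recorded rather than
hidden.

# The local-heterogeneity score

No closed-form definition of "local heterogeneity of activation" was
available for the colony-pattern comparison, so the package defines one:
the fraction of cell pairs within radius r (default 10 um) whose QS
states differ, normalized by `2p(1-p)` (p the activated fraction). A
spatially random assignment of states scores ~1 by construction — the
probabilistic-assignment control is exactly this statistic's null — while
contiguous fronts score below 1 and anti-correlated speckle above. The
score is invariant to relabeling the two states.

# What the synthetic populations do and do not show

The generator emulates: lognormal single-parameter heterogeneity frozen
over each cell's lifetime, exponential growth with per-cell doubling-time
noise, crowding by an element-occupancy cap, and autoinducer transport
with no decay in the medium. It does not emulate: time-varying
intracellular noise, multi-parameter covariation, nutrient fields or
growth-rate feedback, cell death, chemotaxis, EPS/biofilm mechanics, or
3D structure. Passing the package's tests therefore demonstrates the
*mechanism* — desynchronization plus signal consumption yields stable
fractional activation; positive-only feedback yields waves — under
idealized conditions, not a quantitative fit to any particular organism's
culture data. No parameter in this package was fit to experimental
flow-cytometry or AI-2 assay data.

# Numerical edge cases

* Degenerate heterogeneity (sigma = 0) returns the median exactly, not a
  zero-variance sample.
* The activation-time detector fits its baseline on 12-152 min and flags
  the first sample where the trace exceeds three times the extrapolated
  baseline; an exactly linear trace never activates (returns `NA`).
* `exchange()` caps withdrawals at the element's content and reports the
  shortfall; the engine avoids ever needing the cap by integrating cells
  jointly with their pool.
* Negative-state guards reject and shrink integration steps; clipping is
  never used because it silently destroys mole balance.
* Fold-classification is strict (`T > 5 T0`): a cell at exactly fivefold
  is uninduced.
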