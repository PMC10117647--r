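---
title: "The locorecur model: tissue dynamics, recurrence, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The locorecur model: tissue dynamics, recurrence, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`locorecur` simulates multistage carcinogenesis in a tissue of fixed size
`N` and asks how long after surgical resection a locoregional recurrence
takes to appear. Three tissue compartments — normal Type 0 cells,
premalignant Type 1 cells carrying one driver mutation, and Type S−1
cells one mutation short of malignancy — evolve under a Moran process:
the population size is constant, a uniformly chosen cell dies, and the
vacancy is refilled by a division draw weighted by the cell fitnesses
`r0`, `r1`, `rS1`. Mutation happens at division: a dividing Type 0 cell
produces a Type 1 daughter with probability `mu1`, a Type 1 cell a Type
S−1 daughter with probability `muS1`, and a Type S−1 cell a malignant
Type S cell with probability `muS`. Chains requiring more than three
mutational steps are folded into a smaller `muS1`, so the three-step
model covers them without explicit intermediate compartments.

Malignant cells are not part of the tissue. They grow as a branching
process with per-cell birth rate `rS` and death rate `dS`; the model
assumes positive net growth `rS - dS > 0` (the constructor warns
otherwise). When the malignant count first reaches the detection
threshold (10^9 cells, about 1 cm^3) the tumor is detected and resected:
all malignant cells are removed, the tissue composition — the cancerized
field — is preserved, and the clock keeps running until the malignant
count reaches the threshold a second time. That elapsed time is the
recurrence time, the model analog of a patient's disease-free interval.

## Simulation scheme and numerical choices

Events are interleaved by total rate: tissue turnover at `d * N`,
malignant birth at `rS * XS`, malignant death at `dS * XS`. The clock
advances by the mean waiting time `1/(d*N + (rS + dS)*XS)` at every step
(deterministic mean increments rather than exponential draws; for the
time scales of interest — thousands of events per time unit — the
difference is far below the stochastic variation between runs, and the
mean-increment clock is what the update rule of the hybrid scheme is
stated in).

Specific choices that the model statement leaves open, and how this
package resolves them:

- **Malignant births during turnover.** A malignant daughter does not
  fill the dead cell's vacancy: the malignant count is incremented and
  the vacancy draw repeats from the full distribution, so one turnover
  event can spawn several malignant cells. A redraw cap (default 10^4)
  guards inputs with `muS` near 1, where the redraw loop would not
  terminate.
- **Division numerators use the pre-death composition**, including the
  dying cell, exactly as the transition probabilities are written.
- **Hybrid tumor growth.** Below `hybrid_switch * N` (default `2N`)
  malignant cells follow the full stochastic birth-death channels, so
  young tumors can and do go extinct, returning the run to the
  pre-emergence regime. At `2N` the growth switches to deterministic
  exponential expansion, adding `log(threshold/2N)/(rS - dS)` to the
  clock. Tissue turnover continues to be simulated for that interval —
  the composition at surgery drives recurrence and must keep evolving —
  while the tumor birth/death channels are suspended; malignant daughters
  from tissue divisions during this interval are ignored as negligible
  against a macroscopic tumor.
- **Censoring.** Each phase (initiation, recurrence) is capped at
  `max_time` (default 10^4 time units); runs that never detect carry a
  censoring flag rather than being dropped, and a censored initiation
  skips the recurrence phase.
- **Reproducibility.** All stochastic kernels (including the compiled
  ones) draw from R's RNG, so a single `set.seed()`/`seed =` argument
  replays any run bit-identically; outcomes record their seed.

The spatial variant puts the tissue on an `I x J` lattice (derived as the
most square factorization of `N` when not given): the death site is
uniform over sites, only its in-bounds 4-neighborhood competes to refill
it (wall boundaries, so corners have 2 and edges 3 neighbors), and the
division distribution is the same formula evaluated on neighbor-type
counts. Malignant cells live off-lattice, since unbounded growth is
incompatible with the fixed lattice. The lattice persists through
surgery, so the spatial arrangement of the field carries into the
recurrence phase.

The well-mixed and lattice engines are validated in the test suite
against exact absorbing Markov-chain hitting times on enumerable state
spaces (the 10-composition space at N = 3 and the 81-state 2x2 lattice),
against the k/N neutral fixation law, and against the deterministic
passage-time limit of the supercritical birth-death process.

## Pattern classification

Tissue composition at detection is labeled by strict thresholds: one
type above 90% is *dominance*; failing that, two types each above 40%
are *co-dominance*, or all three above 30% triple co-dominance;
precedence is dominance, then pairwise, then triple. These rules do not
cover the simplex — (50%, 30%, 20%) matches nothing — so an `OTHER`
label keeps classification total; censored runs are `NO_CANCER`.
Boundary values (exactly 90/40/30%) deliberately fall to the lower rule.

### A known divergence from the published panels

The published panel experiments report 3 initiation patterns for the
well-mixed model and 7 with spatial structure over the grid `r1, rS1 in
{0.75, 1, 1.25}`, `muS1 in 1e-6..1e-2`, `muS in {1e-3, 1e-2}`. Running
this package's engines — which are oracle-validated implementations of
the printed transition probabilities — over the same grid yields *more*
classes in the well-mixed model (typically 6-7, including Type 0
dominance and `OTHER`). The mechanism is visible in the rates: at
mutation-selection balance the tissue sustains about `N*muS1/s`
premalignant Type S−1 cells (s the selective cost), so for the fast
corners (`muS1*muS ~ 1e-4`) the first surviving malignant lineage
appears within tens of time units — long before the progressive loss of
Type 0 cells completes — and detection then finds a mostly-normal or
mixed tissue. We could not reconcile this with the published claim that
every well-mixed run ends in Type 1/Type S−1 (co-)dominance; the
package reports what the stated dynamics produce, and the corresponding
acceptance checks are left failing rather than adjusted. The directional
spatial finding — lattice structure preserves normal Type 0 cells longer
at equal N — does reproduce and is asserted in the tests.

## Survival statistics and calibration

Recurrence times from repeated full runs form an in-silico cohort
(censored runs enter as right-censored observations). Kaplan-Meier
curves come from `survival::survfit`, curve comparisons from
`survival::survdiff` (Mantel-Cox). The percentile grid takes, for each
quantile 0%, 4%, ..., 100%, the first time the cumulative recurrence
fraction `1 - S(t)` reaches it; 0% maps to time 0 and quantiles the
curve never reaches (censoring) are missing. The fitting objective is
the mean squared natural-log residual between the simulated and clinical
grids over quantiles both reach with positive times (log-MSR; the base
of the logarithm only rescales the objective, and the 0% point is
log-undefined and always excluded). The companion sum form (log-SSR) is
reported alongside, matching the convention of the bundled profile
table.

Calibration is random search: candidates draw fitnesses and rates
uniformly and mutation probabilities log-uniformly within bounds
(defaults bracket the bundled fitted profiles: `r1, rS1 in [0.85,
1.15]`, `rS in [2, 9]`, `dS in [1, 4.5]`, `log10 mu in [-5, -2]`);
structural values (`N`, `r0 = 1`, `d = 1`) stay fixed. One model time
unit is one month, so fitted `dS` reads directly as tissue turnover per
month. Candidates whose cohorts never recur receive a penalty objective
of 10^6 so the search stays total. The accepted fit is checked by
log-rank against the clinical sample (agreement = p above 0.05).

Two structural caveats, documented because they shaped the design:

- The log-MSR objective only sees quantiles both curves reach, so it is
  blind to the never-recurring plateau of a heavily censored cohort; a
  fit can match every shared percentile and still disagree with the
  plateau. Real registry tables blunt this because follow-up ends early
  (patients beyond the horizon leave the risk set); the synthetic-cohort
  generator therefore applies an administrative follow-up horizon
  (default 150 months) on top of optional uniform early censoring.
- The recovery experiment in the acceptance tests uses a truth whose
  cohort recurs almost completely within follow-up (N = 100, `r1 = 1`,
  `rS1 = 1.2`, `rS = 3`, `dS = 1.5`, `mu1 = muS1 = 3e-3`, `muS = 1e-3`),
  where the objective is informative about all of the curve; with 500
  candidates of 100 runs each it recovers the net growth rate within a
  few percent and passes the log-rank check.

## What the synthetic data does and does not emulate

`synthesize_cohort` emulates the clinical DFS tables the fitting
consumes: right-censored recurrence times in months, portal-style status
strings, administrative follow-up, and loss to follow-up. It does not
emulate anything the model itself lacks: metastatic recurrence,
treatment effects, competing mortality, demographic structure, or
measurement error in recurrence dates. Passing recovery tests therefore
show that the fitting machinery is consistent — not that the model is
identified against real cohorts, where those ignored processes are
present.

## Problem sizes used by the tests

The test and acceptance experiments run at deliberately reduced scale,
chosen as the smallest sizes at which each effect is resolved: pattern
grids at N = 300 (well-mixed) and 20x20 (lattice) in triplicate,
parameter-dependence arms at N = 100 with 1,000 runs per arm (the
original panel count) and the null `mu1` comparison at 200 runs per arm,
oracle comparisons at 20,000 replicates, log-rank size calibration at
2,000 null replicates, and the recovery search at 500 candidates by 100
runs. Full-scale runs (N = 2,500 lattice, thousands of candidates) use
the same code paths and are a matter of wall-clock time only.
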