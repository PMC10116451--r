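---
title: "Bi-objective capacity planning for graded elder-care institutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-objective capacity planning for graded elder-care institutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldercap)
```

## The planning problem

Municipal elder-care systems rate institutions on a quality ladder — here
five grades, A (basic) up to AAAAA (premium) — and plan construction in
multi-year cycles. The decision is an `M × N` matrix of non-negative
integers `x[i, j]`: how many grade-`j` institutions to build in cycle `i`.
Each grade `j` carries three per-institution coefficients: a construction
cost `a_j` (area-like units, since floor-area standards drive cost), an
income `b_j` (accommodation fees, subsidies, tax treatment), and a bed
capacity `c_j`. Coefficients are held constant across cycles; the only
time variation the model admits is a per-cycle multiplier `φ_i` on income,
which the smart-community scenario uses. The objectives are

* economic benefit `F1 = Σ_i Σ_j φ_i b_j x[i,j]`, to be maximised, and
* social cost `F2 = Σ_i Σ_j a_j x[i,j]`, to be minimised.

Both are linear in the plan, so objectives are additive across plans and
monotone in every cell — properties the test suite verifies directly.
Internally both objectives are stored in minimisation convention,
`(−F1, F2)`, which makes dominance, crowding, hypervolume and TOPSIS all
"smaller is better" with no special cases.

Constraints come in two modes.

* **Horizon mode** (the baseline): total beds at the end of the horizon,
  `Σ_j d0_j + Σ_i Σ_j c_j x[i,j]`, must reach `rate × P` (60 per 1,000
  elderly at the 2035 population in the shipped parameterisation), and each
  grade's final bed stock must hold at least a share `p_j` of total beds.
  The default `p_j = 0.15` per grade comes from demand being spread evenly
  over five disposable-income quintiles; the five floors jointly guarantee
  75% of demand, and configurations whose shares sum past 1 are rejected at
  load time as structurally infeasible.
* **Per-cycle mode** (the smart-community scenario): a bed floor at the end
  of *every* cycle against a reference population, and the share floors
  applied to the cumulative bed mix of every cycle.

Two numerical conventions deserve a note. First, the published district bed
stocks are integer multiples of the *rounded-up* bed coefficients, so
`derive_initial_beds()` uses `count × ceiling(c_j)` — this reconstructs all
55 published district-by-grade cells exactly — while constraint arithmetic
keeps the raw fractional `c_j`, which is the more faithful reading of each
artifact. Second, all constraints are expressed as slacks (`≥ 0` means
satisfied) and infeasibility is summarised as the sum of negative-slack
magnitudes, which is what the solver's feasibility rule consumes.

The shipped parameterisation uses the citywide population figures (2.56
million elderly projected for 2035; 1.716 million as the near-term reference
for per-cycle floors, obtained as the 1.581 million of end-2020 plus three
years of the stated 40–50 thousand annual growth at its midpoint).
District-level elderly populations were never published, so district
problems default to the citywide values and accept overrides.

## Solving: an elitist non-dominated-sorting integer GA

Institution counts must be integers, so the genome is the integer plan
itself (column-major cell vector), and all variation operators stay on the
integer lattice:

* **Initialisation** — every cell uniform on `{0, …, bound}`. Default
  per-cell bounds are `ceiling(max(0, additional beds required) / c_j)`:
  enough for any single grade to close the bed gap on its own, and finite so
  the search space and the enumeration oracle are well defined.
* **Selection** — roulette with rank-reciprocal fitness `1/rank`. The rank
  is the constrained non-dominated sorting rank; crowding distance is
  deliberately *not* part of the roulette weight and only breaks ties in
  elitist truncation, keeping selection pressure scale-invariant in the
  objectives.
* **Variation** — uniform per-cell crossover (swap probability 0.5 per cell
  pair member at rate `crossover_rate`) and mutation that resamples a cell
  uniformly within its bounds. Children are integers in bounds by
  construction; `integer_repair()` (round then clip) exists for externally
  supplied real-valued plans only.
* **Feasibility** — constrained domination: feasible beats infeasible,
  infeasibles compare by total violation, feasibles by Pareto dominance.
  This needs no penalty weights, which would otherwise have to be tuned to
  the (very different) scales of the bed and share constraints.
* **Elitism** — parents and offspring are merged and the best
  `population_size` survive by (rank, crowding distance), crowding ties
  broken by genome lexicographic order so truncation is deterministic.

A running archive accumulates every feasible non-dominated solution found,
deduplicated by objective pair (duplicate objective pairs add nothing to
the front and would crowd real trade-offs out of a capped archive) and
thinned by crowding distance if it outgrows `max(1000, 4 × population)`.
The archive, not the current population, is what the run returns and what
termination watches: its 2-D hypervolume (reference point: component-wise
worst of the initial archive, slightly inflated) is non-decreasing by
construction, and the run stops when it improves by less than
`stagnation_tol` (default 1e−9) over `stagnation_window` (default 50)
generations, or at the generation cap. The returned archive is truncated to
`round(pareto_fraction × population_size)` members — with the published
settings (population 100, fraction 0.8, up to 500 generations) that is the
80-solution archive a planner works with.

Determinism: the entire run sits under one seed (`withr::with_seed`), so
identical problem, settings and seed reproduce the archive bit for bit.

## Choosing one plan: TOPSIS

The archive is a menu, not an answer. `topsis_decide()` scores each
archived solution: columns (−F1, F2) are normalised to unit Euclidean norm,
weighted (default 0.5/0.5 — benefit and cost treated as equally important,
adjustable to the decision-maker), and each solution's Euclidean separations
`d⁺`, `d⁻` from the ideal (column minima) and anti-ideal (column maxima)
points give the relative closeness `R = d⁻/(d⁺ + d⁻)`, maximised by the
selected plan. Ties take the lowest solution index; an archive of identical
rows is scored 0.5 throughout and the first row selected. Euclidean
distance is used throughout — for a fixed archive of mutually independent
objective columns the rank-reversal and correlation caveats of
distance-to-ideal methods do not bite, so the plain method is the right
tool. Closeness is scale-free (rescaling either objective column by any
positive constant changes nothing) and never contradicts dominance within
the archive; both properties are exercised over a thousand random matrices
in the tests.

## The smart-community scenario

From a chosen switch cycle (default 3, splitting five cycles 2 + 3),
intelligent-robot substitution of human services halves institution income:
`φ_i = 0.5` for `i ≥ 3`, applied to the income coefficients in `F1` —
benefit, not cost, is what the adjustment touches. Meanwhile home-care
demand raises the bed requirement: per-cycle targets climb as cumulative
sums of per-cycle increments, 45 + (3, 3, 4, 4, 4) giving 48, 51, 55, 59,
63 beds per 1,000 against 45 + (3, 3, 3, 3, 3) → 48 … 60 for the original
ramp. For any plan, smart-scenario benefit never exceeds baseline benefit,
with equality exactly when nothing is built from the switch cycle on (or
the factor is 1) — a property the tests check with exact equality
conditions. The per-cycle floors as printed use a single reference
population for all cycles; that is almost certainly a simplification of
cycle-end populations, so the implementation follows the printed form by
default and accepts one population per cycle.

## Synthetic problems and the enumeration oracle

`generate_problem()` draws problems with the same structure as the shipped
parameterisation: coefficients strictly decreasing from the highest grade
to the lowest (the `monotone` flag), ranges matching the real magnitudes
(costs 300–12,000, incomes 700–8,000, beds 30–800 per institution,
populations 1e5–1e6, floors 4–7%), and benefit/cost ratios that differ
across grades — with equal ratios every feasible plan is Pareto-optimal and
a test that passes on such instances shows nothing. Generation rejects
draws until the all-maximum plan is feasible, so every generated instance
is solvable by construction. What the generator does *not* emulate: real
demographic structure (populations are scalar knobs), spatial interaction
between districts, or cycle-varying coefficients; a passing suite therefore
validates the optimisation machinery, not any demographic forecast.

`brute_force_pareto()` enumerates all plans within bounds (capped at 1e6
candidates, which keeps the oracle affordable on a desk machine), filters
feasible ones and returns the exact non-dominated set. It is the ground
truth for the solver tests: on twenty generated instances (two grades, two
cycles, cells bounded at 4, ≤ 625 candidate plans) across ten seeds each,
the GA archive is always a subset of the exact Pareto set and the union
across seeds covers at least 90% of it. The suite runs these instances at
population 60 and up to 120 generations; the worked-example and archive-
sizing runs use the published population 100 / fraction 0.8 settings.

## Degenerate inputs and tie-breaks, collected

* Bounds of zero collapse the search to the zero plan; it is returned (and
  flagged infeasible if even that violates the floors).
* A front of ≤ 2 points has all-infinite crowding; zero-range objectives
  contribute zero gap and never divide by zero.
* TOPSIS rejects an all-zero objective column (normalisation undefined),
  scores identical-row archives 0.5, and breaks closeness ties by index.
* Elitist truncation and archive thinning break crowding ties
  lexicographically on the genome, so every run is reproducible.
* Income factors are constrained to (0, 1]; shares to [0, 1] with sum ≤ 1;
  violations are load-time errors, not solver surprises.

## Limitations

The model allocates *counts per grade per cycle* only: no siting, no
cross-district flows, no population forecasting (populations are inputs),
and exactly two objectives. The GA is a metaheuristic — on large instances
the archive approximates the true front rather than guaranteeing it; the
oracle-backed guarantees hold on enumerable instances. Cost and income
coefficients are abstract units; nothing converts them to currency.
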