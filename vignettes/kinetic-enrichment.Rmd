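---
title: "Enriching constraint-based metabolic models with kinetic steady-state fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enriching constraint-based metabolic models with kinetic steady-state fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxbridge)
```

## The problem

Genome-scale constraint-based models describe metabolism as a tuple
{R, M, S, L, U}: reactions, metabolites, a stoichiometric matrix, and
per-reaction flux bounds. Flux balance analysis (FBA) finds a steady-state
flux vector v maximizing an objective c'v subject to S v = 0 and
L <= v <= U; flux variability analysis (FVA) then computes, per reaction,
the minimum and maximum flux compatible with retaining a fraction q of the
optimum. These models scale to whole organisms, but their default bounds
(typically +/-1000 mmol gDW^-1 h^-1) are so loose that predicted flux
distributions are unrealistic: at the optimum most reactions are *dormant*
(both FVA extremes within epsilon of zero), and competing objectives
degenerate into all-or-nothing vertices.

Kinetic models are the complementary formalism: explicit rate laws over
metabolite concentrations, integrated as ODEs d[x]/dt = S f(x). They are
precise and condition-specific but cover only a small pathway subset
(central carbon metabolism, typically).

`fluxbridge` welds the two: it integrates a kinetic model to steady state,
reads off its reaction fluxes f(r) in mM s^-1, and converts them into flux
bound intervals for the mapped reactions of the constraint-based model,

L(r) = c (1 - d) f(r),  U(r) = c (1 + d) f(r),

where d is a relative uncertainty and c converts units. The uncertainty is
multiplicative because fluxes are proportional to Vmax = kcat [E], and
enzyme abundance varies by fold-changes; an interval in d is therefore a
biologically interpretable perturbation of enzyme expression.

## Reaction mapping

The two formalisms rarely state a reaction identically, so mapped pairs
carry a category that decides the translation rule:

| category | difference | translation |
|----------|------------|-------------|
| C0 | none | direct, after unit conversion |
| C1 | small species (H+, H2O) | direct |
| C2 | bicarbonate vs CO2 | direct |
| C3 | reversibility flag | direct (the kinetic bound overrides) |
| C4 | reactants/products swapped | mirrored: [-c(1+d)f, -c(1-d)f] |
| C5 | different subnetwork structure | net-boundary-flux heuristic |

`classify_pair()` validates a candidate pair; mapping tables themselves are
curated by the user (CSV, one row per correspondence). For C5 entries no
single kinetic flux applies, so the package computes the net steady-state
production/consumption of each metabolite the kinetic subnetwork exposes,
divides by the constraint-side stoichiometric coefficient, reconciles by
the median, and translates the implied flux like C0 (C4 if negative). This
heuristic is this package's own choice of rule for subnetwork
correspondences; it is deliberately confined behind
`translate_c5_subnetwork()` and can simply be left out of a mapping table.

## Units and parameters

* **c = 6.372**: a flux of 1 mM s^-1 times a specific cell volume of
  1.77e-3 L gDW^-1 times 3600 s h^-1 equals 6.372 mmol gDW^-1 h^-1. The
  cell volume is an argument (`cell_volume`) everywhere the factor is used.
* **d** (dimensionless, 0 <= d < 1): relative uncertainty of the kinetic
  flux. d = 0 pins the flux exactly (useful for testing); d >= 1 is
  rejected because the lower bound would change sign. Intervals nest as d
  grows and are centred on c f(r).
* **q = 0.999**: FVA fraction of optimum. q = 1 confines the solution to
  the optimal face, which is numerically fragile; 0.999 keeps a sliver of
  slack.
* **epsilon = 1e-2 mmol gDW^-1 h^-1**: dormancy threshold,
  |minF| <= epsilon and |maxF| <= epsilon (inclusive). It sits far above
  the LP tolerance (1e-9) so solver noise cannot flip dormancy.
* **t_end = 3600 s, tol = 1e-6 mM s^-1**: steady-state integration horizon
  and steadiness criterion (max |d[x]/dt| at t_end). If the criterion
  fails at t_end the horizon is extended once by 10x before the result is
  declared non-converged; divergence is never hidden.
* **Km = 0.495 mM, Vmax = 4.06 mM s^-1**: citramalate synthase defaults.
  The Vmax derives from the maximal per-cell activity of the synthase
  (24.34e-10 nmol s^-1) divided by a cell volume of 6e-16 L
  (`compute_vmax_from_cell_activity()`).

## Growth-rate units

The growth "flux" of a biomass reaction is a specific growth rate in h^-1,
not a metabolite flux, so `extract_growth_rate()` reads the kinetic growth
flux as h^-1 directly and `fix_growth_interval()` applies it to the
biomass reaction without the factor c. This is a documented modelling
assumption: the two unit systems genuinely disagree about what a biomass
flux is, and the fixtures are constructed so the convention is
self-consistent (the growth-interval fix and the metabolite-flux
translation never apply to the same reaction with different units).

## The enrichment sweep

`run_enrichment_sweep()` applies translated bounds one reaction at a time,
cumulatively, in the order given (canonically the order of glucose
metabolism; the order is an explicit input, never hard-coded, because it
materially affects where the trajectory bends). After each step it records
the FBA optimum, the dormant-reaction count, and the number of reactions
whose FV(r) = maxF(r) - minF(r) rose or fell relative to the *original*
model's FVA at the same q. Growth is provably nonincreasing along the
sweep (each step only tightens the feasible region). Tightening can
nevertheless *raise* individual FV(r): pinning the favoured pathway forces
flux through formerly dormant alternatives — the "awakening" the metrics
are designed to expose. An infeasible step is recorded as data
(`feasible = FALSE`) and by default ends the sweep; a skip mode drops the
offending bound instead.

## The citramalate extension and the bifurcation

A production strain synthesizes citramalate from acetyl-CoA and pyruvate
(acetyl-CoA + pyruvate + H2O -> CoA + H+ + citramalate). The constraint
model is extended with the synthase (`CIMA`), two irreversible transport
steps (`CitraTransp1`, `CitraTransp2`), and an exchange
(`EX_Citramalate`) that lets product leave the system so a steady state
exists. On the kinetic side, `add_citramalate_synthesis()` appends the
same stoichiometry with a Michaelis-Menten law in acetyl-CoA (pyruvate is
assumed saturating: present in the stoichiometry, absent from the rate
law), with citramalate as a boundary species.

Plain FBA on the extended model is bistable in the objective: maximizing
growth zeroes secretion, maximizing secretion zeroes growth. The kinetic
model cannot do this — its ODEs keep both branch fluxes positive whenever
substrate is present. `fix_growth_interval()` transfers that property by
constraining the biomass flux to [mu_k (1 - d), mu_k (1 + d)], with mu_k
the kinetic growth rate; maximizing secretion then yields strictly
positive growth *and* product flux.

Conversion efficiency is reported in g/g as
(v_cit x 148.11) / (v_glc x 180.16), the molar-mass ratio of citramalate
(C5H8O5) to glucose (C6H12O6). Mass yield from molar fluxes requires some
such weighting; the molar masses are arguments, so any alternative
definition is one call away. When kinetic bounds are applied at an
uncertainty d, the growth interval uses the same d — the natural pairing,
since both encode the same confidence in the kinetic simulation.

## Synthetic fixtures: what they emulate, and what they do not

The package ships generators for matched kinetic/constraint pairs with
closed-form ground truth, used by the test suite and the acceptance
script:

* `make_linear_chain()` — an n-step pathway with constant inflow; every
  steady-state flux equals the inflow k_in, so unit conversion and bound
  translation have exact expected values. The constraint twin adds two
  dead-end reactions that can never carry flux, giving the dormancy
  metrics a known answer (2).
* `make_branch_fixture()` — the growth/product trade-off in miniature:
  first-order branch propensities split the inflow, so the kinetic model
  always feeds both branches, while the constraint twin (glucose through a
  lumped glycolysis with CoA recycling) exhibits the all-or-nothing
  bifurcation under plain FBA. Defaults are tuned to a glucose-limited
  chemostat: inflow 0.23 mM s^-1 and a kinetic growth rate of exactly
  0.1 h^-1.
* `make_category_zoo()` — one reaction pair per mapping category,
  differing in exactly the feature the category names, plus a two-to-one
  C5 chain with net flux 2 mM s^-1. All zoo species are boundary species
  with constant rates, so the model is trivially at steady state.

All generators are deterministic (byte-identical output), and fixtures are
emitted as real SBML/JSON/CSV files so the I/O paths are exercised, not
bypassed. What the fixtures do *not* emulate: genome-scale network
redundancy (thousands of reactions, alternate optima families),
thermodynamically infeasible loops, realistic biomass compositions, or the
degree distribution of a real metabolic network. Passing tests therefore
demonstrate correctness of the algorithms and conservation of the
qualitative phenomena (monotone growth decay, dormancy changes,
bifurcation resolution), not quantitative genome-scale predictions; those
require real model files, which the package reads through the same
`read_constraint_sbml()`/`read_kinetic_sbml()` entry points.

## Numerical choices

* **LP solver.** FBA and FVA are solved by an internal two-phase dense
  simplex with Bland's anti-cycling rule: variables are shifted by their
  lower bounds, upper bounds become slack rows, and the FVA
  optimum-fraction constraint c'v >= q mu gains a surplus variable. All
  variables are box-bounded, so no LP here is unbounded, and problem sizes
  (tens of columns) make dense tableaus and the slow-but-safe Bland rule
  the right trade-off. The suite cross-checks every optimum against
  brute-force vertex enumeration and an external HiGHS solve.
* **Tolerances.** Simplex pivot tolerance 1e-9; phase-1 infeasibility
  declared above 1e-7; steadiness 1e-6 mM s^-1; FVA results clamp
  minF <= maxF against last-digit jitter on pinned reactions. Dormancy and
  variability-change counting use thresholds (1e-2 and 1e-6) far above
  solver noise.
* **Degenerate inputs.** d = 0 and f = 0 produce legal point intervals;
  empty assignment lists, empty models and empty FVA selections return
  empty results rather than erroring; infeasibility in the sweep is data,
  not an exception; negative kinetic fluxes are rejected (orientation
  belongs in the category, not the sign).
* **Alternate optima.** Only optimum values and FVA extremes enter
  reported metrics, so results do not depend on which optimal vertex the
  solver happens to return.

## Worked example

```{r example}
fx <- make_branch_fixture()
ss <- simulate_to_steady_state(fx$kinetic)
mu_k <- extract_growth_rate(ss, "BIO")
mu_k

ext <- set_objective(extend_gem_with_citramalate(fx$gem), "EX_Citramalate")
run_fba(ext)$fluxes[c("BIO", "EX_Citramalate")]          # bifurcated

fixed <- fix_growth_interval(ext, mu_k, d = 0.1, biomass_id = "BIO")
run_fba(fixed)$fluxes[c("BIO", "EX_Citramalate")]        # resolved
```

## Problem sizes

The test suite and the acceptance script run entirely on the fixtures
above: 3-11 reactions per model, sweeps of at most a handful of steps,
FVA over at most ~30 reactions. These sizes make the brute-force oracles
exact and keep the whole suite in seconds while still exercising every
code path the genome-scale workflow uses.

## Known limitations

* The LP backend is dense and unoptimized; genome-scale FVA (thousands of
  reactions) would need an external solver. The module surface would not
  change.
* C5 translation is a heuristic; entries whose constraint-side reactions
  share no boundary metabolite with the kinetic subnetwork are rejected
  rather than guessed at.
* Bound conflicts are resolved by replacement: a kinetic bound overrides
  the original bound even when the two intervals are disjoint (the
  `bound_source` column records which bounds are kinetic).
* The SBML support covers the core + fbc subset the workflow needs; it is
  not a general SBML toolkit (no rules, events, or unit definitions).
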