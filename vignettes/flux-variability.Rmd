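---
title: "Decomposing the sources of metabolic flux variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the sources of metabolic flux variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxvar)
```

## The question the package answers

A genome-scale metabolic reconstruction constrains the steady-state fluxes
`v` of an organism by mass balance, `N v = 0`, and by per-reaction bounds
`alpha_i <= v_i <= beta_i`. The feasible set is a polytope; its size is a
natural measure of the metabolic flexibility available to the cell. When the
environment (uptake bounds) or a physiological requirement (a growth bound)
changes, the polytope shrinks or grows. `fluxvar` quantifies that change and
attributes it to three sources: the intrinsic freedom of the *internal*
reactions, the freedom of the *exchange* (boundary) fluxes, and the freedom
of the *growth* flux.

Flexibility is quantified through flux variability analysis (FVA): for each
reaction, the minimum and maximum flux attainable under the constraint set.
Relative to reference ranges `[V_i_min, V_i_max]` computed once under a
reference medium with everything free, a condition with ranges
`[j_i_min, j_i_max]` gets

```
Delta = mean over admissible internal i of
        (j_i_max - j_i_min) / (V_i_max - V_i_min)
```

`Delta` is 1 at the reference by construction, 0 when every internal
reaction is pinned, and lies in `[0, 1)` whenever the condition's feasible
set is nested inside the reference set. The decomposition fixes, in turn,
(a) growth and the exchange fluxes at an optimal-growth solution
(`Delta_int`), (b) growth only (`Delta_int+ext`), (c) nothing
(`Delta_tot`), and defines `Delta_ext` and `Delta_gro` as the successive
differences, so

```
Delta_tot = Delta_int + Delta_ext + Delta_gro
```

holds exactly, by construction, in every result this package returns.

## Reaction classes and sign conventions

The growth class is the single designated biomass reaction. Reactions whose
stoichiometric column touches exactly one metabolite are boundary reactions
— exchanges, sinks, demands — and are classed *external*; everything else,
including ATP-maintenance pseudo-reactions (which touch several
metabolites), is *internal*. Whether non-biomass sinks should count as
external is genuinely open; we class them external because they move matter
over the system boundary exactly like an exchange does, and the admissible
set reported with every result makes the effective internal count visible.

Models store fluxes in their native orientation (BiGG convention: a
negative exchange flux is uptake). Every user-facing quantity — medium
limits, scanned grids, coordination results — is a positive uptake
magnitude; the conversion happens exactly once, at the medium/report
boundary, using the sign of the exchange's single stoichiometric entry.
This lets the same code run models with either exchange orientation.

## The admissible set

The `Delta` average divides each condition width by the reference width,
which is undefined for reactions the reference medium already blocks or
pins (width 0). We exclude those reactions from both the numerator and the
divisor — the only division-safe reading — and report the admissible count
alongside every result. `delta_measure(..., include_pinned = TRUE)`
switches to dividing by the full internal count for sensitivity analyses;
on media where few reactions are blocked the two readings differ by a
near-constant factor.

## The Sigma companion measure

`Sigma` is the spread (max minus min) of the *summed* internal flux under a
condition, relative to the same spread at reference. It needs only two LPs
per condition, against two per internal reaction for `Delta`, and is
exposed as an opt-in companion (`sigma = TRUE` in
`decompose_variability()`), never a substitute. Note the reading: the
extremes of the sum, not the sum of the per-reaction extremes — the two
differ whenever reactions cannot reach their individual extremes jointly,
and only the former is computable in two LPs.

## Linear programming backend

All operations reduce to LPs over `N v = 0` with box bounds: growth
maximization (FBA), per-reaction min/max (FVA), Manhattan-distance
minimization to a reference flux distribution (linear MoMA, via split
non-negative deviation variables), and single-flux minimization. The
package ships its own bounded-variable two-phase primal simplex with
Bland's smallest-index pivoting. That choice is about determinism as much
as correctness: Bland's rule terminates on the heavily degenerate bases
FVA produces, and a fixed pivot rule plus a fixed variable order (the
model's reaction order) make the returned optimal *vertex* reproducible
run to run. This matters because the external fluxes at optimal growth are
degenerate in general; the vertex actually used is recorded in results and
run manifests, and `decompose_variability(vext_override = ...)` lets you
probe alternative optima directly. Individual `Delta_int`/`Delta_ext`
values may shift across optima, but their sum and `Delta_gro` are
invariant — a property the test suite asserts on a network built so that
two optimal external patterns genuinely differ.

Numerical choices: infinite bounds are clamped to `1e6` when an LP is
assembled, and an FBA optimum reaching half that clamp is reported as
unbounded rather than returned; mass-balance residual, bound-violation and
zero-width thresholds are all `1e-9`; fixing a flux means `lb = ub =
value` exactly, with an optional relative slack `gamma` on the growth
optimum (default 0 — exact fixing is what the decomposition specifies, and
the exact-arithmetic-scale problems the solver targets do not need slack).

The dense, pure-R simplex targets desk-scale networks — toys, curricula,
method development — where every answer can be cross-checked by
enumeration. Genome-scale reconstructions load and validate through the
same interfaces (the readers handle BiGG JSON and SBML Level 3 + FBC), but
running thousands of genome-scale LPs wants a sparse industrial solver;
that is the package's main known limitation.

## Condition scans

`scan_uptake()` pins an exchange at each grid value and recomputes the
decomposition; the reference is computed once from the base medium and
never per point, so all points share one normalization. Scanning past the
medium's uptake limit is allowed by design (with a warning): probing
whether conclusions depend on where the physiological range ends requires
leaving it. Default grids are 20 evenly spaced points over the
physiological ranges (glucose to 10, oxygen to 40, ammonia to 20); grid
density is a parameter, not a result. Which reference should normalize an
anaerobic scan is ambiguous; we default to the scan's own base medium and
accept an explicit `reference` argument, so normalizing anaerobic
conditions against the aerobic reference — under which the anaerobic total
is well below 1 — is a one-argument choice.

`scan_growth_bounds()` restricts growth four ways: capping it
(`upper_bound`), requiring it (`lower_bound`, with the cap at the
maximum), pinning it (`both_bounds`), or limiting it indirectly through
carbon uptake (`glucose_limited`). On the toys the lower-bound and
both-bounds curves differ (pinning removes the growth range itself), so
their near-identity on real networks is treated as an empirical report,
not an assertable invariant.

## Carbon–nitrogen coordination

The two-stage procedure in `coordinate_carbon_nitrogen()` emulates the
regulatory mechanism that matches glucose consumption to nitrogen-limited
growth (alpha-ketoglutarate inhibition of the phosphotransferase system):
with ammonia uptake pinned, maximize growth, then minimize glucose uptake
subject to growth staying at that maximum. Imposing the resulting glucose
pin during an ammonia scan collapses `Delta_int` and `Delta_ext` to zero
on the two-substrate toy — exactly, at solver tolerance — leaving growth
variability as the only component, which is the qualitative heart of the
growth–flexibility trade-off.

## Adaptation and reorganization

`adapt_moma_scan()` models adaptation between uptake states as minimal
flux adjustment: from the optimal-growth state at carbon uptake 10, each
final state pins a lower uptake and takes the feasible flux vector of
minimal Manhattan distance, with growth either free or pinned at the final
state's maximum. Freeing growth can only shrink the distance (feasible-set
containment; asserted on every tested grid point). Reorganization is
counted as fluxes whose magnitude more than doubles or falls below one
tenth of the initial value — the asymmetry reflects that the summed flux
scales roughly with uptake, biasing transitions toward decreases. How
zero-initial or sign-flipping fluxes should count is unstated in the
counting rule itself; we compare magnitudes and exclude initial
magnitudes below `1e-6`, report the eligible count so the exclusion is
visible, and provide `count_new = TRUE` to count activations as increases.
On the monotone toy topologies the growth-free and growth-fixed
adaptations coincide — growth there is stoichiometrically pinned by carbon
uptake, the same fact behind the steady-state redundancy property — so the
strong growth-fixed/growth-free contrast is a genome-scale observation the
package reports rather than asserts at desk scale.

## What the toys emulate, and what they do not

The three presets reproduce, at hand-computable scale, the structural
features the analysis depends on: a bounded carbon source, internal branch
redundancy (so internal variability exists), a biomass drain (so growth
variability exists), a maintenance demand option (so a minimum feasible
uptake exists), and a second substrate with overflow routes (so uptakes
can decouple and coordination has something to remove). Their golden
answers — the branched decomposition `(0.75, 0, 0.25, 1.0)`, the growth
scans `0.375`/`0.875`, the chain MoMA distance 15, the coordination pair
`(5, 5)` — are hand LP results frozen into tests and independently
confirmed by a brute-force oracle that grid-enumerates the polytope over
the free coordinates of the reduced stoichiometric system, sharing no code
with the simplex. The oracle is an inner approximation guaranteed within
one grid step, and it refuses more than three degrees of freedom rather
than approximating badly.

Passing these tests shows the machinery is correct on networks whose
answers are known exactly. It does not show that any particular published
genome-scale number will reproduce: those depend on the exact medium bound
set (the packaged glucose minimal medium follows BiGG iJO1366 defaults and
is user-overridable precisely because published medium specifications are
often incomplete), on reconstruction versions, and on solver-dependent
choices among degenerate optima.

## Problem sizes used in the shipped checks

Unit and property tests run on the presets (3–8 reactions), a 5-reaction
twin-route network, and randomized chain-with-branch networks (seeded, 5–7
reactions; used only for fuzzing invariants, never for golden values).
Oracle sweeps use grid resolutions of 0.1 (one- and two-dimensional
polytopes) and 0.5 (three-dimensional), with equality tolerances equal to
the resolution. The acceptance script recomputes the reference-condition
`Delta` of the branched toy from scratch.
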