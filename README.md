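# fluxvar

Constraint-based analysis of metabolic flexibility: where does flux
variability come from, and what does it cost in growth?

A genome-scale metabolic model constrains steady-state fluxes by mass
balance (`N v = 0`) and per-reaction bounds (`α_i ≤ v_i ≤ β_i`). The size
of the resulting flux polytope measures the repertoire of responses the
organism can display. `fluxvar` quantifies changes in that repertoire with
the **Δ measure** — the average, over internal reactions with nonzero
reference range, of each reaction's FVA range relative to its range under
a reference medium —

```
Δ = (1/|A|) Σ_{i ∈ A} (j_i^max − j_i^min) / (V_i^max − V_i^min)
```

and decomposes it into additive **internal**, **external** and **growth**
components by successively fixing the growth flux and the exchange fluxes
at an optimal-growth solution:

```
Δ_tot = Δ_int + Δ_ext + Δ_gro        (exact, by construction)
```

Around this core the package provides:

- **Model I/O**: BiGG-style JSON and SBML Level 3 + FBC readers, a JSON
  writer, YAML medium specifications, and a packaged glucose minimal
  medium. Uptake is always a positive magnitude user-side, regardless of
  how the model signs its exchanges.
- **LP engine**: FBA, FVA, linear MoMA (Manhattan-distance minimal
  adjustment) and single-flux minimization on a deterministic
  bounded-variable two-phase simplex (Bland's rule), so degenerate optima
  resolve identically run to run.
- **Scans**: uptake-rate sweeps with per-point decomposition, growth-bound
  sweeps (upper / lower / pinned / carbon-limited), and the two-stage
  carbon–nitrogen coordination procedure (maximize growth at fixed
  ammonia uptake, then minimize glucose uptake at that growth).
- **Reorganization**: MoMA adaptation between uptake states with counting
  of fluxes that more than double or drop below one tenth.
- **Verification**: deterministic toy networks with hand-computable
  answers and an LP-independent brute-force polytope oracle.

## Worked example

Decompose the variability of the branched toy network (one uptake, a stem,
two parallel routes, biomass) at its reference condition:

```r
library(fluxvar)

model <- make_toy("branched")
ref   <- compute_reference_ranges(model)
decompose_variability(model, ref)
#> <variability_components>
#>   delta_int = 0.7500  delta_ext = 0.0000  delta_gro = 0.2500  delta_tot = 1.0000
#>   vgro_max = 10.0000 over 4 admissible internal reactions
```

Reading: at the reference uptake limit (10), total variability is 1 by
definition. Three quarters of it survives even with growth and all
exchanges pinned at the optimal-growth solution (the free split between
the two internal routes), none is contributed by the exchanges (the single
uptake is forced by optimal growth), and one quarter is contributed by the
freedom of the growth flux itself. Restricting growth trades flexibility
for growth:

```r
scan_growth_bounds(model, mode = "both_bounds", fractions = c(0, 0.5, 1),
                   reference = ref)[, c("fraction", "vgro", "delta_tot")]
#>   fraction vgro delta_tot
#> 1      0.0    0     0.000
#> 2      0.5    5     0.375
#> 3      1.0   10     0.750
```

And coordinating carbon with nitrogen uptake on the two-substrate toy
removes internal and external variability entirely:

```r
toy3 <- make_toy("two_substrate")
coordinate_carbon_nitrogen(toy3, v_nh4 = 5,
                           n_exchange = "EX_N", c_exchange = "EX_C")
#> <cn_coordination> v_NH4 = 5 -> v_gro_max = 5, v_Glc_min = 5
```

A command-line front end with the same operations (subcommands `fba`,
`fva`, `decompose`, `scan-uptake`, `scan-growth`, `reorganize`, `toy`;
TSV results plus JSON run manifests) ships as
`inst/cli/fluxvar.R`:

```sh
Rscript inst/cli/fluxvar.R toy --preset branched --out toy2.json
Rscript inst/cli/fluxvar.R decompose --model toy2.json --out-dir out
```

See the vignette (`vignettes/flux-variability.Rmd`) for the model, the
measures, the degenerate-optimum treatment, and the package's limitations
(the dense pure-R simplex targets desk-scale networks).

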