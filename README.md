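# fluxscreen

Constraint-based reconstruction and analysis (COBRA) of metabolic models in
R, built around a composable, parallel **variant-screening** framework.

Genome-scale metabolic models describe an organism as a constrained linear
system: a stoichiometric matrix *S* over metabolites × reactions, flux
bounds *l ≤ v ≤ u*, and boolean gene–protein–reaction (GPR) rules gating
reaction availability. At steady state *S v = 0*, and the classic analyses
are linear programs over that polytope:

- **FBA** — maximize an objective *cᵀv* (growth, product export);
- **FVA** — per-reaction flux minima/maxima subject to retaining a fraction
  γ of the optimum (*cᵀv ≥ γZ\**);
- **gene deletion screens** — FBA after forcing reactions whose GPR fails
  to bounds (0, 0), for single genes or pairs;
- **production envelopes** — extremes of a target flux as another reaction
  is swept across its feasible range.

Where most toolkits hard-wire parallelism into a few chosen methods,
fluxscreen separates *what varies* from *what is computed*: serializable
model **variants** (knockouts, bound changes, objective changes) form
Cartesian grids, any registered analysis runs on every variant of a base
model through a worker pool, and the outputs land in a dense
multi-dimensional **result array** — deterministically, whatever the worker
count. Composing a new screen (say, FVA inside every knockout) takes one
call instead of a bespoke reimplementation.

The package reads and writes the COBRA JSON dialect, reads SBML Level 3
`fbc`, joins member models into multi-organism community models sharing an
environment compartment, ships deterministic fixture generators with
closed-form optima, and includes its own bounded-variable simplex backend
(Rcpp) behind a narrow, swappable solver seam.

## Worked example

A branched fixture: substrate → intermediate, an efficient product branch
(yield 1, gated by isozymes `gP or gP2`) versus a wasteful ungated branch
(yield 0.5), objective on product export.

```r
library(fluxscreen)

m <- make_branched(10, 1, 0.5, gene_gating = TRUE, isozyme = TRUE)
fba(m)
#> <flux_solution> status: optimal   objective: 10
#> EX_S_e    UPT  PCONV  WCONV EX_P_e EX_W_e
#>     10     10     10      0     10      0
```

All 10 units of substrate run through the efficient branch. Single
deletions show `gU` (gating uptake) is essential — zero growth, reported as
`optimal` with objective 0, distinct from `infeasible` — while each isozyme
alone is dispensable:

```r
single_gene_deletion(m)
#>   gene  status objective
#> 1   gU optimal         0
#> 2   gP optimal        10
#> 3  gP2 optimal        10
#> 4   gX optimal        10
```

The screening framework composes knockouts with FVA in one call — each
cell applies its variant to a fresh copy of `m` and runs the analysis as an
independent task (`workers = n` parallelizes without changing any value):

```r
r <- screen(m, list(list(variant("wt"),
                         variant("koP", mod_knockout(c("gP", "gP2"))))),
            analysis = "fva", args = list(gamma = 1))
subset(r$values[[2]], reaction %in% c("PCONV", "WCONV", "EX_P_e", "EX_W_e"))
#>   reaction minimum maximum status_min status_max
#> 3    PCONV       0       0    optimal    optimal
#> 4    WCONV      10      10    optimal    optimal
#> 5   EX_P_e       5       5    optimal    optimal
#> 6   EX_W_e      10      10    optimal    optimal
```

With both isozymes knocked out the efficient branch is pinned to zero and
flux reroutes through the wasteful branch at half yield: the synthetic
lethal pair drops the optimum from 10 to 5. A production envelope
quantifies the same trade-off continuously — with a pure waste branch
(`yield_w = 0`), every exported waste unit displaces one substrate unit
from the product branch:

```r
production_envelope(make_branched(10, 1, 0), "EX_P_e", "EX_W_e", n_points = 3)
#>   level target_min target_max status_min status_max
#> 1     0          0         10    optimal    optimal
#> 2     5          0          5    optimal    optimal
#> 3    10          0          0    optimal    optimal
```

A command-line interface over the same functions lives at
`inst/cli/fluxscreen.R` (subcommands `convert`, `fba`, `fva`, `deletions`,
`envelope`, `screen`, `join`, `fixture`; TSV to stdout, `--json` for a
machine envelope; exit codes 0 success / 1 usage / 2 infeasible / 3
missing environment).

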