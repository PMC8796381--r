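---
title: "Constraint-based modeling and parallel variant screening with fluxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling and parallel variant screening with fluxscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscreen)
```

## The model

fluxscreen treats an organism's metabolism as a constrained linear system.
A genome-scale model lists $m$ metabolites and $n$ reactions; the
stoichiometric matrix $S \in \mathbb{R}^{m \times n}$ holds the coefficient
of metabolite $i$ in reaction $j$ (negative = consumed, positive =
produced). At steady state, every internal metabolite's production balances
its consumption, and each reaction's flux $v_j$ (mmol gDW$^{-1}$ h$^{-1}$)
is confined to bounds that encode reversibility, enzyme capacity and medium
composition:

$$ S v = 0, \qquad l \le v \le u . $$

**Flux balance analysis (FBA)** maximizes a linear objective $c^\top v$ —
typically biomass or product export — over this polytope. **Flux
variability analysis (FVA)** asks, reaction by reaction, how much freedom
the optimum leaves: it first computes the optimal value $Z^\*$, then
minimizes and maximizes each flux $v_j$ subject to the additional
constraint $c^\top v \ge \gamma Z^\*$, where the *optimum fraction*
$\gamma \in [0, 1]$ (default 1) dials how much of the optimum must be
retained. **Gene deletion screens** evaluate each reaction's
gene–protein–reaction (GPR) boolean rule with a chosen gene set marked
absent, force the bounds of unavailable reactions to $(0, 0)$, and re-run
FBA. **Production envelopes** sweep one reaction's flux across its feasible
range and record the extremes another reaction can reach at each level —
the classic phenotype phase plane, reported as a table.

Three design points deserve emphasis:

* The $\gamma$ requirement is imposed as a linear constraint on the
  *objective expression*, never by clamping the bounds of "the objective
  reaction": the two are equivalent only when the objective involves a
  single reaction. When $Z^\* = 0$ the constraint degenerates to
  $c^\top v \ge 0$ for every $\gamma$; this is documented behaviour and not
  special-cased.
* Deletion screens distinguish *zero growth* (status `optimal`, objective
  0: a feasible model that cannot grow) from *infeasible* (no steady-state
  flux distribution at all, objective `NA`). Coercing the latter to 0 would
  discard information, so neither is ever converted into the other.
* Metabolic LPs are massively degenerate: alternate optima are the rule.
  Only the objective value and FVA bounds are deterministic quantities; the
  flux vector returned by `fba()` is *one* optimal vertex and carries no
  uniqueness contract. Tests and downstream analyses respect this.

## The LP solver

No LP solver is a hard dependency of this package's interface: the solve
seam is deliberately narrow (constraint matrix, bounds, objective in;
status, objective value, primal vector out) so backends can be swapped.
The built-in backend is a dense bounded-variable two-phase primal simplex
written in C++ (Rcpp/RcppArmadillo). It handles variable bounds natively
(including infinite ones), prices with Dantzig's rule and falls back to
Bland's rule after a fixed iteration budget to rule out cycling, and
reports `optimal`, `infeasible` or `unbounded` faithfully. The default
tolerances — feasibility $10^{-9}$, reduced-cost $10^{-9}$, both
configurable via `lp_tolerances()` — match common LP-solver defaults;
optimal solutions are additionally checked against the steady-state
residual $\lVert S v \rVert_\infty \le 10^{-6}$. A dense tableau is the
right trade-off at the scales this package targets (up to a few hundred
reactions); genuinely genome-scale work (tens of thousands of reactions)
would need a sparse factorized backend behind the same seam.

The test suite cross-checks this backend against an *independently coded*
oracle: a pure-R two-phase full-tableau simplex over the explicit standard
form (shifted variables, hand-added slacks, Bland's rule throughout), with
the equality matrix rebuilt directly from the per-reaction stoichiometry
dictionaries. Implementation and oracle agree to ~$10^{-14}$ over hundreds
of randomized models and all FVA settings, which is the package's main
correctness argument.

## The screening framework

The architectural core is the separation of *what varies* from *what is
computed*. A `variant()` is a label plus an ordered list of plain-value
transformation descriptors — `mod_knockout()`, `mod_bounds()`,
`mod_objective()` — applied left-to-right to a fresh copy of a base model.
Descriptors are data, not closures, so variants serialize cleanly, appear
verbatim in logs, and can cross process boundaries. `variant_grid()` forms
the Cartesian product of one variant list per axis; `screen()` applies each
grid cell's variant to the base model, runs a *registered* analysis on the
variant model, and assembles the outputs into a dense array whose axes are
the grid axes.

The contract that makes this safe to parallelize:

* model edits never mutate their input (verified by byte-comparison in the
  tests), so concurrent tasks can share the base model;
* analyses are referenced by registry name plus serializable keyword
  arguments, never by closure;
* cells are enumerated in row-major order (last axis fastest) and that
  ordering is part of the interface, so array indices are stable across
  versions and worker counts;
* the assembled result is a pure function of (model, grid, analysis):
  byte-identical for 1, 2 or any number of workers.

Execution uses a fork-based worker pool (`parallel::mclapply`) on a single
machine; results are collected in task order regardless of completion
order. Multi-node transports are out of scope — the portable content is
the task decomposition (one serializable variant/analysis pair per cell;
FVA further splits into one LP per task), not any particular scheduler.
`screen()` aborts on the first failing cell; `screen_fallible()` stores a
structured error value (code, message, variant label) in failing cells and
completes the rest, which is what long campaigns over flaky subproblems
need. No cell is ever silently missing. No built-in analysis is
stochastic, but `screen(seed =)` threads a per-cell seed (base + cell
index) so user-registered stochastic analyses stay reproducible.

## GPR rules

The GPR grammar follows the dominant COBRA convention, which no standard
pins down formally: identifiers are maximal runs of non-whitespace
characters excluding parentheses; `and`/`or` are case-insensitive
keywords; `and` binds tighter than `or`; there is no negation; the empty
string is the always-satisfied rule. Parse errors report a character
offset. Consecutive same-operator applications are flattened into n-ary
nodes, which makes `parse_gpr()` and `deparse_gpr()` mutually inverse —
the property that keeps GPR strings stable across file-format round trips.
`eval_gpr()` is checked against brute-force truth-table evaluation of
independently translated expressions on randomized rules.

## File formats

The COBRA JSON dialect (the COBRApy interchange schema, v1) is the
canonical read/write format. Reading fills missing bounds with $(0, 1000)$
— the conventional irreversible defaults; the dialect has no reversibility
flag, a reaction is reversible exactly when its stated lower bound is
negative. Writing emits keys in a fixed order at 17 significant digits, so
serialization is deterministic and numerically exact for binary64; the
write/read round trip is lossless for every structural model field.
Unknown top-level keys are preserved in the model's annotations and
re-emitted. SBML Level 3 with the flux-balance-constraints package (fbc,
v2) is read-only from the user's perspective: bounds resolve through
parameter references (a dangling reference is an error naming the
reaction; when both a `reversible` attribute and bound parameters exist,
parameters win), the active objective comes from `fbc:listOfObjectives`,
GPRs from `fbc:geneProductAssociation` trees, and species flagged
`boundaryCondition="true"` are excluded from the constraint set (no matrix
row). A minimal internal SBML serializer exists so the fixture generators
can materialize format twins of the same model for cross-format
equivalence tests; JSON remains the canonical write format. The COBRA
MATLAB dialect is detected by `detect_format()` but not parsed: this build
has no MAT-file reader, and the dialect was an optional tier from the
start.

## Community models

`join_models()` implements one standard convention for multi-organism
community construction — the literature has several, so the choice is
documented plainly. Each member keeps its entire network with ids prefixed
`memberId#` (the `#` is reserved and validated). For every shared
metabolite X, an environment metabolite `X_env` is created together with
an environment exchange `EX_X_env` (stoichiometry `{X_env: -1}`, bounds
from the specification, so negative flux imports into the shared
compartment). Each member's exchange reaction for X — exchange detection
is structural, a reaction touching exactly one metabolite, with the `EX_`
naming convention accepted only as a hint — is rewired into a transfer
between the member's X and `X_env`, with the environment-side coefficient
scaled by the member's normalized abundance. Member fluxes thus stay per
unit of member biomass while environment totals are community-weighted.
Shared-metabolite matching strips the conventional extracellular suffixes
(`_e`, `[e]`) and can be overridden per member. The resulting matrix is
block-diagonal over members except for the environment rows and columns, a
structure the tests assert directly. Abundances are relative weights
normalized to sum 1; dynamic community simulation and abundance fitting
are out of scope.

## Synthetic fixtures as study conditions

The package is exercised exclusively on generated models with closed-form
answers; no external model repository is required or bundled. The
generators fix the study conditions used throughout tests and the
acceptance script:

* `make_chain(n, u)`: a linear pathway whose optimum is the uptake bound
  `u`; at $\gamma = 1$ every flux range collapses to `[u, u]`.
* `make_branched(u, y_p, y_w, ...)`: an efficient product branch (yield
  `y_p`, optionally gene-gated by `gP` or the isozyme pair `gP or gP2`)
  against an ungated wasteful branch that still makes the product at yield
  `y_w` while excreting one waste per substrate; optimum
  `u * max(y_p, y_w)`. Defaults (u = 10, y_p = 1, y_w = 0.5) give the
  canonical numbers: wild type 10, efficient-branch knockout 5, isozyme
  singles 10, synthetic-lethal pair 5. With `y_w = 0` the wasteful branch
  makes no product and the three-point production envelope over waste
  levels 0/5/10 caps the product at 10/5/0.
* `make_diamond(u)`: two interchangeable routes; each spans `[0, u]` at
  the optimum while their sum is pinned.
* `make_random_viable(p, l, seed)`: `p` independently parameterized
  pathways (random capacity in [1, 10], random yield in [0.25, 2], random
  single-gene or isozyme gating) drawing on one shared substrate whose
  uptake bound is the sum of capacities, so the analytic optimum is
  $\sum_p \mathrm{cap}_p \cdot y_p$ and every gene deletion has a
  closed-form effect. One seed, one model, byte for byte; the generator
  guards the caller's RNG state.

These fixtures emulate the *stoichiometric* structure of real models
(exchange prefixes, compartment suffixes, isozymes, capacity bottlenecks)
but not their scale, loops, cofactor coupling or growth-associated
maintenance. Passing tests therefore demonstrate correctness of the
algorithms on well-posed inputs, not biological realism of any particular
reconstruction.

Problem sizes were chosen so the full verification remains comfortable on
one CPU: 200 random models for the FBA/oracle comparison, 55 fixtures
times four $\gamma$ values for FVA (about 1 650 range comparisons), 24-cell
screens for determinism, and a ~100-reaction fixture for the scale check
(12 pathways of length 7), which completes FVA in well under a second.

## Known limitations

Dense linear algebra bounds practical model size to a few hundred
reactions. No thermodynamic/loopless constraints, flux sampling,
parsimonious FBA, MOMA or quadratic objectives. SBML writing is
intentionally minimal and fbc-only; SBML groups/annotations/notes are not
interpreted. Community joining supports a single shared environment
compartment. The CLI (`inst/cli/fluxscreen.R`) is a thin veneer over the
exported functions with stable exit codes (0 success, 1 usage/validation,
2 infeasible/unbounded, 3 missing environment) and is not a scheduler.
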