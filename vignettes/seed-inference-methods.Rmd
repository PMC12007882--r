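---
title: "Seed inference: models, engines and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed inference: models, engines and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedkit)
```

seedkit answers an inverse question about metabolism: which metabolites,
assumed available from the environment, suffice to make a metabolic
objective satisfiable in a genome-scale metabolic network (GSMN)? This
vignette is the package's own account of the underlying models, the solving
engines and their guarantees, the tunable parameters, and the places where
the design was genuinely open and a choice had to be made.

## Two notions of "satisfiable"

**Boolean producibility (network expansion).** Starting from a seed set
$S \subseteq M$, a reaction activates once all of its reactants are
reachable, and its products then become reachable; the *scope*
$\mathrm{Scope}(N, S)$ is the least fixed point of this operator. The
computation is purely structural: stoichiometric coefficients and flux-bound
magnitudes are ignored (scaling them leaves the scope unchanged, a property
the test-suite asserts). The Boolean seed problem asks for
$T \subseteq \mathrm{Scope}(N, S)$, where the target set $T$ is derived from
the objective: the reactants of the objective reaction in target mode, an
explicit metabolite list, or all metabolites in full-network mode.

Boolean producibility over-approximates what a steady-state flux can do. The
optional *no-accumulation* constraint tightens it: every scope metabolite
must be consumed by at least one activated reaction. It is a qualitative
surrogate of mass balance, cheap to check, but still weaker than a linear
program — it counts consumption, not quantities.

**Flux validity (FBA).** A seed set is flux-valid when the linear program
$\max \nu_{obj}$ subject to $X\nu = 0$ and bound constraints, solved on a
*validation copy* of the original model, attains an objective flux above
`flux_epsilon`. The validation copy closes every pre-existing import route
(negative lower bounds of productless boundary reactions are raised to zero,
reactant-less import reactions are capped at zero) so the candidate seeds
are the model's only inputs, then injects the seeds: an extracellular seed
with an exchange reaction has its import bound reopened; every other seed
receives a fresh reversible sink $m \leftrightarrow \emptyset$. Validation
deliberately runs on the *original* network, not the normalized one, so
stoichiometry and reversibility match the published model semantics.

## Normalization

The Boolean view needs unambiguous reactants and products; SBML models speak
flux bounds. Reconciliation applies four rewrites, in this order, to each
reaction: zero-bound reactions are deleted; reactions with
$\nu_{max} \le 0$ are written backwards; reversible reactions
($\nu_{min} < 0 < \nu_{max}$) are split into a forward copy
$[\max(0, \nu_{min}), \nu_{max}]$ and a reverse copy $[0, -\nu_{min}]$; and
the import direction (reverse copy) of exchange and sink reactions is
dropped — or kept as an explicit $\emptyset \to m$ reaction under
`keep_import = TRUE` — because an open import would silently act as a seed
during inference. Demand reactions only consume and are never blocked; sinks
are treated uniformly with exchanges, the two being the same pattern in
different compartments. Splitting alone preserves the flux polytope's
projection onto the objective (asserted on random networks); import blocking
intentionally does not. Reverse copies are named `<id>_rev` (then `_rev2`,
… on collision), and a provenance table maps every surviving reaction to
its original and direction, so results can always be reported in the input
model's vocabulary.

## Candidate pools

Every subset-minimal Boolean solution lies inside the backward closure of
the targets (targets, plus reactants of any reaction producing a member,
iterated to a fixed point) — so that closure is the reasoning candidate
pool, and targets themselves are admissible seeds (a target nothing produces
can only be satisfied by seeding it). Hybrid solutions may additionally need
seeds whose only role is to *drain* an accumulating by-product through their
injected sink; such metabolites necessarily lie in the scope of the backward
closure, so the hybrid pool is the closure united with its own scope. This
is the package's design choice where a purely Boolean argument gives no
bound; it is what lets the guess-and-check engine find, e.g., `{A, C}` on
the trap fixture when `{A}` alone fails flux validation.

In full-network mode, *external* metabolites — consumed somewhere but
produced by no reaction, or only by transport reactions (same base molecule,
different compartments) — are forced seeds, and the pool is every metabolite
outside their initial scope, plus the forced seeds. Transport detection uses
the base-identifier convention (species id stripped of its trailing
compartment token), there being no operational definition in SBML itself.

## Engines and their guarantees

*Reasoning.* The Boolean predicate is monotone, so subset-minimal solutions
are enumerated by a hitting-set search: each found solution must lose at
least one non-forced element; if the remaining pool is still feasible it is
shrunk (greedy single deletions, lexicographic, repeated to stability —
1-minimality equals subset-minimality for monotone predicates) into a
provably new minimal solution; infeasible exclusion branches are memoized
and stay valid as constraints accumulate. Exhaustion of the search is a
proof that no further minimal solution exists, which is what lets an
`unsatisfiable` status be distinguished from `timeout`.

*Guess-and-check (hybrid).* Secondary checks — FBA, and no-accumulation,
which is **not** monotone (a larger scope can strand a new by-product) — are
layered on through a cardinality-ordered queue primed with all Boolean
subset-minimal sets. A popped set failing the check is rejected *exactly*
and its one-element extensions re-enter the queue; a passing set is emitted
and all its supersets are discarded. Cardinality-ordered processing makes
every emitted set subset-minimal for the joint problem, and a run to
exhaustion emits exactly the globally minimal joint solutions: any joint
solution reaches the queue through a chain of single extensions from some
Boolean-minimal set, and any proper subset that could disqualify it is
processed first. The brute-force oracle (direct subset walk in increasing
cardinality) confirms this equivalence on ensembles of random networks.

*Diversification.* Ties among equal-cardinality queue entries are broken
towards seeds least used in previously emitted solutions (then
lexicographically, for determinism). This provably cannot affect soundness
or minimality — it only permutes entries within a cardinality level — and
empirically widens the union of seeds seen in a truncated enumeration,
which is what matters when solutions feed experimental media design.

*Full hybrid search.* A direct in/out search over candidates checks linear
feasibility on partial assignments: the optimistic seed set (included plus
undecided) is tested for both reachability and positive flux, and both
checks being monotone, a failing branch is pruned without losing solutions.
Nodes whose included set is already jointly feasible are recorded and their
supersets skipped. The mode refuses networks beyond 200 reactions (unless
forced): intertwining an LP with every branching decision does not scale to
genome-sized models, and the scalable route is precisely the guess-and-check
decomposition above.

*Optimization.* `subset_minimal` is the default and the recommended setting:
it yields a richer solution family. `minimize` filters the enumeration to
globally smallest cardinality; the cardinality-ordered queue makes the
cut-off exact (processing stops once popped sets exceed the first accepted
size).

## The LP layer

No linear-programming package being a dependency the package could rely on,
the flux module carries its own dense two-phase primal simplex with Bland's
anti-cycling rule (smallest-index entering, smallest-basic-index leaving).
Bland's rule makes the solver fully deterministic and guarantees finite
termination — properties the guess-and-check loop depends on, since a flux
verdict that flips between calls would corrupt the blocking store. Upper
bounds enter as explicit slack rows, so phase 1 always starts from an
identity basis; the reduced-cost row is recomputed from the tableau at every
iteration (cheap at these sizes, and free of accumulation drift); a
feasibility audit re-checks the returned vertex against bounds and
steady-state residuals at tolerance `1e-6` (relative). FBA problems here are
always box-bounded — infinite bounds are encoded as ±1000, the conventional
default — so unboundedness cannot occur and the only LP outcomes are
optimal and infeasible.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flux_epsilon` | `1e-6` | objective flux above which a seed set counts as flux-valid; must dominate LP noise (`lp_tolerance`, `1e-9`) |
| `injected_sink_bounds` | `[-1000, 1000]` | bounds of sinks created for seeds, and the reopened import bound; the COBRA default bound |
| `keep_import` | `FALSE` | keep import directions as explicit `∅ → m` reactions instead of blocking them |
| `no_accumulation` | `FALSE` in target mode, `TRUE` in full-network mode | the qualitative steady-state surrogate; the full-network default reflects that reaching *all* metabolites without consuming them is rarely the intended question |
| `max_solutions` | `10` | enumeration cap; engines report `solution_limit` vs `exhausted` honestly |
| `time_budget` | `Inf` | cooperative deadline, checked between solver steps; partial results are flagged `timeout`, never silently truncated |

A negative objective coefficient in an SBML model (a minimization
objective) is flagged with a warning and otherwise kept as declared; the
intended semantics of such models is ambiguous and guessing silently seemed
worse.

## Synthetic networks: what they emulate, what they do not

`generate_random_network()` grows a random reactant/product structure
outward from a set of exchanged metabolites, guaranteeing the biomass
reaction is reachable from the exchange set — so every generated instance
has at least one Boolean solution, and property tests never vacuously pass
on unsatisfiable inputs. Reactions draw 1–3 reactants and products with
small integer stoichiometry; a configurable fraction is reversible. The
test-suite and the acceptance script use ensembles at 10 metabolites / 15
reactions (candidate pools ≤ 12, so the brute-force oracle stays exact) and
a single larger 18/36 instance for diversity comparisons, sizes chosen so
the exhaustive dual-route checks stay cheap while still exercising splits,
reversals, by-products and alternative routes.

These generators emulate the *structural* features seed inference depends
on — branching, reversibility, by-products, multiple routes to the
objective — but not the biology of curated GSMNs: no compartments beyond a
nominal extracellular set, no cofactor/currency metabolites (which dominate
real scopes), no gene–protein–reaction structure, and flux bounds far
simpler than curated models'. Passing tests therefore demonstrate the
*algorithms' contracts* (soundness, minimality, completeness against
oracles, determinism), not predictive accuracy on any particular organism.
Genome-scale SBML models from public databases can be fed through the same
pipeline unchanged; their runtimes and solution counts will differ.

## Numerical and degenerate-input choices

Scope iteration order is fixed (a queue with counting activation), which the
least-fixed-point semantics makes irrelevant to results but keeps logs
reproducible. Lexicographic tie-breaks appear wherever an arbitrary choice
exists (shrink order, queue pop order, sink naming), making every engine
deterministic at fixed configuration; the `random_seed` in the run
configuration exists for the synthetic generators — the solvers themselves
draw no random numbers. Empty seed sets, seedless scope (kept imports still
activate), reactions with a metabolite on both sides (net-balanced in the
matrix), productless multi-reactant pseudo-reactions (classified internal,
with a message), and objective reactions that normalization reversed
(resolved through provenance) are all defined behaviours with tests.

## Known limitations

The reasoning enumerator materializes each solution before the next is
searched, and the guess-and-check queue is primed with the full Boolean
minimal family: enumeration at genome scale with very large solution
families will be slower than a solver-native implementation with clause
learning, though the algorithms' asymptotics are the problem's (it is
NP-hard regardless). No-accumulation tolerates no self-regenerating cycles:
a metabolite consumed only by the cycle that produces it still counts as
consumed, but a cycle that needs an initial pulse to start is not granted
one — the stricter initial-state reading is intentional. Flux validation
checks satisfiability of a positive objective flux, not parsimony,
variability, or thermodynamic loop-freedom.
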