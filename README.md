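# seedkit

Inferring the nutrients an organism needs is the inverse of the usual
metabolic-modelling question. Given a genome-scale metabolic network (GSMN)
and a metabolic objective — typically the biomass reaction — seedkit computes
**seed sets**: subset-minimal collections of metabolites which, if assumed
exogenously available, make the objective satisfiable. This is the core
computation of reverse ecology: raising hypotheses about growth media for
organisms known only from their genome, including uncultured ones.

seedkit is aimed at systems-biology and microbiology researchers who work
with SBML models (e.g. from BiGG or automated reconstruction pipelines) and
want candidate minimal media, or candidate precursor sets for a chosen
target metabolite, with explicit control over which metabolites may or must
be seeds.

## The model

Two semantics of "the objective is satisfiable from seeds S" are combined:

* **Network expansion (NE).** The *scope* of S is the least fixed point

  ```
  M0 = S,   M(i+1) = Mi ∪ ⋃ { products(r) : reactants(r) ⊆ Mi }
  ```

  A reaction activates when all its reactants are reachable; stoichiometric
  quantities play no role. The Boolean problem asks for S ⊆ M with
  T ⊆ Scope(N, S), where the target set T is the reactants of the objective
  reaction, an explicit metabolite list, or all of M ("full network" mode).
  An optional **no-accumulation** constraint additionally requires every
  scope metabolite to be consumed by some activated reaction — a qualitative
  surrogate of steady state.

* **Flux balance analysis (FBA).** The linear program
  max ν_obj s.t. X·ν = 0, ν_min ≤ ν ≤ ν_max, where X is the stoichiometric
  matrix. A seed set is flux-valid when, after closing all pre-existing
  imports and injecting the seeds (reopening their exchange reaction, or
  creating a reversible sink), the maximized objective flux is positive.

Because reversible reactions make "reactant" and "product" ambiguous, models
are first *normalized*: reversible reactions are split into two irreversible
copies, backwards-written reactions (bounds [−b, 0]) are reversed, zero-bound
reactions are deleted, and the import direction of exchange and sink
reactions is blocked (optionally kept) so that pre-encoded media do not act
as silent seeds.

Enumeration is of **subset-minimal** solutions (no proper subset is a
solution), optionally restricted to globally minimal cardinality. Five
engines are provided: pure Boolean `reasoning`; `hybrid_filter` (reasoning
then FBA filtering); `hybrid_gc` guess-and-check (failed sets are blocked
exactly, so their supersets become candidate minimal solutions of the joint
NE+FBA problem); `hybrid_gc_div` (the same, with enumeration biased towards
seeds not yet used, widening the explored union); and `full_hybrid_solve`
(direct search with LP checks on partial assignments, for small networks).
A brute-force oracle cross-checks all of them on small instances.

## Worked example

The `trap` toy network — `r1: A → B + C`, `r2: B → T`, demand `DM_T: T → ∅`,
objective `DM_T` — separates the two semantics: seeding `A` reaches the
target `T` but strands the by-product `C`, which steady state cannot allow.

```r
library(seedkit)
trap <- generate_fixture("trap")
problem <- seed_problem(trap, mode = "target")

enumerate_reasoning(problem)
#> 3 seed solution(s) [reasoning, exhausted]
#> {T} [ne_subset_minimal]
#> {B} [ne_subset_minimal]
#> {A} [ne_subset_minimal]

hybrid_gc(problem)
#> 3 seed solution(s) [hybrid_gc, exhausted]
#> {B} [hybrid_subset_minimal] flux = 10
#> {T} [hybrid_subset_minimal] flux = 10
#> {A, C} [hybrid_subset_minimal] flux = 10
```

The Boolean engine accepts `{A}`; the guess-and-check engine rejects it
(zero objective flux), blocks it, and later finds `{A, C}` — flux-valid
because the sink injected for `C` drains the by-product, and subset-minimal
for the joint problem even though it is not Boolean-minimal. The reported
flux of 10 is the demand's upper bound, the most the objective can carry.

The same run from a shell:

```sh
Rscript inst/cli/seedkit.R fixtures trap -o trap.sbml
Rscript inst/cli/seedkit.R infer trap.sbml --mode target --solve hybrid-gc -o out.json
```

`out.json` records the configuration, the normalization report, one record
per solution (seeds, Boolean/no-accumulation/FBA validity, minimality) and
diversity statistics; its layout is described by
`inst/schema/results.schema.json`.

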