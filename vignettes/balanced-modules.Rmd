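---
title: "Balanced module extraction: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced module extraction: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontobalance)
```

## The problem

Large clinical terminologies such as SNOMED CT are organised as a rooted
directed acyclic graph of classes: every class has *is-a* parents, and
defined classes additionally *reference* other classes in the right-hand
sides of their axioms (a fracture of the femur has a finding site that is a
bone structure; a product has an active-ingredient substance). The region
below each direct child of the root is a *sub-hierarchy* — clinical
findings, procedures, organisms, body structures, and so on — and the vector
of relative class frequencies per sub-hierarchy is the terminology's
*shape*.

Many applications (quality-assurance sampling, demo versions, reasoner and
editor scaling testbeds, alignment experiments with constrained upper-level
ontologies) need a module that is not merely *about* some topic but is a
miniature of the whole terminology: same shape, much smaller. Classical
signature-based modularization does not deliver this. Following definition
references drags in classes from coupled sub-hierarchies without limit, so
the module's shape drifts away from the source's — anatomy gets
over-represented because findings and procedures constantly point into it.

`ontobalance` implements a *balanced module* extractor. A balanced module
`M` of a source ontology `S` satisfies:

(a) every class in `M` is connected to the root exactly as in `S` (all its
    ancestors are present);
(b) every class in `M` keeps its full definition (all referenced classes are
    present);
(c) the sub-hierarchy distribution of `M` approximates that of `S`.

## Extraction and the shape metric

`extract_module()` computes the least fixpoint of: seeds are in; parents of
members are in; references of members are in, and referenced classes become
new target nodes themselves. This guarantees (a) and (b) by construction.
Traversal is upward-only — descendants of targets are never added. Two
closure policies exist: the default `all` follows the references of every
member (the only policy under which (b) provably holds for every module
class); `seeds_and_references` follows references only from seeds and from
classes that are themselves reference targets. The restricted policy is kept
for experimentation; its modules can fail (b), and while extraction is
idempotent under `all` (the module is closed under both rules), it is not
under the restricted policy.

Requirement (c) is quantified per sub-hierarchy `k` in percentage points,

    Error(k) = f_M(k) − f_S(k),

where `f_X(k)` is the percent of `X`'s classes (root excluded) in
sub-hierarchy `k`, and aggregated as the residual sum of squares

    RSS = (1/K) * sum_k Error(k)^2,

with `K` the number of sub-hierarchies of the *source* (18 for SNOMED CT
after dropping the metadata sub-hierarchy). Working in percentage points
makes the convergence threshold `RSS < 1` interpretable: the RMS
per-sub-hierarchy error is below one percentage point. The inequality is
strict; a vector of errors all equal to one point has `RSS = 1` and does not
converge.

## The iterative rebalancing algorithm

Since (a) and (b) are non-negotiable, the only free lever for (c) is the
composition of the seed signature. `balance()` iterates:

1. Draw a stratified random signature of `n` classes under the current
   weight vector (initially the source's own relative frequencies), with at
   least one class per sub-hierarchy. Seats are apportioned by largest
   remainder (`allocate_seats()`); sampling is uniform without replacement
   within each stratum.
2. Extract the module and profile it against the source.
3. Stop if `RSS < rss_threshold`; otherwise update every weight
   multiplicatively, `w_k <- w_k * f_S(k) / f_M(k)`, renormalize to the
   simplex, and repeat with a fresh signature.

Under-represented sub-hierarchies thus receive more seeds next round and
over-represented ones fewer. The compensation is inherently conflicting:
adding finding seeds to fix finding under-representation necessarily adds
more referenced anatomy too, so beyond some point the error oscillates
instead of shrinking. `balance()` therefore caps the loop at `max_iter` and
returns the best-RSS iteration's module either way — never worse than the
naive stratified module of iteration 1.

### Tunable parameters

* `n` — signature size (classes). Default 2000, the size used in the
  reference experiment on SNOMED CT; at the ten-thousand-class synthetic
  scale used in the tests, 500 is proportionate. Larger `n` gives larger
  modules and finer-grained control of the shape.
* `rss_threshold` — squared percentage points; default 1 (RMS error under
  one point).
* `max_iter` — default 25. Oscillation typically sets in within ten
  iterations; the cap guarantees termination.
* `rng_seed` — iteration `i` draws its signature with child seed
  `rng_seed + i`, so the entire trajectory, including every intermediate
  signature, is reproducible and the global RNG stream is left untouched.
* `closure_policy` — see above; default `all`.

### Numerical and tie-break choices

* The weight update renormalizes to the simplex after the multiplicative
  step; without this, seat apportionment would be ill-defined as weights
  drift. A zero target frequency zeroes the weight outright.
* Because every stratum receives at least one seed, every stratum appears in
  the module, so the update's denominator `f_M(k)` is never zero for a
  sub-hierarchy with positive target; the guard error for that condition is
  unreachable in normal use.
* Seat apportionment resolves ties deterministically (larger fractional
  remainder first, then lexicographic sub-hierarchy id). It is exactly the
  solution of minimising the total seat–quota deviation subject to the
  minimum-one and capacity bounds; the greedy fill is optimal because the
  objective is separable and convex.
* Classes reachable from several top-level children are assigned to the
  lexicographically smallest sub-hierarchy id, with a warning. SNOMED CT's
  top hierarchies are disjoint in practice, but the container is generic.
* The root belongs to no sub-hierarchy and is excluded from every count and
  frequency.
* Degenerate inputs fail fast with typed validation errors (cycles are
  reported with a witness path; dangling identifiers name the offender).

## The synthetic generator

Everything is testable without the license-restricted SNOMED CT release.
`snomed_like_spec(scale)` builds a generator specification with 18
sub-hierarchies whose sizes are the published per-sub-hierarchy concept
counts (summing to 299,239) times `scale`, each at least 1 — so the extreme
size ratio between clinical findings (100,893) and physical forces (171)
survives down-scaling. Generation is count-exact: sizes are hard
constraints, only edges are stochastic, so shape profiles of generated
ontologies are deterministic. Within a sub-hierarchy, each class attaches at
depth `1 + Poisson(depth_mean − 1)` below the top-level class (default mean
depth 5), with an optional extra parent (`multiparent_prob`, default 0.02);
acyclicity holds by construction because parents always precede children in
generation order.

Cross-hierarchy coupling is the generator's scientifically load-bearing
part. Each `"SRC->TGT"` rate is the expected number of definition references
per source class, drawn Poisson and targeted uniformly within the target
sub-hierarchy. The default concentrates reference mass where SNOMED's
definitions do: findings on body structures (finding sites) and organisms
(causative agents), procedures on body structures, products on substances —
`CF->BS` 0.10, `CF->OR` 0.03, `PR->BS` 0.06, `PB->SU` 0.12. The absolute
rates are deliberately lower than the roughly one-site-per-finding density
one might expect at full SNOMED scale, because uniform targeting makes the
reference-forced module mass scale-sensitive: in a ten-thousand-class
ontology, a rate near 1 makes nearly every distinct anatomy class a
reference target of some finding member, leaving body structures irreducibly
over-represented no matter how the signature is rebalanced — a regime the
full-size terminology, with its highly repetitive references to common
finding sites, does not exhibit. The chosen defaults reproduce the
qualitative mechanics at desk scale: at iteration 1 body structures come out
over-represented and clinical findings under-represented, the update then
raises the finding weight, and runs converge within a handful of iterations.

What the generator does *not* emulate: label semantics, SNOMED's actual
depth and branching statistics (unpublished), the skewed, hub-like
distribution of reference targets, multiple relationship types, or
equivalent-class versus subclass axiom structure. Passing tests therefore
demonstrate the algorithm's correctness and its convergence behaviour on
SNOMED-*shaped* inputs, not numerical agreement with results obtained on the
licensed release.

## Problem sizes used in the test and acceptance suites

The shipped suites run extraction–oracle equivalence on 200 random
ontologies of up to 500 classes; monotonicity, idempotence and
well-formedness on over 500 generated cases; and the convergence study on
twenty independently seeded ~10,000-class SNOMED-shaped ontologies with
`n = 500`, requiring at least 18 of 20 runs to converge within 25 iterations
with every converged run's largest per-sub-hierarchy error below 8
percentage points. `scripts/acceptance.R` recomputes these quantities from
scratch for any seed.

## Known limitations

* Minimality is operational (the fixpoint of the stated rules), not a
  description-logic guarantee; no reasoning or locality-based module
  semantics is involved.
* The OWL reader covers the EL-like subset that SNOMED's official OWL
  rendering uses (`SubClassOf`, `EquivalentClasses`,
  `ObjectIntersectionOf`, `ObjectSomeValuesFrom`, arbitrarily nested);
  other axiom types are counted and skipped, and OWL output is not written.
* Module size is an outcome, not a control: at small synthetic scales the
  ancestor overhead per seed is proportionally larger, so modules are a
  bigger fraction of the source than a same-`n` extraction from the full
  terminology would be. Signature-size selection is out of scope.
* The treemap layout is squarified and deterministic; colour fidelity to any
  particular rendering is not attempted.
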