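---
title: "Identifying causal effects when some mechanisms are deterministic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying causal effects when some mechanisms are deterministic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalfid)
```

## The problem

A causal effect `Pr(Y | do(x))` asks what the distribution of the outcomes
`Y` would be if the treatments `X` were set to `x` by intervention.  Given a
causal diagram `G` and observational data on a subset `V` of its variables,
the effect is *identifiable* when every pair of discrete causal Bayesian
networks (CBNs) on `G` that agree on `Pr(V)` also agrees on `Pr(Y | do(x))`.
With hidden variables this frequently fails, and the classical decision
procedure is *project-ID*: collapse the hidden variables into bidirected
edges (latent projection onto an acyclic directed mixed graph, ADMG), then
run the complete ID algorithm, which returns an identifying formula over
`Pr(V)` or a hedge witness.

This package is about two refinements of that question:

* **Positivity as an explicit input.**  Identification algorithms assume
  positivity conditions such as `Pr(V) > 0`.  We represent constraint sets
  `{Pr(S | Z) > 0}` as first-class objects ([`constraint_set()`]) and track
  throughout which decisions they license.  Without any positivity, almost
  nothing is identifiable: if some treatment has a directed path to an
  outcome avoiding the other treatments (a *first ancestor*) and the
  constraints do not imply `Pr(X) > 0` for it, the effect is not
  identifiable, and [`fid_check()`] short-circuits on that criterion.

* **Qualitative functional dependencies.**  A variable is *functional* when
  its conditional distribution is deterministic — its value is a fixed but
  unknown function of its parents (driving age is determined by country
  without our knowing the statute).  Declaring a set `W` of functional
  variables shrinks the model class quantified over, so effects that are
  classically unidentifiable can become *F-identifiable*.

## Separation with deterministic nodes

Conditioning on all parents of a functional variable pins its value, so the
conditioning set may be closed under the rule "add any functional variable
whose parents are already in the set" ([`functional_closure()`]).
D-separation — the deterministic-node refinement of d-separation — is then
ordinary d-separation with the closed set ([`D_separated()`]).  d-separation
itself is implemented by Bayes-ball style reachability rather than
moralization so that the traversal could report path witnesses; only the
boolean is part of the contract.  One guard for degenerate inputs: the
closure never absorbs members of the query sets themselves, which keeps the
three sets disjoint.

## Functional elimination and projection

The workhorse transform is *functional elimination*
([`functional_eliminate()`]): connect every parent of a functional variable
to every child, then delete it.  Eliminating several variables gives the
same DAG in any order (the implementation uses topological order purely for
reproducible traces), and the transform preserves every D-separation among
the survivors.  Strict mode refuses to eliminate non-functional variables —
the operation is unsound for them — and a `force` flag exists for
experimentation only.

*Functional projection* ([`functional_project()`]) eliminates the functional
variables outside the projection set and then applies classical latent
projection.  The projection is computed directly by reachability on the
original graph (a directed edge where a directed path runs through hidden
intermediates; a bidirected edge where some hidden variable reaches both
endpoints through hidden intermediates), which is equivalent to first
splitting hidden non-roots as in the textbook construction but avoids the
intermediate blow-up.  Functional projection provably turns every
D-separation of the original graph into a plain d-separation of the output,
which is what allows classical algorithms to consume it; its bidirected
part is always a subset of the classical projection's.

## The decision pipeline

[`fid_check()`] reduces F-identifiability to classical identifiability in
stages:

1. the first-ancestor/no-positivity short circuit;
2. eliminate all hidden functional variables (always an equivalence);
3. greedily eliminate observed functional variables that are neither
   treatments nor outcomes, are mentioned by no constraint, and have
   observed parents (a fixpoint, since eliminations can expose new
   candidates; also an equivalence).  These variables are exactly the
   *dispensable observations*: the final estimand never mentions them;
4. run latent projection + ID on the reduced tuple, provided the constraint
   set implies strict positivity over the remaining observed variables
   (otherwise the ID route is reported `INAPPLICABLE` rather than silently
   assumed).  An `IDENTIFIABLE` verdict is always sound — the functionally
   restricted model class is a subset of the classical one.  A FAIL is a
   proof of F-unidentifiability only when no functional variables remain or
   every remaining one has a hidden parent; the pipeline records which
   condition held.
5. One empirical subtlety motivates an extra step: elimination densifies
   the graph, and a causal effect can be classically identifiable *before*
   stage 3 yet classically unidentifiable after it (F-identifiability is
   preserved, the classical surrogate is not).  When the stage-3 FAIL is
   not a certificate anyway, the pipeline therefore retries project-ID on
   the stage-2 graph before giving up; any success there is still a sound
   certificate.
6. Under the exact per-treatment regime `{Pr(X) > 0}` the pretend-observed
   reduction applies: close the observed set under "parents observed ⇒
   functional child observed" and decide classical identifiability of the
   enlarged tuple.  No off-the-shelf algorithm works under such weak
   positivity, so this route is decided constructively: the package searches
   for two parameterizations that agree on the (pretend-)observed joint via
   a zero-probability context — a treatment that deterministically copies a
   co-parent makes certain parent contexts observationally impossible but
   interventionally reachable, leaving the mechanism there unconstrained.
   A verified pair is returned as a numeric non-identifiability certificate;
   otherwise the result is `UNKNOWN`, never a guess.

Consistency of constraints with functional variables is only ever
*certified* (by the interceptor condition: no single constraint mentions
both a functional variable and all ways of cutting it off from
non-functional ancestors); when certification fails the pipeline warns and
continues, because consistency in general is not decidable by any procedure
we implement.  Likewise constraint implication is deliberately syntactic
and conservative — `Pr(S) > 0` yields all sub-marginals, and
`Pr(S | Z) > 0` chains with an implied `Pr(Z) > 0` — so unprovable
implications push decisions toward `INAPPLICABLE`/`UNKNOWN` rather than
unsound answers.

## The ID algorithm and estimands

The ID algorithm is implemented in its standard recursive form on the ADMG,
with deterministic topological-lexicographic tie-breaking.  Estimands are
expression trees over the observational distribution (sums over index
variables, products, quotients, probability terms), built alongside the
recursion; marginalization inside a recursive call sums only over variables
of the *current* subgraph, since free variables inherited from an enclosing
call are fixed conditioning values.  Interventions absorbed because they
have no causal path to the outcomes leave the value constant; such variables
are pinned to an arbitrary state by an explicit `fix` node rather than left
dangling.  No symbolic simplification beyond dropping empty sums and
products is attempted — published formulas are typically hand-simplified, so
equality is checked *numerically*: [`estimands_equivalent()`] compares two
expressions on random strictly positive joints, either unconstrained (for
expression-level equality) or induced by random parameterizations of a given
diagram (the right notion for two identifying formulas of the same effect,
which need only agree on distributions the model can produce).

Evaluation follows the convention that a term whose conditioning event has
probability zero contributes zero; this is what makes back-door style
formulas well defined under merely conditional positivity.

## The CBN oracle

Every identifiability claim in the test suite is backed by a fully
parameterized oracle.  [`random_cbn()`] draws one CPT per node — symmetric
Dirichlet rows floored at `1e-3` and renormalized for strictly positive
mechanisms (the floor keeps conditionals numerically stable), uniformly
random 0/1 rows for functional ones; all variables are binary by default,
which is sufficient for every invariant we check while keeping exact
enumeration cheap.  [`causal_effect_oracle()`] computes ground truth by graph
surgery plus variable elimination restricted to the outcome's ancestors, and
is itself cross-checked against brute-force enumeration of the full joint.
[`cbn_functional_eliminate()`] mirrors functional elimination at the CPT
level (children's tables are composed through the eliminated variable's
function) and preserves the marginal joint to `1e-12`.

[`counterexample_search()`] looks for direct witnesses of
non-identifiability: two CBNs agreeing on `Pr(V)` with different effects.
Both the observational joint and the effect are linear in any single CPT, so
for each perturbable mechanism the search computes the nullspace of the
joint map (SVD) intersected with the row-sum-preserving directions, and
follows the direction with the largest effect component as far as the
`[0, 1]` box allows.  The perturbed model matches `Pr(V)` to machine
precision by construction and the pair is verified numerically before being
returned.  Hidden variables are given four states (versus two for observed
ones) because unidentifiable structures need hidden mechanisms richer than
the observed ones for a one-mechanism perturbation to exist; on fully
observed, strictly positive models the nullspace is exactly trivial, so the
search provably returns nothing there.  A failed search is reported as "no
witness found", never as identifiability.

## The random-graph experiment

[`run_table1()`] reproduces the screening experiment: 50 Erdős–Rényi DAGs
per setting with `N ∈ {50, 100, 150}` ordered vertices, each forward pair an
edge with probability 0.1, and at most 6 parents per vertex (the cap is
enforced by uniformly dropping surplus incoming edges, one of several
details the protocol leaves open).  Roles are sampled per graph: `0.8N`
observed, `0.2N` treatments and `0.2N` outcomes disjoint within the observed
set, and `W ∈ {0.25N, 0.5N, 0.75N}` functional variables among the non-root
vertices.  Treatments and outcomes are restricted to observed variables
because the query is asked of `Pr(V)`.  The functional set is drawn last so
that settings sharing a seed have identical classical verdicts, and
per-graph seeds are derived from the base seed and the graph index so every
row is independently reproducible.  Strict positivity is assumed over the
observed variables remaining after the reductions, which is the convention
of the original experiment.  Counted per setting: classically unidentifiable
effects (`uid`), those of them rescued by the functional pipeline
(`uid_fid`), and the mean number of observed variables handed to project-ID
(`mean_obs`).  Because the protocol's seeds and sampling details are not
fully specified, these counts reproduce in distribution, not bit for bit.

## What the synthetic data does and does not show

All inputs are either graphs printed in the literature, graphs reconstructed
from printed factorizations, or the random families above; there are no
external datasets.  The oracle CBNs are small (at most ~10 binary variables,
exact enumeration) — they verify the *logic* of identification exactly, but
say nothing about finite-sample estimation, continuous mechanisms, or
misspecified graphs, all of which are out of scope.  Problem sizes in the
test suite were chosen so the full suite and the acceptance script each run
in minutes on a single core: 1,000 random diagrams of up to 10 nodes for the
separation/projection equivalences, 100–150 random CBNs for the
marginal-preservation and independence suites, 100 parameterizations per
worked identification example, and the full 50-graph screening settings.

## Known limitations

* Exact consistency of a constraint set with a functional set is not
  decided, only certified by a sufficient condition.
* The pretend-observed route returns `UNKNOWN` whenever its constructive
  witness search fails; a complete identification algorithm under
  per-treatment positivity is an open problem we do not attempt.
* Queries must be over observed variables; cyclic graphs, selection
  variables, counterfactual (rung-3) queries, conditional effects (IDC) and
  surrogate-experiment variants are out of scope.
* `counterexample_search()` perturbs one mechanism at a time; some
  unidentifiable structures need coordinated multi-mechanism witnesses and
  will come back "no witness found".
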