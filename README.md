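# causalfid

Causal effect identifiability under positivity constraints and qualitative
functional dependencies, for epidemiologists, biostatisticians and
causal-inference methodologists who work with causal diagrams that contain
hidden variables.

A causal effect `Pr(Y | do(x))` is *identifiable* from a causal diagram `G`
and the observational distribution `Pr(V)` of its observed variables when
every pair of discrete causal Bayesian networks on `G` that agrees on
`Pr(V)` also agrees on the effect.  The classical decision procedure is
**project-ID**: latent-project `G` onto an acyclic directed mixed graph
(ADMG) over `V`, then run the ID algorithm, which returns an identifying
formula such as the back-door adjustment
`Pr_x(y) = Σ_c Pr(c) Pr(y | c, x)` or fails with a hedge.

`causalfid` implements that stack and extends it along two axes:

* **Positivity constraints are explicit inputs** — sets of inequalities
  `Pr(S | Z) > 0` with a sound syntactic implication calculus, so every
  decision records which positivity assumptions license it (and degrades to
  `INAPPLICABLE`/`UNKNOWN` rather than silently assuming strict
  positivity).
* **Functional variables** — variables known to be *deterministic*
  functions of their parents, the functions themselves unknown.  Declaring
  them shrinks the model class, and classically unidentifiable effects can
  become **F-identifiable**.  The package implements functional elimination
  of a variable (connect parents to children, delete it), functional
  projection, D-separation (d-separation with deterministic nodes, via
  closure of the conditioning set), and a reduction pipeline
  (`fid_check()`) that converts F-identifiability to classical
  identifiability and runs project-ID.

Everything is backed by a discrete causal-Bayesian-network oracle: exact
mutilation-based effects, CPT-level functional elimination, and a
nullspace-based search for explicit pairs of models that agree
observationally but disagree interventionally.

## A worked example

Driving age `A` is functionally determined by country `C`; `C` and `A`
cause speed `X`; `A` and `X` cause accidents `Y`.  Only `C`, `X`, `Y` are
observed.

```r
library(causalfid)

m <- causal_diagram(c("C", "A", "X", "Y"),
                    c("C -> A", "C -> X", "A -> X", "A -> Y", "X -> Y"),
                    observed = c("C", "X", "Y"), functional = "A")
q <- causal_query("X", "Y")

# classical project-ID: the hidden confounder defeats identification
id_algorithm(latent_project(m), q)
#> Decision: NOT_IDENTIFIABLE
#> Hedge witness: confounded component { Y } inside { X,Y }

# knowing A is functional flips the verdict
dec <- fid_check(fid_tuple(m, positivity_preset("strict", m)), q)
dec
#> Decision: IDENTIFIABLE
#> Estimand: sum_{c} [sum_{x,y} P(c,x,y)] P(c,x,y) / (sum_{y} P(c,x,y))
```

The estimand is the back-door form `Σ_c P(c) P(y | c, x)`.  The oracle
confirms it on a random model in which `A` really is a deterministic
function of `C`:

```r
mm <- random_cbn(m, seed = 42)                      # A gets a 0/1 CPT
jv <- array_marginal(joint_distribution(mm), m$observed)
evaluate_estimand(dec$estimand, jv, c(X = "1", Y = "1"))
#> [1] 0.8947862
causal_effect_oracle(mm, c(X = "1"), "Y")[["1"]]
#> [1] 0.8947862
```

`fid_check()` also reports *dispensable observations* — observed functional
variables whose elimination preserves F-identifiability, so they never need
to be measured — and a full reduction trace.  A thin command-line driver
(`inst/cli/causalfid.R`) exposes the same operations (`dsep`, `Dsep`,
`eliminate`, `project`, `fproject`, `identify`, `fid`, `oracle-effect`,
`table1`, `generate`) over a small graph/CBN JSON schema; see
`to_dot()` for Graphviz export.

## The random-graph screening experiment

`run_table1(n, wfrac)` generates 50 Erdős–Rényi DAGs (edge probability 0.1,
at most 6 parents), samples 0.8N observed / 0.2N treatment / 0.2N outcome /
`wfrac`·N functional variables, and counts how many effects are classically
unidentifiable (`uid`) and how many of those the functional pipeline
rescues (`uid_fid`), along with the mean number of observed variables the
reductions leave for project-ID (`mean_obs`).

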