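---
title: "Signed path counting in Boolean network stable states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed path counting in Boolean network stable states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolpath)
```

## The problem

A Boolean model of a signaling network assigns each molecular species a
binary state and a logical update rule over its regulators. Its fixed
points (stable states) are routinely interpreted as cellular phenotypes,
but the binary readout hides how *strongly* the network commits to each
value: two stable states can share identical phenotype-node states while
being driven by very different amounts of upstream signaling. `boolpath`
quantifies that commitment by exhaustively counting, for every node in
every stable state, the logically valid acyclic paths that explain the
node's value — positive counts for activation, negative for repression.
The count acts as a semi-continuous measure of signal transduction
strength layered on top of ordinary stable-state analysis.

## From rules to paths

The pipeline has four stages.

**1. Minimal forms.** For each node we compute the minimal disjunctive
normal form of its rule (`cdnf`, explaining the active state) and of the
negated rule (`cndnf`, explaining the inactive state). "Minimal" means a
minimum-cardinality irredundant cover by prime implicants: we generate all
prime implicants with the Quine–McCluskey procedure over the rule's truth
table and select an exact minimum cover (essential primes first, then
branch-and-bound over the cyclic core). Every conjunctive block of the
chosen cover is a potential step of signal transduction; redundant or
subsumed blocks would inflate path counts, which is why a minimum
irredundant cover — and not, say, the full Blake canonical form with its
consensus terms — is the right normal form here. When several minimum
covers exist, we pick the lexicographically smallest under the canonical
clause order (clauses sorted by size, then by sorted literal text). The
tie-break makes driver sets, and hence path counts, fully deterministic;
it is worth noting that on rules with several minimum covers a different
(equally valid) cover choice can change individual counts, so exact
numeric agreement with other minimizers is not guaranteed on such rules.
Rules are capped at 16 variables (`var_cap`), comfortably above the
in-degrees seen in curated models and in the scalability study below.

**2. Drivers.** Fixed points are enumerated either by a vectorized sweep
of all \(2^N\) assignments (default up to 22 nodes) or by a
propagate-and-branch constraint search; the two agree exactly wherever
both apply, since fixed points are update-scheme independent. Given a
stable state, each non-input node's *drivers* are the conjunctive blocks
of its state-appropriate form (cdnf if active, cndnf if inactive) that
evaluate to true under the state; at a fixed point at least one block is
always true. Input nodes — self-identity or constant rules, the bnet
encoding of "no incoming regulation" — are terminal and have no drivers.

**3. Unit-lateral propagation.** Before counting, trivial intermediates
are flattened: whenever a node's entire driver set has collapsed to a
single one-literal clause `L`, that literal is substituted for the node in
every other node's clauses, repeatedly, with literal- and clause-level
deduplication after each round. Two guards guarantee termination when
single-literal drivers form a cycle: each node is used as a substitution
source at most once per run, and a substitution that would make a clause
refer to its own node is skipped (so a two-node loop is returned
unchanged). Substitution preserves path counts on acyclic structures
*except* when deduplication actually merges clauses: if a node's drivers
contain both `{x}` and `{L}` while `x`'s sole driver is `{L}`,
substitution yields `{L}` twice and the duplicate is dropped, merging two
formerly distinct paths that carry the same signal content. We treat the
merged count as the intended semantics (the duplicate path is redundant
by construction); `simplify_drivers()` flags the event in its
`collapsed` field, and the test suite verifies exact count preservation
whenever the flag is clear.

**4. Counting.** Paths are built backwards from the target: expanding a
node means choosing one of its driver clauses and recursively expanding
every literal of that clause (a k-literal clause forms the Cartesian
product of its literals' sub-path sets), until every branch reaches an
input. The result is a canonical expansion tree; trees are deduplicated
by structural equality and counted, with the sign taken from the target's
state. A path is *simple* if every chosen clause has one literal and
*complex* otherwise. Counts therefore obey two useful laws on disjoint
substructures: alternatives add (d independent OR-branches give count d)
and conjunctions multiply (a k-literal clause over independent chains
gives the product of chain counts), with every chain contributing exactly 1.

**Loops.** A branch that revisits a node is handled by one of two
policies. Under `discard` (the default) the whole candidate tree is
rejected, so only acyclic paths are counted — the documented consequence
being that a node sustained solely by a feedback loop gets count 0.
Under `truncate` the branch ends at the repeated node and the tree is
kept. We default to `discard` because feedback-loop and cyclic-attractor
analysis is explicitly outside this package's scope; `truncate` is
offered for users who want loop-touching evidence counted once.

**Performance.** Three interchangeable backends produce bit-identical
results. The reference is a cache-free naive recursion
(`enumerate_paths()`). `count_paths()` reuses sub-path sets computed for
upstream nodes within the same stable state by materialize-then-filter
memoization: full subtree sets are cached per node, and at reuse any
cached tree whose node set intersects the current branch's ancestors is
filtered out — this is provably equivalent to the naive recursion under
`discard`, and is therefore only used there (under `truncate` a cached
tree might need re-truncation, so the naive recursion is used). Finally,
when the state's driver dependency graph is acyclic — the common case —
counts compose by sum-over-clauses / product-over-literals and a
count-only dynamic program avoids materializing trees altogether. The
test suite checks all backends against the naive reference on hundreds of
random models under both loop policies.

## Perturbations

Replacing a rule with a constant, the usual knockout/overexpression
device, would leave the target without any explanatory path. Instead,
each perturbation adds a dedicated *perturbation input node* `P` (rule
`P, P`) and rewrites the target rule `R` as `P` (non-additive
activation), `(R) | P` (additive activation), `!P` (non-additive
inhibition) or `(R) & !P` (additive inhibition). `P` is left free: the
perturbed model's fixed points cover both regimes, and
`filter_states_by_pert()` selects the states where the perturbation is
effectively active. Two identities follow and are tested: with `P = 0`
the additive modes reproduce the original fixed points exactly, and with
`P = 1` a non-additively perturbed target has exactly one path, through
`P`. Perturbation nodes are named `<target>_ACT` / `<target>_INH` with a
numeric suffix on collision.

## The synthetic-model generator

`generate_random_model()` emulates the structure of curated signaling
models at configurable scale: `n_inputs` designated input nodes (default
3) and regulated nodes whose in-degree is drawn uniformly from
`1..k_max`. Regulators are sampled uniformly from all *other* nodes — a
self-draw would silently turn a regulated node into an extra input and
break the stratification — each regulator is negated with probability
0.5, and literals are chained left-associatively with independently
uniform `&`/`|` connectives. This rule synthesis guarantees every sampled
regulator is functional while spanning AND-dominant and OR-dominant
logic; it is the one place where the synthetic corpus is a modeling
choice rather than a forced structure, since real curated rules are not
uniform in operator mix. What the corpus does *not* emulate: scale-free
degree distributions, coherent feed-forward motif enrichment, and the
long feedback cycles of real signaling maps — so passing tests on it
demonstrate correctness of the algorithms, not biological realism of any
particular count.

The scalability harness (`run_scalability()`) generates a grid of such
corpora, enumerates all fixed points of each model and counts all paths
in every state, recording per-state totals and timings (timings are
informational only; they are never asserted). The packaged sweep uses
N in {10, 15, 20} and k_max in {2, 3} with 20 models per cell, sizes
chosen so the whole sweep runs in minutes on one core while still showing
the expected growth of per-state path counts with connectivity; the
behaviour at larger N is the same mechanism at larger exponents.

## Scoring layer

For perturbation screens, per-condition scores are computed on two
channels from the same included states: the Boolean channel averages a
pro-phenotype node's local states and `1 - state` of an anti-phenotype
node; the count channel averages the signed path counts and the *negated*
signed count of the anti node. The negated count is our analogue of
`1 - state` for a signed quantity — the natural choice, but a choice:
count-channel results depend on it. Scores across conditions are min-max
scaled with the unperturbed setup as the reference (reference included in
the range, so it maps exactly to 0 and scaled scores lie in [-1, 1];
a zero range maps everything to 0). Association between phenotype axes is
summarized by the sample Pearson correlation with the usual t-based
two-sided p value.

## Worked example

The packaged seven-node model (`sevennode_synthetic.bnet`, a constructed
illustration) converges two inputs through an OR node and an AND node
into a chain ending at `G`:

```{r}
m <- read_bnet(system.file("extdata", "sevennode_synthetic.bnet",
  package = "boolpath"
))
fp <- fixed_points(m)
st <- fp[fp[, "G"] == 1, ]
trees <- enumerate_paths(m, st, "G")
length(trees)
sum(!vapply(trees, `[[`, logical(1), "simple"))
```

Both paths traverse the two-literal driver of `E`, so both are complex;
the OR node `C` contributes the factor of two.

## Degenerate inputs and numerical choices

* A model with no fixed point yields an empty count table with a warning.
* A constant-rule node is terminal exactly like a self-identity input.
* A non-input rule that minimizes to a tautology has the constant-true
  clause as its only driver, which expands to a single childless step.
* Tree materialization is capped (`max_trees`, default 1e6); exceeding
  the cap raises an error suggesting the count-only mode, and the
  scalability harness flags the model and continues.
* All orderings (clauses, children, states) are canonical, so repeated
  runs are byte-identical; stochastic components (the generator, the
  sweep) are driven by explicit integer seeds.

## Known limitations

Only fixed points are analyzed; cyclic attractors, trap spaces and
reachability are out of scope. Path weighting (edge strengths, decay) is
not implemented — every path counts 1. Counts can grow combinatorially
with connectivity; the enumeration backends are exact, so very dense
models are limited by the materialization cap rather than by heuristics.
The `discard` policy's count of 0 for purely feedback-sustained nodes is
a definition, not a measurement of their stability.
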