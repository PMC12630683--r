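# boolpath

Signed path counting in the stable states of Boolean networks.

Boolean models of signaling networks report only binary outcomes: in a
stable state (fixed point) each node is active or inactive, with no notion
of how strongly the network commits to that value. `boolpath` adds that
missing axis. For every node in every stable state it exhaustively counts
the logically valid acyclic paths that explain the node's value, tracing
each path backwards from the node through the true conjunctive blocks
("drivers") of each rule's minimal disjunctive normal form until an input
node is reached. Counts are signed: `+k` means k distinct activation
paths, `-k` means k distinct repression paths. Two stable states with
identical phenotypes can thus be separated by the amount of signaling that
sustains them — useful for ranking in-silico perturbations, comparing
cell-fate branches, or any analysis where signal transduction *strength*
matters.

The package is aimed at systems biologists working with logical models in
the standard BoolNet (`.bnet`) format.

## Method in brief

For a model with rules f_i and a fixed point x* (f_i(x*) = x*_i for all
i):

* each rule's minimal DNF (`cdnf`) and the minimal DNF of its negation
  (`cndnf`) are computed as minimum irredundant prime-implicant covers
  (Quine–McCluskey + exact cover selection, deterministic tie-breaking);
* the *drivers* of node i under x* are the conjunctive blocks of cdnf_i
  (if x*_i = 1) or cndnf_i (if x*_i = 0) that evaluate to true under x*;
  trivial single-literal intermediates are flattened by iterative
  unit-lateral propagation;
* a *path* for node i is an expansion tree: choose one driver of i, then
  recursively one driver for every literal of that clause (k-literal
  clauses branch via a Cartesian product), until every branch reaches an
  input; branches revisiting a node are discarded (default) or truncated;
* `count(i) = sign(2 x*_i - 1) * #{distinct expansion trees}`; paths are
  *simple* when every chosen clause has one literal, *complex* otherwise.

Alternatives add and conjunctions multiply: d independent OR-branches
give count d, a k-way AND over independent chains gives the product of
the chain counts.

Also included: the four-mode perturbation framework (additive /
non-additive activation and inhibition via dedicated perturbation input
nodes), a seeded random-model generator stratified by size and maximum
in-degree with a scalability harness, and a scoring layer (min-max
scaling against a reference condition, two-channel phenotype scores,
Pearson correlation).

## Worked example

```r
library(boolpath)
m <- read_bnet(system.file("extdata", "toy_convergent.bnet", package = "boolpath"))
m
#> Boolean model with 6 nodes (2 inputs)
#>   I1, I1
#>   I2, I2
#>   A, I1
#>   B, I1 & !I2
#>   C, A | B
#>   D, !C

fp <- fixed_points(m)
fp
#>      I1 I2 A B C D
#> [1,]  0  0 0 0 0 1
#> [2,]  0  1 0 0 0 1
#> [3,]  1  0 1 1 1 0
#> [4,]  1  1 1 0 1 0

count_paths(m, fp[3, ])
#> I1 I2  A  B  C  D
#>  1 -1  1  1  2 -2
```

In the stable state with I1 on and I2 off, node `C` is explained by two
activation paths (`C←A←I1` and `C←B←{I1, !I2}`, one simple and one
complex), so `count(C) = +2`; `D` is off and inherits both paths through
its repressor, so `count(D) = -2`; the inactive input `I2` is its own
single repression path, `-1`. The full table over all stable states:

```r
count_model(m)
#> Path count table: 4 stable state(s) x 6 node(s)
#> loop policy: discard | drivers: simplified
#>      I1 I2  A  B  C  D
#> [1,] -1 -1 -1 -1 -1  1
#> [2,] -1  1 -1 -2 -2  2
#> [3,]  1 -1  1  1  2 -2
#> [4,]  1  1  1 -1  1 -1
```

A command-line wrapper over the same functions is installed at
`inst/cli/boolpath.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "boolpath.R", package = "boolpath"))')" \
  count model.bnet --format tsv
```

See `vignettes/path-counting-methods.Rmd` for the model of computation,
the loop policies, the perturbation identities and the design decisions.

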