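# causalsig

Statistical significance for hypotheses on signed causal graphs.

A signed causal graph encodes curated regulatory knowledge: a directed edge
`a -> b` with sign `+` (`-`) means that increasing `a` increases
(decreases) `b`. Given gene-expression data reduced to a ternary
classification — each transcript upregulated (+1), downregulated (-1) or
unchanged (0) — every vertex plus a perturbation direction is a *hypothesis*
whose predicted downstream regulation can be scored against the data:
+1 per sign match, -1 per sign mismatch, 0 otherwise. The score equals the
dot product of the predicted and experimental ternary vectors.

`causalsig` computes the two null distributions that turn such scores into
p-values:

* **Ternary dot product distribution** — the exact law of the score when
  the predicted classification is rearranged uniformly at random with its
  margin counts `(n+, n-, n0)` fixed. A generalization of Fisher's exact
  test to ternary variables: the probability of a 3x3 contingency table is
  a product of three multinomial coefficients
  `D = C(q+; n++, n+-, n+0) C(q-; n-+, n--, n-0) C(q0; n0+, n0-, n00)`
  normalized by `C(T; n+, n-, n0)`, aggregated by the score
  `S = n++ + n-- - n+- - n-+`. Implemented four ways: an exhaustive exact
  reference, a quartic-time full enumeration of 2x2 blocks, and two
  thresholded algorithms that discard whole families of negligible tables
  (the superfamily variant is the production path, fast even at
  `n+ = q+ = 512`, `n0 = q0 = 5120`).
* **Causal graph randomization** — Markov-chain sampling of signed directed
  graphs preserving each vertex's signed in- and out-degrees, simplicity
  and weak connectedness, via same-sign edge switches and triangle flips
  with dynamic-interval connectivity checking. Supports empirical p-values
  (`proportion of randomized graphs scoring at least as well`), obstacle
  diagnostics (strong quadrilaterals / strong triangles), exhaustive
  state-space enumeration for small graphs, and a constructive
  auxiliary-edge procedure that flips a strong triangle in nine legal
  moves.

## Worked example

```r
library(causalsig)

# experimental calls: 2 up, 1 down, 2 unchanged
experimental <- ternary_classification(c(1, 1, -1, 0, 0),
                                       ids = c("g1", "g2", "g3", "g4", "g5"))
# a hypothesis predicting g1 up, g4 down, rest unchanged
predicted <- ternary_classification(c(1, 0, 0, -1, 0),
                                    ids = c("g1", "g2", "g3", "g4", "g5"))

m <- margins_of(experimental, predicted)
d <- tdp_distribution(m)
d
#> Ternary dot product distribution (superfamily-thresholded)
#>   T = 5, q = (2,1,2), n = (1,1,3)
#>   support: -2..2  total mass: 1
sum(unclass(experimental) * unclass(predicted))  # observed score
#> [1] 1
pvalue_right_tail(d, 1)
#> [1] 0.4
```

The observed score 1 (one correct prediction, one ambiguous) has an exact
right-tail p-value of 0.4: under random rearrangement of one +1, one -1 and
three 0s, scores of 1 or 2 arise with probability 0.3 + 0.1.

The graph null, end to end:

```r
g   <- gen_connected_signed_graph(12, 20, 8, seed = 5)
exp <- gen_classification(3, 3, 6, seed = 6, ids = g$vertices)
reps <- lapply(1:100, function(i)
  randomize(g, randomization_config(gamma = 5, seed = i))$graph)
score_hypotheses(g, exp, max_depth = 1, replicates = reps)[1:3, ]
#>   rank hypothesis direction correct incorrect ambiguous score       tdp_p empirical_p ...
#>   1    v9         -1        4       0         8         4     0.0045      ...
```

Each row gives the hypothesis, its correct/incorrect/ambiguous counts, the
score, the exact ternary-dot-product p-value and the empirical
graph-randomization p-value; ties share competition ranks.

## Command-line tool

`exec/causalsig` (installed under the package's `exec/` directory) wraps
the same functions:

```sh
causalsig=$(Rscript -e 'cat(system.file("exec", "causalsig", package = "causalsig"))')
Rscript "$causalsig" tdp --q-plus 2 --q-minus 1 --q-zero 2 \
    --n-plus 1 --n-minus 1 --n-zero 3 --score 1 --out pmf.tsv
Rscript "$causalsig" randomize --graph network.tsv --gamma 100 \
    --replicates 10 --seed 1 --out-dir replicates/
Rscript "$causalsig" score --graph network.tsv --experimental calls.tsv \
    --replicate-dir replicates/ --out results.tsv
```

Graphs are tab-separated edge lists (`source  target  sign`) or SIF-like
files (`source activates target`); classifications are two-column TSVs
with values `-1/0/1` or `down/none/up`.

## Package layout

* `R/classification.R`, `R/contingency.R` — ternary classifications,
  margins, 3x3 tables, D-values.
* `R/distribution.R`, `R/tdp-quartic.R`, `R/tdp-threshold.R`,
  `R/tdp-cubic.R` — the four distribution algorithms and the exact
  recursion machinery.
* `R/digraph.R`, `R/moves.R`, `R/randomize.R` — signed digraphs, chain
  moves, the randomization driver, obstacle diagnostics, state-space
  enumeration.
* `R/hypothesis.R` — prediction, scoring, both p-values, ranking.
* `R/fixtures.R`, `R/io.R` — seeded generators and plain-text formats.
* `vignettes/causal-graph-significance.Rmd` — the methods vignette: model,
  algorithms, parameter defaults, numerical conventions, design decisions
  and limitations.
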