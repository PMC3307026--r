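---
title: "Significance testing on signed causal graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Significance testing on signed causal graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalsig)
```

# The problem

A signed causal graph encodes literature-curated regulatory relationships:
vertices are genes, transcripts, compounds or processes, and a directed edge
$(a, b)$ with sign $+$ ($-$) states that increasing $a$ increases
(decreases) $b$. Given a differential-expression experiment summarized as a
*ternary classification* — each measured transcript called upregulated
($+1$), downregulated ($-1$) or unchanged ($0$) — every vertex $v$ plus a
perturbation direction forms a *hypothesis* whose predicted downstream
classification can be compared with the data. A prediction is *correct* when
predicted and observed signs are both $+$ or both $-$, *incorrect* when they
disagree in sign, and *ambiguous* otherwise; the hypothesis *score* is
correct minus incorrect, which equals the dot product
$\mathbf{u}(C) \cdot \mathbf{u}(C')$ of the two ternary vectors.

A raw score is not evidence: hubs reach many transcripts and score well by
connectivity alone. The package therefore implements the two null models
under which a score can be calibrated:

1. **Ternary dot product (TDP) null.** Hold the experimental classification
   $C$ fixed and rearrange the predicted classification $C'$ uniformly at
   random among all classifications with the same counts
   $(n_+, n_-, n_0)$. The exact distribution of the score is a ternary
   generalization of Fisher's exact test.
2. **Graph-randomization null.** Hold the data fixed and resample the graph
   uniformly among all simple, weakly connected signed digraphs with the
   same signed in- and out-degree of every vertex, giving an empirical
   p-value for the hypothesis score.

# The ternary dot product distribution

Cross-tabulating $C$ (rows, margins $q_\sigma$) against $C'$ (columns,
margins $n_\tau$) gives a $3\times 3$ contingency table $n_{\sigma\tau}$.
The number of rearrangements of $C'$ producing a given table is a product of
one multinomial coefficient per row,

$$D[n_{\pm\pm}] \;=\; \binom{q_+}{n_{++},\,n_{+-},\,n_{+0}}
\binom{q_-}{n_{-+},\,n_{--},\,n_{-0}}
\binom{q_0}{n_{0+},\,n_{0-},\,n_{00}},$$

which depends only on the top-left $2\times 2$ block since the margins fix
the rest. The score of a table is
$S = n_{++} + n_{--} - n_{+-} - n_{-+}$, the total count is
$D_{\mathrm{tot}} = \binom{T}{n_+,\,n_-,\,n_0}$, and
$p(S) = \sum_{\text{tables with score } S} D / D_{\mathrm{tot}}$. P-values
are inclusive right tails $P(S \ge s_{\mathrm{obs}})$ — the standard
exact-test convention; inclusivity is our choice, as either convention is
defensible.

Four routes to $p(S)$ are implemented, all returning the same object:

* `tdp_exhaustive()` enumerates every feasible table in exact integer
  arithmetic (counts are small integers, exactly representable in doubles,
  with a guard at $2^{53}$). It is the independent reference oracle and
  refuses problems with more than $10^7$ arrangements.
* `tdp_quartic()` visits every feasible $2\times2$ block — work scaling as
  $n_+ n_- q_+ q_-$. All D-values are computed in log space from shared
  log-factorial decompositions, normalized by the global maximum D-value
  (so every accumulated weight lies in $(0,1]$), and aggregated by score.
  Normalizing by the maximum rather than by the value at the all-zero block
  also covers margins where the all-zero block is infeasible
  ($q_0 + n_0 - T + 1 \le 0$), which would otherwise need a special-case
  starting cell.
* `tdp_thresholded(..., superfamilies = FALSE)` exploits the observation
  that almost all tables are negligibly improbable. Tables are grouped into
  one-parameter *families* fixing the block row sums $(r_+, r_-)$ and
  column sums $(c_+, c_-)$; within a family, parameterized by $u = n_{++}$,
  the ratio $D[u-1]/D[u] = u(r_- - c_+ + u) /((r_+-u+1)(c_+-u+1))$ is a
  ratio of monic quadratics crossing $1$ exactly once, so $D$ is unimodal
  with integer maximizer at $\lfloor (r_++1)(c_++1)/(t+2) \rfloor$ (clamped
  to the feasible range). A family whose maximum falls below
  $\varepsilon \cdot s \cdot D_{\max}$ is discarded whole; surviving
  families are swept outward from the maximizer until the D-value drops
  below threshold, which unimodality makes sound.
* `tdp_thresholded(..., superfamilies = TRUE)` (the default production
  path) first bounds entire *superfamilies* in which only $(r_+, r_-)$ are
  fixed, using a proportional fill of the left $3\times 2$ submatrix
  evaluated through the Gamma function at real-valued cells. One check can
  eliminate a whole one-parameter swath of families — the dominant saving
  in the sparse regime typical of expression data, where only a few percent
  of transcripts are regulated.

## Tunable parameters

* `epsilon` (default `1e-16`, dimensionless): relative pruning threshold.
  Machine-epsilon scale suffices because the final pmf is reported relative
  to the distribution's bulk; discarded tail scores are only known to be
  below the recorded `tail_bound`
  ($\varepsilon D_{\max} \cdot \#\text{skipped}/D_{\mathrm{tot}}$).
* `safety_factor` (default `1e-2`): extra slack multiplying the threshold.
  The family maximum used for pruning is exact, but the superfamily bound
  comes from a proportional fill, which is a heuristic rather than a proven
  maximum; the slack absorbs its rounding error. The pruning-soundness
  tests audit this bound exhaustively at small sizes.
* `max_depth` (default 1): prediction depth. The default scores only
  direct targets, the setting used in the worked examples; unlimited depth
  is available, in which case each node takes the sign product along one
  shortest path and conflicting equally-short paths yield no prediction
  (value 0, flagged) — a deliberate neutral treatment, since the upstream
  convention for resolving such conflicts is not part of this package's
  scope.

## Numerical conventions

All large factorials live in log space. Probability mass is only ever
*added* (log-add-exp accumulation, or sums of non-negative weights bounded
by 1), never subtracted, so rounding error is additive and well controlled:
with $O(N^3)$ summands per score the accumulated relative error is far
below the $10^{-9}$ the tests assert. The global maximum table is found by
largest-remainder proportional fill followed by greedy single-unit
$2\times2$ rotations; exhaustive enumeration at small sizes confirms the
greedy search attains the true maximum, and the threshold's safety slack
covers it in any case.

## The exact recursion (research extra)

Aggregating D-values by $\gamma_1 = n_{++}+n_{--}$ and
$\gamma_2 = n_{-+}+n_{+-}$ reduces the inner sum to
$F[n] = \sum_k \binom{n}{k}\binom{v-n}{w-k}\binom{x-n}{y-k}$, which
satisfies a linear recursion in $n$ with polynomial coefficients — the key
to a cubic-time algorithm. Consecutive $F[n]$ values shrink roughly
geometrically (for $v=20, w=10, x=10, y=5$ they fall from 46,558,512 at
$n=0$ to 6,006 at $n=15$), so a floating-point recursion cancels
catastrophically; `f_recursion()` therefore works in exact integer
arithmetic only, and the thresholded algorithm remains the production path.

The recursion's coefficient polynomials are not built in: `f_recursion()`
derives them per parameter set at run time by solving the homogeneous
linear system built from exact `f_direct()` values (floating-point reduced
row echelon form, continued-fraction rationalization), and **accepts a
candidate only after verifying the relation exactly at every feasible
index**. Derivation restricts itself to the exactly-representable integer
window (all intermediates below $2^{53}$) and refuses — rather than
risking an unverified recursion — on parameter sets whose canonical
nullspace entries are rationals too large to recover at double precision;
in practice balanced parameter sets with $v, x \lesssim 25$ work. On short
feasible ranges the exactly recoverable relation may have effective order
below three; it is then re-verified over the longer range that order
allows. Isolated zeros of the leading coefficient polynomial are bridged
by direct evaluation.

# Graph randomization

The null family fixes three properties of the original network: per-vertex
signed in- and out-degrees, simplicity (no self-edges, at most one edge per
ordered pair — anti-parallel pairs allowed, as the strong-triangle structure
itself requires), and weak connectedness. Sampling uses a Markov chain
whose moves are *same-sign edge switches*
($(a,b),(c,d) \to (a,d),(c,b)$) and *same-sign triangle flips* (reversing
a directed 3-cycle). Each proposal draws two distinct edges uniformly;
every failed check (different signs, blocked target cells, no completing
triangle edge) is a restart, so proposals are symmetric and the stationary
distribution is uniform over the reachable states.

Weak connectivity is global and thus expensive, so it is verified only
every $K$ proposals: success saves the state and grows $K$ by $1+Q_+$;
failure reverts to the last saved state and shrinks $K$ by $1-Q_-$
(defaults $K_0 = 50$, $Q_+ = 0.131$, $Q_- = 0.076$, the dynamic-interval
heuristic of Viger and Latapy). When several failures occur in a row the
chain reverts to the *last successfully checked* state each time. The run
length is $\gamma \lvert E \rvert$ proposals with $\gamma = 100$ by
default; "iterations" counts proposals including restarts, which is the
denominator under which obstacle occurrence rates are meaningful.
Connectivity checks rebuild a union-find structure from scratch — checks
are infrequent by design, so incremental connectivity is not worth its
complexity here.

Sign constraints create local obstacles that plain directed-graph
randomization does not have: the *strong quadrilateral* (a same-sign edge
pair whose crossing edges exist with opposite sign, blocking the switch)
and the *strong triangle* (a same-sign 3-cycle whose reversal exists with
opposite sign, blocking both flips). `detect_obstacles()` counts them
exhaustively, `randomize()` tallies encounters per run, and
`flip_strong_triangle_aux()` demonstrates constructively — by a fixed
sequence of nine legal moves using three disjoint auxiliary edges — that a
strong triangle is not a true obstacle in a sparse graph. The move set is
deliberately limited to switches and flips: some state-space members are
unreachable without a 3-swap (the 4-vertex path is the minimal example,
and `enumerate_state_space()` exhibits its unreachable partner), so
uniformity claims are always made relative to the reachable component, and
the uniformity test first verifies by breadth-first search over moves that
the enumerated space is move-connected.

Interval batching trades strictness for speed, and the trade is visible on
small graphs: between checks the chain may pass through a *disconnected*
state and reconnect into a member of the family that is unreachable when
connectivity is enforced move by move (the 4-vertex path is the minimal
example — its unique switch disconnects, yet a second switch on the
disconnected intermediate reaches the 3-swap-only partner). On large sparse
networks such tunneling is vanishingly unlikely and the batched chain is
the right tool; when exact adherence to the connected state space matters —
small graphs, uniformity diagnostics — configure per-move enforcement
(`k0 = 1` with negligible interval growth) or use `chain_states()`, which
always checks connectivity after every accepted move and reverts
immediately.

# What the synthetic generators emulate — and what they do not

`gen_classification()` realizes the TDP null exactly (uniform arrangement
of fixed counts). `gen_connected_signed_graph()` builds a random spanning
tree (connectivity by construction, avoiding a repair loop) and adds
uniform random extra arcs with rejection of duplicates — adequate for
exercising every invariant of the randomization machinery, but it does not
reproduce the long-tailed degree distributions of real curated networks,
nor their edge-sign composition (roughly two positive edges per negative
one in large commercial networks, which the test fixtures mimic only
loosely). Passing tests therefore certify the algorithms' contracts —
degree preservation, simplicity, connectivity, uniformity on small spaces,
exactness of the score law — not biological realism of any particular null
sample.

# Problem sizes used in the tests

Exhaustive cross-checks of all four distribution algorithms cover every
margin pair with $T \le 10$; conservation of D-values is checked
exhaustively at selected sizes up to $T = 12$. The scaling check runs the
superfamily algorithm at $n_+ = n_- = q_+ = q_- = 512$ with
$n_0 = q_0 = 5120$ (about 80 seconds on one core). Uniformity uses a
6-vertex fixture with a 20-member move-connected state space and $10^6$
proposals thinned to $10^5$ samples; randomization invariants run on
twenty seeded fixtures of 50–500 edges. These sizes were chosen as the
smallest that exercise the asymptotic behavior each property describes.

# Known limitations

* The empirical graph p-value is bounded below by $1/R$ for $R$
  replicates; reporting follows the `< 1/R` convention.
* `f_recursion()` is domain-restricted as described above.
* The chain's mixing time is not theoretically known; $\gamma = 100$
  follows prior practice, and convergence diagnostics (edge overlap between
  runs at increasing $\gamma$) suggest much smaller values suffice on
  large sparse networks.
* The randomization null is stratified only by degree signature;
  multilevel stratification (e.g. by regulatory layer) is out of scope.
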