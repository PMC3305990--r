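---
title: "How crnrealize decides what a reaction network's dynamics can and cannot tell you"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How crnrealize decides what a reaction network's dynamics can and cannot tell you}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnrealize)
```

## The model

A mass-action chemical reaction network over species $X_1,\dots,X_n$ is a
weighted directed graph whose vertices are *complexes* — formal nonnegative
integer combinations of species such as $2X_1$, $X_2+X_3$, or the empty
(zero) complex — and whose edges are reactions $C_j \to C_i$ with positive
rate coefficients. The package stores a network as the pair $(Y, A_k)$:

* $Y$, the $n \times m$ composition matrix: column $j$ holds the
  stoichiometric coefficients of complex $C_j$;
* $A_k$, the $m \times m$ Kirchhoff matrix: off-diagonal entry
  $[A_k]_{ij} \ge 0$ is the rate coefficient of $C_j \to C_i$, and every
  column sums to zero (the diagonal absorbs the column's outflow).

Mass-action kinetics gives the species ODEs
$\dot x = Y\,A_k\,\psi(x)$, where $\psi_j(x) = \prod_i x_i^{Y_{ij}}$ is the
monomial of complex $j$ (the zero complex contributes the constant 1).

Two networks over the same complex set are *dynamically equivalent* — they
generate identical ODEs — precisely when $Y A_k^{(1)} = Y A_k^{(2)} =: M$.
We call $M$ the invariant matrix; it is the complete fingerprint of the
dynamics once the complex set is fixed. Equivalence testing in
`check_dynamical_equivalence()` is therefore purely algebraic: the two
complex sets are merged into a common ordered union, both invariant
matrices are zero-padded onto it, and their max-norm difference is compared
at a relative tolerance (`1e-8` by default). No ODE integration is ever
involved, so the test has no step-size or horizon parameters.

## Why realizations are linear programs

Fixing $Y$ and $M$, the set of all dynamically equivalent realizations is a
polyhedron in the off-diagonal entries of $A_k$:
$$Y A_k = M,\qquad \textstyle\sum_i [A_k]_{ij} = 0,\qquad [A_k]_{ij}\ge 0
\;(i \ne j),$$
optionally intersected with a *constraint set* that pins selected entries
to zero (excluded reactions). Three structural facts drive everything the
package computes:

* **Super-structure.** The *dense* realization — the one with the maximal
  reaction set — has a unique unweighted graph, and the graph of every
  (constrained) realization is a subgraph of it.
* **Sparse non-uniqueness.** Realizations with the minimal number of
  reactions generally have several distinct graphs.
* **Uniqueness test.** The structure is uniquely determined by the
  dynamics if and only if the dense and sparse graphs coincide, which
  reduces to comparing the dense reaction count with the minimal
  cardinality.

### Column separability

Both $Y A_k = M$ and the column-sum condition act on each Kirchhoff column
independently, and bounds and exclusions are entrywise. After eliminating
the diagonal through the column-sum identity, column $q$ becomes its own
small problem in the variables $a_p = [A_k]_{pq} \ge 0$:
$$\sum_{p \ne q} \bigl(Y_{\cdot p} - Y_{\cdot q}\bigr)\, a_p = M_{\cdot q}.$$
The package exploits this throughout: the per-edge maximization for edge
$(q \to p)$ only involves column $q$, the feasibility of the whole problem
is the conjunction of per-column feasibilities, the minimal cardinality is
the sum of per-column minima, and the set of minimal graphs is the
Cartesian product of the per-column alternatives. This turns one linear
program with $m(m-1)$ variables into $m$ programs with $m-1$ variables —
identical optima, far better conditioning, and the 51-complex repressilator
sweep runs in seconds on one core.

### The dense sweep

`dense_realization()` performs the $m(m-1)$-step sweep: for every ordered
complex pair it maximizes the corresponding rate coefficient over the
constrained polyhedron. An edge belongs to the dense realization exactly
when its maximum is strictly positive. To also return one concrete dense
Kirchhoff matrix, the per-column optimizers are averaged — the average of
feasible points is feasible by convexity and is strictly positive exactly
on the dense edges — and a final feasibility program is solved with those
averages (clipped to at most ten times the zero-detection tolerance, so
that a tiny average never dips under the solver's feasibility resolution)
as lower bounds on the dense edges.

### Core reactions

A reaction is *core* when it appears in every dynamically equivalent
(constrained) realization. `core_reactions()` tests each dense edge by one
feasibility problem with that single rate pinned to zero: infeasibility
means the network cannot do without the reaction. Core reactions are
always a subset of every minimal structure, but the converse fails: a
sparse realization typically also contains non-core reactions, which is
exactly how alternative minimal structures arise.

### Sparse realizations and their enumeration

`sparse_realization()` minimizes the number of reactions by mixed-integer
programming: binary indicators $\delta_e$ with linking constraints
$a_e \le U_e\,\delta_e$, restricted to the dense support (valid by the
super-structure property — this shrinks the binary space from $m(m-1)$ to
the dense count, e.g. from 2550 to 70 for the repressilator). The linking
bound $U_e$ is the edge's maximal rate from the dense sweep — the tightest
valid choice — which keeps the LP relaxation's indicator values commensurate
with the integrality tolerance. `enumerate_sparse_supports()` then fixes
the per-column cardinality at its minimum and repeatedly adds no-good cuts
($\sum_{e \in S}\delta_e \le |S|-1$ for each support $S$ already found)
until the column's alternatives are exhausted; global structures are the
combinations across columns.

## The optimization backend

No linear-programming package is available in the package's dependency
footprint, and the realization algorithms need exact infeasibility
detection (the core test *is* an infeasibility test), deterministic
output, and robustness to rate coefficients spanning seven orders of
magnitude. The backend therefore implements:

* a two-phase bounded-variable primal simplex with Bland's rule
  (deterministic, finite under degeneracy). Pivot eligibility is relative
  to the magnitude of the transformed column, so cancellation noise is
  never chosen as a pivot; basic solutions get one step of iterative
  refinement;
* row equilibration by $\max(|\text{coefficients}|, |\text{rhs}|)$, which
  makes every nonzero right-hand side $O(1)$. Phase-I infeasibility is then
  detected at an absolute $10^{-10}$ threshold: genuine infeasibility gaps
  in these integer-matrix systems sit at or above the smallest relative
  rate ratio (about $10^{-9}$ for a $10^7$ rate span), while refined solver
  noise stays below $10^{-12}$;
* a depth-first branch-and-bound for the small MILPs (at most a few dozen
  binaries after the dense restriction), branching on the most fractional
  indicator, down-branch first. A relaxation solution that merely *looks*
  integral is never accepted on faith: the integers are fixed at their
  rounded values and the LP is re-solved, which is what makes big-M
  linking rows safe.

The suite cross-checks this backend against an independent simplex
implementation (`pracma::linprog`) on hundreds of random programs and
against exhaustive subset enumeration on every network small enough to
enumerate; the two routes never share code.

### Tolerances and bounds

* `tol_zero` (default `1e-7`) decides when a maximized rate counts as
  present. It is applied *per column*, scaled by
  $\max(1, \lVert M_{\cdot q}\rVert_\infty)$: a single network can carry
  dimerization rates of $10^7$ next to basal transcription at $0.025$, and
  a global threshold proportional to $\lVert M \rVert_\infty$ would wipe
  out the small-rate columns. Solver noise on structural zeros sits around
  $10^{-12}$ of the column scale, so the $10^{-7}$ line has five orders of
  safety on either side for rate spreads within a column of up to about
  $10^5$.
* Upper bounds `ubound` on rate coefficients keep the per-edge LPs bounded
  (some edge maxima are genuinely unbounded — e.g. a production/degradation
  pair whose rates can grow together). The default is per column,
  $1000 \cdot \max(1, \lVert M_{\cdot q}\rVert_\infty, \text{input column
  max})$: LP basic solutions live at the column's scale, so the margin is
  large, while the bound stays commensurate with the data (a single global
  bound taken from the $10^7$ column would bury a $0.05$-scale column's
  constraints below feasibility resolution). Dense membership must not and
  does not depend on this choice; the tests double the bound and require
  the identical support.
* Supports are compared as sorted label pairs, never by matrix position,
  so complex ordering (order of first appearance in the reaction list) is
  purely cosmetic.

## The example systems

Four constructors build the study systems entirely in code:

* `example_positive_feedback()` — the 5-species, 11-complex, 9-reaction
  gene-autoregulation motif, with its published rate set as default and an
  `extended = TRUE` variant that appends the unused complex $X_2+X_4$.
  Everything about this system is deterministic.
* `example_yeast_switch()` — the 9-species, 17-complex, 18-reaction
  cell-cycle switch. The literature source publishes the structure but not
  the rates.
* `example_repressilator()` — five genes in a repression ring with
  auto-activation: 25 species, 51 complexes, 55 reactions including
  protein degradation through the zero complex.
* `example_grn_pattern()` — the 10-node sparse linear gene network used as
  the worked reachability example (validated in the tests by its census:
  11 activation, 6 repression, 3 autoregulation entries).

Where rates are unpublished, fixtures take a `random_rates()` sampler:
uniform on $[0.5, 20.5)$, seeded, with the global RNG state preserved. The
interval is a generic "order of magnitude around 1" choice for
dimensionless benchmark rate constants; the structural quantities the
package reports (dense/core/sparse counts and supports) are
parameter-generic — they are invariant on a full-measure set of rate
vectors — and every stochastic test and the acceptance script recompute
them at two distinct seeds and require identical structure. What the
sampler does *not* emulate is biologically calibrated kinetics: magnitudes,
units and correlations between rates are arbitrary, so passing tests say
nothing about dynamical behaviour (steady states, oscillations) of the
fixtures, only about the combinatorial geometry of their equivalence
classes, which is what the package is about.

## The linear identifiability module

For sparse linear gene-network models $\dot x = Ax + Bu$, a nonzero
$A_{ij}$ means node $j$ influences node $i$. With a single perturbed node,
zero initial conditions and no further prior knowledge, a *necessary*
condition for structural identifiability is that every node be reachable
from the perturbed node along the directed influence edges $j \to i$;
states outside the reachable set are never excited, and the columns of $A$
that multiply them are undetectable in principle. The module implements
exactly this necessary condition (no rank or observability tests) with
depth-first search, cross-checked against a boolean matrix-power oracle.

`generate_sparse_linear_model(n, k)` draws exactly `k` distinct nonzero
positions per row, uniformly over all `n` columns. The diagonal
(autoregulation) is permitted by default — the worked 10-node example has
three autoregulation links — and can be excluded with
`include_diagonal = FALSE`, since generators in the literature are rarely
explicit on this point. The perturbed node is node 1; the generator is
exchangeable over node labels, so the choice is immaterial.
`nonidentifiable_fraction()` also accepts `orientation = "transpose"`,
which follows edges $i \to j$ instead (rows read as out-neighbour lists):
published Monte Carlo percentages for this experiment are substantially
higher than what the influence orientation yields and sit closer to the
transposed reading, and the flag lets users reproduce that sensitivity
analysis themselves rather than trusting either convention blindly. The
package's default remains the influence orientation because it is the one
consistent with the signal flow of $\dot x = Ax$ and with the worked
10-node example, where nodes 3–10 must be unreachable from node 1.
Under these defaults, 10-node models with two entries per row fail the
reachability condition in roughly a quarter of draws (the acceptance
script recomputes the exact fraction), and the failure rate drops steeply
as `k` grows — the monotonicity is asserted in the tests across
`k = 1..n`.

## Problem sizes and determinism

The test-suite runs every algorithm end-to-end: the full 11- and
12-complex motif analyses, both 17-complex switch seeds, both 51-complex
repressilator seeds (a 2550-step sweep each), Monte Carlo studies at up to
10000 draws, 150 random LPs against the independent solver, and
exhaustive subset enumeration on all fixtures with at most 4 complexes.
Those sizes were chosen so a complete check stays in the low minutes on a
laptop core while still covering every published quantity at full scale.
All solver paths are deterministic; the only randomness is the seeded rate
sampler and the seeded Monte Carlo generator, and identical seeds always
reproduce identical output bit-for-bit.

## Known limitations

* Only dynamical equivalence over a *fixed, known* complex set is
  considered. Realizations with altered complex sets, linear conjugacy,
  weak reversibility or detailed/complex balancing are out of scope.
* Mass-action kinetics only — no rational (Michaelis–Menten/Hill) rate
  laws, and no stochastic semantics.
* The identifiability module implements the reachability *necessary*
  condition only; a model passing it can still be non-identifiable for
  algebraic reasons.
* Feasibility thresholds are calibrated for rate spreads up to roughly
  $10^8$ within one network; data far beyond that would need the
  tolerances revisited.
* `enumerate_sparse_supports()` caps its output at `max_count` structures;
  the cap is applied per column and to the final combination, so a network
  with astronomically many minimal structures returns a deterministic
  prefix, not a sample.
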