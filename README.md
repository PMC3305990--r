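# crnrealize

Can you tell what a biochemical network looks like from the differential
equations it generates? Usually not — and `crnrealize` tells you exactly
how badly, and what it would take to fix it.

Under mass-action kinetics a reaction network over a complex set given by
the composition matrix *Y* and a Kirchhoff matrix *A<sub>k</sub>* of rate
coefficients produces the species ODEs

    dx/dt = Y · A_k · ψ(x),      ψ_j(x) = ∏_i x_i^{Y_ij}.

Networks with *Y·A<sub>k</sub><sup>(1)</sup> = Y·A<sub>k</sub><sup>(2)</sup> = M*
are **dynamically equivalent**: they generate identical dynamics, so no
amount of perfect concentration data can distinguish them. For a fixed
complex set this equivalence class is a polyhedron in the rate
coefficients, and `crnrealize` characterizes it completely:

* **dense realization** — the unique maximal reaction graph containing
  every equivalent structure as a subgraph, found by a linear-programming
  sweep that maximizes each candidate rate coefficient in turn;
* **core reactions** — reactions present in *every* equivalent
  realization, detected by one LP infeasibility test per reaction;
* **sparse realizations** — equivalent networks with the minimal number
  of reactions, found by mixed-integer programming and enumerated
  exhaustively (they are generally not unique);
* **constrained variants** of all of the above under reaction-exclusion
  sets, and the resulting **structural uniqueness test**: the structure is
  uniquely determined by the dynamics iff the dense and sparse graphs
  coincide.

A companion module quantifies, by Monte Carlo, how often sparse linear
gene-network models *ẋ = Ax + Bu* fail the reachability-based necessary
condition for structural identifiability (all nodes reachable from the
perturbed node along influence edges *j → i* for nonzero *A<sub>ij</sub>*).

The package is aimed at systems biologists and modellers doing network
inference who need to know whether "the" network behind their model is
actually determined by it, and at anyone studying kinetic realizability.

## Worked example: a positive feedback motif

The bundled 5-species gene-autoregulation motif (protein dimerizes, the
dimer occupies the promoter, transcription and translation close the
loop) has 11 complexes and 9 reactions:

```r
library(crnrealize)

net <- example_positive_feedback()
glance(net)
#> # A tibble: 1 × 3
#>   n_species n_complexes n_reactions
#>       <int>       <int>       <int>
#> 1         5          11           9

dense <- dense_realization(net)
core  <- core_reactions(net, dense = dense)
glance(core)
#> # A tibble: 1 × 3
#>   n_core n_non_core n_dense
#>    <int>      <int>   <int>
#> 1      8          4      12
```

Twelve reactions are mathematically able to participate in these exact
dynamics — three more than the model has — and only 8 of them are
mandatory. Which ones:

```r
tidy(core)
#> # A tibble: 12 × 3
#>    source  target  core
#>    <chr>   <chr>   <lgl>
#>  1 2 X1    X2      TRUE
#>  2 X1      0       TRUE
#>  3 X1      2 X1    FALSE
#>  4 X2      2 X1    TRUE
#>  5 X2 + X3 X4      TRUE
#>  6 X3      X3 + X5 TRUE
#>  7 X4      X2 + X3 TRUE
#>  8 X4      X4 + X5 TRUE
#>  9 X5      0       FALSE
#> 10 X5      2 X1    FALSE
#> 11 X5      X1      FALSE
#> 12 X5      X1 + X5 TRUE
```

Note row 9: mRNA degradation (`X5 -> 0`) is *not* a core reaction — the
identical ODEs can be produced by networks without it. The minimal
equivalent networks need 9 reactions, and three different 9-reaction
structures exist, one of them the original model:

```r
sparse <- sparse_realization(net, dense = dense)
glance(sparse)
#> # A tibble: 1 × 3
#>   cardinality n_dense structure_unique
#>         <int>   <int> <lgl>
#> 1           9      12 FALSE

length(enumerate_sparse_supports(net, dense = dense))
#> [1] 3

is_structure_unique(net)
#> <structure not unique: dense 12 reactions, minimal 9>
```

So even with every species measurable and the dynamics known exactly,
this motif's wiring is not identifiable without prior constraints.
Allowing one extra complex (`X2 + X4`) makes things worse — the dense
realization grows to 17 reactions of which only 5 are core, and 9 distinct
minimal structures realize the same dynamics:

```r
ext <- example_positive_feedback(extended = TRUE)
glance(core_reactions(ext))
#> # A tibble: 1 × 3
#>   n_core n_non_core n_dense
#>    <int>      <int>   <int>
#> 1      5         12      17

length(enumerate_sparse_supports(ext, max_count = 600))
#> [1] 9
```

Other bundled systems: `example_yeast_switch()` (a 17-complex cell-cycle
switch whose 18-reaction structure becomes provably unique after excluding
just 4 reactions) and `example_repressilator()` (51 complexes, 55
reactions; its dense realization has 70). For the linear module:

```r
glance(nonidentifiable_fraction(10, 2, trials = 10000, seed = 1))
# fraction of 10-node, 2-per-row models failing the reachability condition
```

A thin command-line interface ships in `inst/cli/crn`
(`dense`, `sparse`, `core`, `unique`, `example`, `grn-mc` subcommands over
a plain-text reaction format, with DOT graph export).

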