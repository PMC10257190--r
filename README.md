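# egmcts

Multi-step retrosynthetic route planning with an experience-guided
Monte Carlo tree search.

## The problem

Retrosynthetic planning works backwards from a target molecule to a set
of purchasable building blocks `B`, using a single-step model `S(m)`
that proposes the top-k reaction templates for any molecule together
with their probabilities `P(m, T)`. Because a template imposes *all* of
its reactants while a molecule needs only *one* workable template, the
search space is an AND-OR tree: molecule (OR) nodes succeed when one
child reaction succeeds, reaction (AND) nodes succeed only when every
reactant child does. The tree is explored by PUCT selection

    T* = argmax_T  Q̄(m,T)/N(T) + c · P(m,T) · sqrt(N(T')) / (1 + N(T))

where `Q̄` is a reaction node's running average score, `N` its update
count and `N(T')` the grandparent reaction node's count. Instead of
rollouts, leaf evaluations come from an **experience guidance network**
(EGN) — a 4096→256→1 value network over concatenated molecule and
template fingerprints — trained on `(m, T, Q̄)` records harvested from
the search's own finished trees, failed and unproven decompositions
included. Proven reaction nodes are rewarded `+z`, disproven ones `-z`
(default `z = 10`), and undecided ones the mean of their reactants'
values, so a template splitting a molecule into one building block and
one unproven molecule scores 1/2.

The package is aimed at researchers studying search-and-learning methods
for synthesis planning. It ships a synthetic reaction-universe generator
with exactly known ground truth (solvability and minimal route length
for every molecule), so the whole workflow — planning, phase-I training
with its stopping rule, route extraction, matching-degree and
route-quality metrics, network-of-organic-chemistry construction, and a
benchmark harness with greedy-DFS and non-learning baselines — runs and
is tested without any chemistry dataset. A real-chemistry single-step
model can be plugged in through three S3 methods (`model_predict`,
`model_reactants`, `model_is_block`).

## A worked example

```r
library(egmcts)

u <- generate_universe(n_blocks = 5, n_nonblocks = 12,
                       unsolvable_fraction = 0.3, seed = 7)
target <- tail(u$molecules, 1)
tree <- plan(target, u, egn = NULL,
             config = planner_config(iter_limit = 500, seed = 3))
tree
#> <search_tree> target M0012 [proven], 1 iterations, 6 molecule nodes, 4 reaction nodes

route <- extract_route(tree)
route
#> <synth_route> target M0012, 1 step(s)
#>   M0012 >> B0003
route_is_valid(route, u$blocks)
#> [1] TRUE
```

The target is proven in one iteration; the extracted route synthesizes
`M0012` in a single reaction terminating in a building block (`B...`
identifier), and `route_is_valid()` confirms the structural invariants.
With `u$min_len` the generator certifies length 1 is minimal here.
Harder universes (deeper layers, unsolvable decoys, misleading
probabilities) are one `generate_universe()` call away.

Training the guidance network and benchmarking it against the
non-learning planner (`egmcts0`, every initial score fixed at 0.5) and
probability-greedy DFS:

```r
res <- train_egn_loop(train_molecules, val_molecules, u,
                      config = planner_config(iter_limit = 100, seed = 1))
report <- run_benchmark(u, test_molecules,
                        algorithms = c("egmcts", "egmcts0", "greedy"),
                        egn = res$egn, config = planner_config(iter_limit = 100))
report$aggregates      # success rate, Avg iter, Avg M, Avg T per algorithm
report$quality$metrics # LRN / SRN / mean route length on commonly solved molecules
```

A command-line launcher with subcommands `gen-universe`, `plan`,
`train`, `bench` and `noc` is installed at `exec/egmcts` inside the
package library.

See `vignettes/egmcts-methods.Rmd` for the full model description,
parameter meanings and design notes.

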