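---
title: "Experience-guided tree search for retrosynthetic planning: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Experience-guided tree search for retrosynthetic planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egmcts)
```

## The problem

Multi-step retrosynthetic planning asks for a sequence of reactions that
synthesizes a target molecule from a set of purchasable building blocks
$\mathcal{B}$. The search is driven backwards: a single-step model
$S(m)$ proposes, for any molecule $m$, the top-$k$ reaction templates
$T_j$ with probabilities $P(m, T_j)$; applying a template decomposes $m$
into a reactant set $R_j$, and planning recurses on every reactant that
is not a building block. Because each template imposes *all* of its
reactants while a molecule needs only *one* workable template, the
natural search structure is an AND-OR tree: molecule (OR) nodes succeed
when at least one child reaction succeeds, reaction (AND) nodes succeed
only when every reactant child does.

This package implements the full workflow around that search: a
synthetic reaction universe with exactly known ground truth, the guided
Monte-Carlo tree search itself, a small value network (the *experience
guidance network*, EGN) trained on the search's own successes and
failures, route extraction and route-level metrics, reaction-network
construction for training-set selection, and a benchmark harness.

## The search

Each molecule node stores a value $V_m$; each reaction node stores a
running average score $\bar{Q}$, an update count $N$, an initial network
score $Q_0$, and the model prior $P$. One iteration performs:

**Selection.** From the root, at a molecule node choose the reaction
child maximizing

$$\frac{\bar{Q}(m,T)}{N(T)} + c\,P(m,T)\frac{\sqrt{N(T')}}{1+N(T)},$$

where $N(T')$ is the update count of the grandparent reaction node. At a
reaction node, unexpanded molecule children take priority (one is chosen
uniformly at random); otherwise one of the not-yet-proven children is
chosen at random. The walk ends at an unexpanded non-block molecule
node.

Two readings of the exploitation term are implemented. The dividing form
above is the default but is undefined at $N=0$; the divisor is floored
at 1, so a fresh node's score is its $Q_0$. A configuration switch
(`exploitation = "plain"`) provides the conventional PUCT form with
$\bar{Q}$ undivided, since the division may well be a typographical
artifact. The division makes every node's exploitation term decay with
visits — deliberate breadth-forcing behaviour, but at desk scale (a
100-iteration budget over trees of branching factor five) the decay is
fast enough to wash out value guidance of *any* quality, including an
omniscient value function that knows every template's viability; under
the conventional form the same guidance helps substantially (the test
suite demonstrates this with a ground-truth value function). The
learning-effect study therefore runs with `exploitation = "plain"`; the
dividing form remains the default elsewhere. For reaction
children of the root, which have no grandparent reaction node, $N(T')$
is taken as one plus the summed update counts of the siblings — the
standard parent-visit surrogate, finite at the first visit and growing
thereafter.

**Expansion.** The single-step model is called once per iteration on the
selected leaf. An empty prediction disproves the leaf. Otherwise each
predicted template becomes a reaction child with
$\bar{Q} = Q_0 = f_\theta(m, T_j)$ from the EGN (or $Q_0 = 0.5$
everywhere in the non-learning configuration), and each reactant becomes
a molecule grandchild. A reactant identical to any molecule on the path
to the root trips a *cycle guard*: that grandchild is created disproven,
disproving its reaction. The guard is needed because template sets can
regenerate an ancestor, which would otherwise stall the search.

**Update.** The reward of a reaction node is $+z$ if it is proven, $-z$
if disproven, and otherwise the mean of its children's $V_m$ under the
leaf conventions $V=1$ for building blocks and $V=0$ for unexpanded
molecules (disproven molecule nodes pin $V=0$). Hence a template that
splits a molecule into one building block and one unproven molecule
scores $1/2$. The update pass first scores each newly created reaction
child with its first reward, then walks to the root, setting each
molecule's $V_m = \max_T \bar{Q}(m,T)$ and folding a fresh reward into
each reaction node on the path via

$$\bar{Q}(m,T) = \frac{1}{N+1}\sum_{j=0}^{N} Q_j(m,T),$$

with $Q_0$ averaged in but never counted in $N$. Scoring the new
children immediately matters: they include the templates that are
decided at creation (all reactants in $\mathcal{B}$, or cycle-guarded),
and without a first reward their stored scores would never reflect that
verdict — which would in turn starve the experience set of exactly its
most informative labels.

Statuses are maintained incrementally but are always equal to a full
bottom-up recomputation; `audit_tree()` verifies this, together with the
closed-form identity $\bar{Q}(N+1) - Q_0 = \sum_j Q_j$ and the
$V_m$-max equation, on any tree.

## The experience guidance network

The EGN is a one-hidden-layer regressor $4096 \to 256 \to 1$: the input
is the concatenation of a 2048-bit molecule fingerprint and a 2048-bit
template fingerprint, the hidden layer is rectified, and the output is
squashed by the logistic into $(0,1)$. In the synthetic universes both
fingerprints are deterministic hash fingerprints of the identifier (32
pseudo-random bit positions from a seeded linear-congruential stream); a
real-chemistry adapter would substitute a radius-2 circular fingerprint
and a structural reaction fingerprint folded to the same width. Bit
collisions between distinct identifiers are tolerated by construction,
as they are for folded fingerprints generally.

Training minimizes the squared error against $\bar{Q}$ labels harvested
from finished trees, with Adam (learning rate $10^{-3}$, batch size 128
— unstated in the method's description; these are the standard choices
for this optimizer and data scale), dropout 0.1 on the hidden layer, and
20 epochs per round. Labels live on the reward scale, roughly
$[-z, z]$; they are mapped affinely into $[0,1]$ by
$(\bar{Q}+z)/2z$ with clipping, and predictions are used *directly* as
$Q_0 \in (0,1)$ without un-mapping. The method never reconciles the two
scales explicitly; this choice keeps initial scores small against the
$\pm z$ reward regime, so network guidance influences which template is
tried first without overriding evidence accumulated by search.

## Phase I: learning from self-play

Round $i$ plans every training molecule with the round-$(i{-}1)$
network, collects one record per reaction node — proven, disproven and
still-open alike; the unproven ones are the point — deduplicates
repeated $(m,T)$ actions to the mean of their scores, trains the network
for 20 epochs, and validates by planning a held-out molecule set,
recording the success rate $R_s$ and the average number of iterations
$R_a$ (failures charged the full budget). The loop continues while the
current round improves on the best of the last five rounds:
$R_{s_i} - R_{s_{max}} > \varepsilon_1$ or
$R_{a_{min}} - R_{a_i} > \varepsilon_2$, with
$\varepsilon_1 = 0.015$ and $\varepsilon_2 = 3$. The prose around the
stopping rule admits both polarities; the printed inequality is the only
precise statement and is implemented exactly. Experience is pooled
fresh each round rather than replayed across rounds, matching the
per-round index on the experience set.

By default the loop first evaluates the non-learning planner on the
validation set and records it as round 0. This row seeds the stopping
window, which gives the degenerate cases sensible behaviour (a
validation set of building blocks scores perfectly at round 0 and the
loop ends right after the mandatory first round) and provides the
baseline row reported in the training history. Training plans run in
multi-route mode (the budget is exhausted rather than stopping at the
first route) so trees keep accumulating failure experience; validation
plans stop at the first route, since $R_a$ measures time-to-solution.

## Phase II: routes and metrics

Route extraction is a breadth-first queue walk from the root: each
non-block molecule follows one proven reaction child — the one with the
highest $\bar{Q}$, matching the search's own preference, with ties
broken by insertion order — and a non-block molecule with no proven
child fails the extraction with an empty reaction list. A molecule
already synthesized by an earlier step is not synthesized again. The
returned route satisfies checkable invariants (first product is the
target, every reactant is a block or another step's product, the
dependency relation is acyclic) and replays forward against the
universe's decomposition table.

The *matching degree* against a published route is the number of
matching generated steps divided by the generated route's length. A step
matches when it appears in the published route in the same order;
"same order" is implemented as the longest common ordered subsequence of
step signatures, where a signature is the product plus the deduplicated
reactant set, so by-products and their multiplicities are immaterial. A
matched step need not be consecutive in the published route, only in
order. Similarity between molecule sets is Tanimoto over the molecule
fingerprints — the field's default for bit fingerprints; the method
itself does not name one.

## The synthetic reaction universe

Real deployments of this search borrow a single-step model trained on a
patent reaction corpus and a commercial building-blocks catalogue.
Neither is needed to exercise the method: `generate_universe()` builds a
world of opaque molecule tokens in layers above the building blocks, in
which every template decomposes its product into strictly lower layers.
Acyclicity by construction makes exact ground truth computable — a
solvability flag and a minimal route length for every molecule, by
dynamic programming — which the tests then arbitrate with an
*independent* brute-force AND-OR enumerator.

Each solvable molecule carries one viable template (all reactants
solvable) plus up to `max_templates_per_molecule` further templates
drawn from the whole lower population, which may dead-end; each
unsolvable molecule carries only templates containing at least one
unsolvable reactant, or none. Template probabilities are normalized
exponential weights scaled to sum below 1; `prior_quality` (default 1)
multiplies the viable template's weight by `1 + prior_quality`, so the
emulated single-step model ranks the productive decomposition higher on
average — as a policy trained on real reaction corpora does — without
guaranteeing it the top rank, and assigns no boost at unsolvable
molecules, where the model is confidently wrong. This keeps
probability-greedy search fallible and leaves room for value guidance.
Probabilities are stored at generation and never re-sampled:
$S(\cdot)$ is a fixed function during search.

Reactants are drawn from the layer immediately below the product with
probability `chain_bias` (default 0.7) and uniformly from all lower
layers otherwise. Without this bias almost every molecule decomposes
directly into building blocks and routes are one to three steps long;
with it, minimal route lengths grow with the target's layer, which is
the regime where multi-step planning is actually exercised.

What the generator does *not* emulate: chemical similarity (hash
fingerprints of distinct tokens share bits only by collision, so the
network can memorize molecule-template pairs but cannot generalize
across structurally similar molecules, which the real method also
exploits), reagents and conditions, stereochemistry, and any notion of
reaction plausibility. Passing tests therefore demonstrate the search
and learning mechanics, not chemical validity of routes.

## Study conditions used by the shipped experiments

The learning-effect study (in the acceptance suite and
`scripts/acceptance.R`) uses universes of 50 building blocks and 400
non-block molecules in 10 layers, up to 5 templates per molecule, up to
3 reactants per template, 40% of non-block molecules unsolvable, and
`chain_bias` 0.85 — deep enough that an unguided 100-iteration search
fails on a substantial fraction of upper-layer targets. Training sets
are 100 molecules drawn from the middle layers (2–6), the held-out
evaluation sets 50 molecules from layers 5 and up; this mirrors the
method's cost-based selection of training molecules, whose rationale is
that searches of higher-cost molecules traverse — and thus re-encounter
the experience of — the lower-cost ones. Evaluation budgets are 100
iterations per target, with one phase-I round and the conventional PUCT
exploitation (see above). Oracle-equivalence checks run on universes of
at most 40 molecules with a 2000-iteration budget, where exhaustive
enumeration is cheap. These sizes are the package's desk-scale choices:
large enough for the phenomena, small enough to run in minutes. At this
scale the learning effect is real but modest: the guided search
typically gains on average iterations in most replicates, while
per-replicate success-rate gains amount to a few targets out of fifty
and can tie; a ground-truth value function (the suite's omniscient
control) attains considerably more, so the remaining headroom lies in
the network's pair coverage and label sharpness after a single training
round rather than in the search itself.

## Numerical and degenerate-input choices

* Selection ties in the argmax break by insertion order, which equals
  descending prior; all randomness flows from one seed per run, so every
  tree, training round and benchmark is bit-reproducible.
* A selection walk that finds no expandable leaf (saturated tree)
  ends the run early; the iteration makes no model call.
* `max_depth` (default 15) bounds the molecule depth selection will
  descend to; deeper non-block molecules count as unproven value-0
  children.
* Network outputs are clamped to $[10^{-7}, 1-10^{-7}]$ so the open
  interval contract survives saturated weights.
* An expansion that yields zero templates disproves the leaf; a
  molecule node recomputes to disproven from the stored `expanded` flag,
  so statuses can always be audited from scratch.
* NOC costs are defined on acyclic graphs only; a reachable cycle is an
  error, never a silent truncation. Cost counts edges; seed nodes (no
  incoming edge) cost 0.
* Average iterations in benchmark reports charge failures the full
  iteration limit (stated in the report), making the figure comparable
  across algorithms with different success rates.

## Known limitations

* The tree deliberately has no transposition table: the same molecule
  may be searched independently at several nodes, as in the original
  description of the method; experience deduplication happens only at
  training time.
* The synthetic world cannot test similarity-based generalization of
  the value network (see above), nor chemical feasibility.
* Baselines cover probability-greedy depth-first search and the
  non-learning tree search; proof-number and rollout-based planners are
  out of scope.
* The real-chemistry adapter (SMILES/SMARTS over an external template
  model) is an extension point: any object with `model_predict`,
  `model_reactants` and `model_is_block` methods can replace the
  synthetic universe.

## A worked example

```{r example}
u <- generate_universe(n_blocks = 5, n_nonblocks = 12,
                       unsolvable_fraction = 0.3, seed = 7)
target <- tail(u$molecules, 1)
tree <- plan(target, u, egn = NULL,
             config = planner_config(iter_limit = 500, seed = 3))
tree
route <- extract_route(tree)
route
route_is_valid(route, u$blocks)
```
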