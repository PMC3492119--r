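---
title: "Parsimonious reconstruction of interaction-network histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimonious reconstruction of interaction-network histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancnet)
```

## The model

Present-day protein–protein and regulatory networks are the product of four
kinds of events: gene duplication, gene loss, interaction gain, and
interaction loss. `ancnet` encodes such a past in a *history graph*. Its
backbone is a **duplication forest**: one rooted binary tree per homology
group, whose internal nodes are duplication events (a gene is replaced by
its two children) and whose leaves are extant genes (*Present*) or lost
lineages (*Absent*). Interaction dynamics are laid on top as **flip
edges** — non-tree edges between two forest nodes, each one marking a single
gain-or-loss event among the descendants of its endpoints.

The link from a history to an observable network is a parity rule. Writing
$P_x$ for the path from leaf $x$ to its root, extant genes $x$ and $y$
interact exactly when an *odd* number of flips join $P_x$ to $P_y$: the
first such flip creates the interaction, the second removes it, and so on.
Interactions therefore propagate through duplications for free — a flip
placed between two internal nodes is inherited by every pair of descendant
leaves below them — which is what makes parsimony on this encoding
non-trivial and useful.

Not every flip placement is a possible past. Each node $u$ lives on an
existence interval $[t^c_u, t^d_u)$, children are created at their parent's
duplication time, and a flip can only happen while both endpoints exist. A
history admitting such times is *valid*. Validity has a purely combinatorial
characterization: a **$k$-blocking loop** is a set of flips
$\{u_i, v_i\}_{0\le i<k}$ in which each $u_{i+1 \bmod k}$ is a *proper*
ancestor of $v_i$; a history is valid if and only if it contains no blocking
loop of any length. ("Proper" matters: the inequality chain that derives the
contradiction collapses when $u_{i+1} = v_i$.) The package implements both
directions: `find_blocking_loop()` searches a derived digraph whose vertices
are role-assigned flips and whose arcs encode the proper-ancestor condition
(a blocking loop is exactly a directed cycle there, found via strongly
connected components with a deterministic, label-sorted walk), and
`assign_times()` constructs integer event times by a deferred depth-first
search, returning the stalled set as a certificate when no timing exists.
Both are exercised against each other, and against a transitive-closure
enumeration of the definition, on thousands of random histories.

## The parsimony dynamic program

Given a forest $F$ and an extant graph $G$, `min_flip_cost()` finds a
minimum-cost flip set constructing $G$, excluding blocking loops of lengths
1 and 2 (longer ones are handled afterwards — see below). The recurrence
tracks, per pair of forest nodes, only the *parity class* of the target
encoding: either the subtree pair still has to realize $G$'s edge indicator
($f = d_G$, "even") or its complement ("odd"). For a pair $(u,v)$ the
program either splits one side without paying anything, or places a flip at
$(u,v)$ — flipping the parity below — and then splits:

* split: $A(u_L,v,f) + A(u_R,v,f)$ (and symmetrically in $v$),
* flip + split: $c(f) + A(u_L,v,\bar f) + A(u_R,v,\bar f)$ (and
  symmetrically),

with leaf–leaf base case $A(x,y,f) = f(x,y)\,c(f)$ and subtree totals
$S(u) = S(u_L) + S(u_R) + A(u_L,u_R,f)$. The forest optimum is
$\sum_r S(r) + \sum_{r<q} A(r,q,\text{even})$ over roots. A flip taken while
the pair's parity is even is an interaction *gain* and costs `c_add`; at odd
parity it is a *loss* and costs `c_loss` (ancestral root pairs start
interaction-free, and parity counts the flips already placed above). Because
each state is constant work and only two parity classes occur, the program
is $O(n^2)$ time and space in the number of forest nodes; it is implemented
in C++ (`src/dp.cpp`), with the table exposed to R for ancestor inference.

Three variants share the same engine:

* **Self-loops** (`min_flip_cost_selfloops()`): a flip at $(u,u)$ toggles
  every interaction — self-loops included — among the descendants of $u$;
  the subtree recurrence gains a parity bit, and the leaf base pays for a
  required homodimer: $S'(x,f) = f(x,x)\,c(f)$, the only leaf base
  consistent with the pairwise one.
* **Directed graphs** (`min_flip_cost_directed()`): each pair carries two
  parity bits (one per direction); a flip option may insert the forward
  edge, the backward edge, both, or neither, paying per direction.
* **Branch lengths**: when the forest carries branch lengths, node times
  $t^c/t^d$ accumulate root-to-node and a flip between nodes whose
  existence intervals are disjoint additionally pays
  $\alpha\,\delta(u,v)$, where $\delta$ is the gap between the intervals
  (0 when they overlap). `alpha = Inf` turns branch lengths into hard
  constraints. With real gene trees the two children of a node are created
  at different accumulated depths; we take $t^d(u)$ as the larger child
  creation time, so an interval covers the node's whole lifetime.

Several contract details are deliberate: pairs involving an Absent leaf
contribute zero at every parity (lost lineages impose no observable
constraint, and any other convention would force events onto unobservable
branches); ties in the minimization are broken in a fixed option order
(no-flip before flip, lower-indexed split first) so `backtrack_flips()` is
reproducible; forbidden node pairs disable only the flip-bearing options of
that exact pair. Floating-point comparisons in backtracking use a 1e-9
tolerance; all unit-cost arithmetic is exact.

## Making histories valid

The DP's structural restriction rules out 1- and 2-blocking loops, so its
cost is a *lower bound* on the optimal valid history. `reconstruct_history()`
— the package's fitting function — turns the DP solution into a valid one:
while the backtracked flip set contains a blocking loop, one flip of the
loop is chosen uniformly at random (seeded, reproducible), its node pair is
forbidden, and the DP reruns. The forbidden set grows strictly, and the
all-leaf placement is always valid, so termination is guaranteed; in
practice loops are rare and the greedy cost almost always equals the lower
bound. The returned object records both, so the relative excess — the
quantity the method's near-optimality claim is about — is always available
from `summary()`.

## Common ancestors of two networks

For two extant networks with post-speciation forests, lineages evolve
independently, so the pair tables can be computed per forest and combined.
For homology groups $r, q$ (forest roots), an ancestral interaction is
placed exactly when

$$c_{\text{add}} + A_{F_1}(r,q,\bar d_1) + A_{F_2}(r,q,\bar d_2)
  < A_{F_1}(r,q,d_1) + A_{F_2}(r,q,d_2),$$

i.e. when paying for the edge and explaining both networks from the flipped
state is strictly cheaper. Equality yields *no* edge (the rule is a strict
inequality). A group absent from one forest contributes zero on both sides.
For directed networks the rule is applied per direction with the other
direction's parity even. Note a structural consequence at unit costs: the
per-lineage gap $A(\text{even}) - A(\text{odd})$ never exceeds
$c_{\text{add}}$ (the top-level flip option caps it), so an ancestral edge
requires supporting evidence from *both* lineages — single-lineage evidence
produces exact ties. Ancestral homodimers are not inferred by default; the
analogous rule on subtree tables is available behind
`ancestral_selfloops = TRUE` as a documented extension.

The DP tables are used directly, without loop-breaking: the rule only reads
pair costs, not a concrete history.

## Simulators and what they emulate

`generate_instance()` produces ground-truthed instances: a random connected
directed seed graph (10 nodes, 25 interactions by default; a random
Hamiltonian cycle plus random extra pairs, so every node starts with an
out-edge) evolves by 200 events into an ancestor $X$; a speciation event
copies it; each lineage then evolves independently (200 events by default;
the divergence experiment uses other values), with every interaction event
logged as a flip on the lineage's duplication forest. The logged history
reconstructs the extant graph through the parity rule exactly — an
end-to-end consistency check between simulator and model that runs in the
test suite.

The **degree-dependent model** (DDM) picks, per event, node duplication,
node loss, interaction gain or interaction loss with probabilities
$P_{ndup}, P_{nloss}, P_{egain}, P_{eloss}$ (defaults 0.35/0.05/0.30/0.30,
the divergence-experiment setting), then an object: duplication and loss
target node $u$ with weight $1/k_u$ (total degree), gains take ordered
non-adjacent pairs with weight $k^{out}_u$ on the source (preferential
attachment at the source, uniform target), losses take existing edges with
weight $1/k^{out}_u$. The **degree-independent model** (DIM) draws objects
uniformly. Duplication copies every incident edge to both children (with a
self-loop copying as self-loops on both plus the mutual pair); divergence
after duplication comes from subsequent loss events. Nodes whose out-degree
reaches 0 are removed — transitively, after every event — and become Absent
leaves. Operations are sampled among the currently feasible ones, so every
sampled event is applied; an instance whose graph empties is discarded and
regenerated. The **Foster model** grows by duplication alone: the copy
keeps each incoming/outgoing edge with probability
$P_{inkeep}$/$P_{outkeep}$ and gains an innovation edge with probability
$P_{innovation}$; dropped edges are logged as loss flips so the parity
invariant still holds. The package defaults (0.5/0.5/0.1) sit mid-range of
the regimes the model is typically swept over; they are arbitrary to that
extent and exposed as parameters.

Ancestors are filtered for biological plausibility: an instance is kept
when the in-degrees fit an exponential law with maximum-likelihood rate in
$[1.0, 1.2]$ ($\hat\lambda = 1/\bar k$) *or* the out-degrees fit a discrete
power law with MLE exponent in $[1.8, 2.2]$
($\hat\gamma = 1 + n/\sum \ln k_i$, $x_{\min} = 1$); degenerate
(fewer-than-two-valued) degree sequences fail. Under the default DDM
setting the accepted ancestors average ≈ 54 nodes.

What the simulation does *not* emulate: sequence evolution, de novo gene
birth, and any correlation between lineages after speciation. Passing the
simulation benchmarks therefore says nothing about error in the duplication
forests themselves — on real data the forests come from gene-tree inference
and reconciliation, which the package treats as given input.

## Experiment drivers and the choices behind them

`run_divergence_sweep()` and `run_parameter_sweep()` drive the two
simulation studies (quality vs evolutionary distance; quality and
loop-breaking statistics across model parameters). Scoring is at the
homology-group level: precision, recall and
$F_1 = 2pr/(p+r)$, with the convention that an empty prediction has
precision 1 (flagged) so sweeps remain total. `f1_excluding_lost()`
additionally removes interactions incident to groups lost in *both*
lineages, which no method could recover; excluding them can only raise
recall.

The loop-breaking study uses a 10-point DDM grid,
$P_{ndup} \in \{0.30, 0.35, 0.40, 0.45, 0.50\} \times
P_{nloss} \in \{0.05, 0.10\}$ with the remaining probability split evenly
between gain and loss, 20 replicates each. The grid spans growth-dominated
regimes, where reconstructions involve hundreds of events; strongly
shrinking settings rarely pass the degree filter and produce trivially
small instances for which a relative-excess criterion is uninformative.

Two calibration notes, established while building the package and worth
stating plainly. First, the divergence experiment's scores are sensitive to
the simulator's gene-loss semantics: under transitive out-degree pruning
roughly a third of true ancestral interactions end up incident to a group
pair surviving in only one lineage, and such interactions are *provably*
beyond the parsimony rule (they produce exact ties at best). The test suite
asserts the operating range this experiment is designed around; the honest
medians under this package's pruning semantics sit near its lower edge. Second, problem sizes in the
test suite are chosen to keep the full run in the tens of minutes: oracle
comparisons use forests of ≤ 12 nodes (exhaustive search is exponential),
the validity property uses 1000 random histories, the loop-breaking suite
200 instances of the full 200/200-operation protocol, and the divergence
experiment the full 100 replicates at 300 operations.

## Worked example

```{r}
f <- read_forest(text = "((a,b)r);\nc;")
g <- interaction_graph(edges = rbind(c("a", "c"), c("b", "c")))
fit <- reconstruct_history(f, g, seed = 1)
summary(fit)
backtrack_flips(fit$tables)
```

One flip at the internal pair (r, c) explains both extant interactions: the
interaction arose once, before the duplication of r, and was inherited.

## Known limitations

* Whether minimizing flips under full validity is NP-hard is open; the
  greedy loop-breaker is a heuristic with an instance-wise certificate
  (cost vs lower bound), not an approximation guarantee.
* The ancestor rule treats exactly two lineages; deeper species trees
  require recursing over ancestors and are out of scope.
* Weighted-cost oracle comparisons are limited: the exhaustive oracle
  searches by subset size, hence unit costs only.
* The exclusion score removes interactions unrecoverable *in principle*;
  interactions whose evidence survives in only one lineage remain counted
  even though the strict rule can never recover them at unit costs.
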