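---
title: "Constrained modularity clustering of directed weighted connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained modularity clustering of directed weighted connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoclust)
```

## The problem

A wiring diagram of a small nervous system — every neuron, every
chemical synapse, every gap junction — is a directed weighted network.
The scientific question this package addresses is whether such a
network decomposes into topological clusters (groups of neurons more
densely wired among themselves than a strength-matched random network
would predict), how those clusters relate hierarchically, and how
individual neurons and whole clusters participate in the flow of
information between them.

The model organism motivating the defaults is the *C. elegans*
somatic connectome: 279 non-pharyngeal neurons, thousands of chemical
synapses, hundreds of gap junctions, a one-dimensional body axis along
which each soma has a position, and a strong bilateral symmetry — most
neurons come in left/right pairs with near-identical function. The
package, however, is generic: anything expressible as the canonical
wiring tables can be analyzed.

## Network model

The adjacency convention is fixed package-wide: `A[i, j]` is the total
synaptic weight **from node j to node i** — rows receive, columns send.
A chemical synapse row `(source, target, count)` adds `count` to
`A[target, source]`; an electrical junction adds its multiplicity in
*both* directions, so the grand total `w` equals the chemical count
plus twice the electrical count. Incoming strength
$S^{in}_i = \sum_j A_{ij}$ and outgoing strength
$S^{out}_j = \sum_i A_{ij}$ both sum to $w$. Self-loops are allowed and
carried through every statistic.

## Modularity and its optimization

For a partition with cluster labels $c_i$, directed weighted
modularity is

$$Q = \frac{1}{w} \sum_{ij:\,c_i = c_j}
      \Big[ A_{ij} - \frac{S^{in}_i S^{out}_j}{w} \Big].$$

The null term pairs the receiver's in-strength with the sender's
out-strength, so $Q$ rewards within-cluster weight in excess of what a
random network with the same strength sequences would carry. $Q$ of
the one-cluster partition is identically zero; positive values signal
modular structure.

Maximizing $Q$ is NP-hard and the high-$Q$ region of the landscape is
degenerate: many structurally different partitions score almost
equally well. Two ideas address this:

* **Biological constraint.** Bilateral left/right partners are
  near-functional duplicates, so a biologically valid partition should
  never separate them. The optimizer's *move units* are therefore
  single unpaired nodes or whole bilateral pairs; both members of a
  pair are always reassigned together, so no visited partition — let
  alone the returned one — separates a pair. This is a hard
  constraint, asserted at every temperature stage.
* **Stochastic search.** Simulated annealing with a metropolis rule:
  a proposed move with modularity gain $\Delta Q \ge 0$ is always
  accepted, otherwise with probability $e^{\Delta Q / T}$. $\Delta Q$
  is computed incrementally from the moved unit's rows and columns and
  is exact to floating-point precision (verified against full
  re-evaluation in the test suite).

### Two sequential phases, alternated

A full run is structured as node-level cooling cycles alternating with
cluster-level merge phases:

1. **Node phase.** Starting from a uniformly random assignment of move
   units to cluster slots, units are proposed into uniformly random
   slots (empty slots act as fresh clusters, so clusters can nucleate
   at any temperature) while $T$ cools geometrically.
2. **Merge phase.** At the stop temperature, whole-cluster merges are
   proposed and accepted by the same metropolis rule, in sweeps, until
   a sweep accepts no improving merge.

The two phases alternate — with geometrically shrinking reheats —
until an alternation no longer improves the best solution (at most six
rounds). The phases are deliberately *sequential*, not interleaved
within a temperature stage: at high temperature a bad merge is
accepted with probability near one but can only be undone one node at
a time, which makes interleaved merging a ratchet toward coarse
partitions. On five-block planted benchmarks the sequential design
recovers the planted structure in 19–20 of 20 seeded runs, whereas the
interleaved variant we first tried recovered at most 4 of 20.

### Schedule parameters

| parameter | default | meaning |
|---|---|---|
| `T0` | calibrated | initial temperature; chosen from 100 probe moves at the random start so a median-magnitude unfavorable move is accepted with probability ≈ 1/2 |
| `cool` | 0.995 | multiplicative cooling per stage |
| `node_moves_factor` | 10 | proposals per stage = 10 × number of move units |
| `T_min` | `T0/1000` | stop temperature; a *relative* floor, because the calibrated `T0` scales like 1/w and any absolute floor would truncate the anneal on heavy networks |
| `stall_limit` | 200 | stages without best-Q improvement before a cycle stops |

Temperatures live on the scale of $\Delta Q$, i.e. modularity units.
Every run is a pure function of `(network, pairing, schedule, seed)`:
the sampler carries its own PCG32 generator and never touches R's RNG
state, so restarts parallelize trivially and results are independent
of scheduling order.

`multi_restart()` runs independent seeded searches, sorts them by $Q$,
and summarizes the stability of the high-$Q$ region by the mean
pairwise normalized variation of information among solutions within
`q_window` (default 0.01) of the best — tight planted structure gives
identical solutions and VI 0.

## Hierarchy

`aggregate_clusters()` collapses a partition into a cluster graph
`W[c, d]` = summed weight from cluster `d` to cluster `c`, diagonal =
intra-cluster weight. The diagonal is kept: that choice makes the
modularity of a super-partition on the cluster graph exactly equal the
modularity of the corresponding merged partition on the original
network (asserted numerically in the tests), so re-running the same
annealer on the cluster graph (`super_partition()`, no pairing
constraint) is a faithful second level of the same objective.
`assign_nomenclature()` names base clusters with two digits — grand
cluster first, within-grand index second (`"11", "12", ..., "21",
...`). The ordering is deterministic but arbitrary: grand clusters by
descending total intra-cluster weight, members by descending node
count. Comparisons with any published labeling should go by membership,
not by label string.

## Null models

`rewire_out_strengths()` randomizes by target exchange: two directed
weighted edges swap their targets unless that would create a
self-loop. Weights stay attached to their source, so out-strengths are
preserved *exactly* while in-strengths redistribute; parallel edges
arising from a swap are summed in the adjacency. The default dose is
10 swap attempts per edge. `null_q_distribution()` reruns the
(by default equally constrained) annealer on each rewired network,
yielding the modularity a strength-matched random network supports —
the reference against which an observed $Q$ is judged. Whether the
published analysis constrained its null optimization by the pairing is
not stated; we default to applying the same constraint as the real run
(the comparison should differ from it only through the rewiring), and
the flag is exposed.

## Partition comparison

Variation of information between partitions $X$ and $Y$ is
$V = H(X|Y) + H(Y|X)$, a true metric on partitions (nonnegativity,
symmetry and the triangle inequality are property-tested on random
triples). Normalization divides by $\log n$, making the value
base-invariant and at most 1 when $n$ is the size of the compared node
set. When a partition is compared with a labeling of a *subset* (for
example, an 84-neuron functional grouping inside a 279-neuron
network), published analyses sometimes normalize by the full network's
$\log n$; both conventions are available through `n_norm`, and the
default is the compared set's size. Zero-probability contingency cells
contribute zero to every entropy term.

`concordance_test()` bootstraps the null: random partitions with the
observed cluster-size distribution, restricted to the subset, give a
null sample of VI values; the one-sample t statistic of that sample
against the observed VI, plus an empirical tail probability, quantify
whether the partition tracks the functional grouping better than
chance.

## Cartography, composition, flow

* **Within-module weight** $Z_i$: z-score (population SD) of the
  node's total in+out weight to its own cluster, within that cluster.
  Degenerate modules (zero spread, singletons) get $Z = 0$.
* **Participation coefficient**
  $P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$ with $\kappa_{is}$ the in+out
  weight between $i$ and cluster $s$. The undirected total is used
  because the cartographic convention generalizes degree to strength;
  the published description says only "weight", so this is a choice,
  and $\kappa$ is exposed for any directed variant a user wants.
* **Roles R1–R7**: non-hubs ($Z <$ 2.5) split at $P$ = 0.05, 0.62,
  0.80 into ultra-peripheral, peripheral, connector, kinless; hubs
  split at 0.30, 0.75 into provincial, connector, kinless hubs.
  Boundaries fall to the lower class. These are the conventional
  cartography cutoffs; all are configurable since the source analysis
  did not print its exact table.
* **IQV** $= \frac{K}{K-1}(1 - \sum_c p_c^2)$ over a *global*
  categorical domain of $K \ge 2$ categories — a cluster of one
  dominant type scores near 0, a uniform mixture 1. The domain is
  taken from the whole metadata table, not per cluster, so empty
  categories count.
* **Flow**: per-cluster outward fraction
  `out / (out + in)` over the diagonal-excluded cluster graph;
  hub/authority scores by power iteration of the mutually reinforcing
  recurrences (L2-normalized each step, relative tolerance $10^{-10}$,
  checked against a dense eigendecomposition in the tests). The
  diagonal is excluded by default because intra-cluster weight would
  otherwise dominate the between-cluster question; a flag restores it.
* **Geometry**: mean pairwise 1-D distances within/between clusters
  (diagonal over distinct pairs; singleton diagonal undefined) and
  per-cluster Gaussian kernel densities with reflection at both ends
  of the `[0, 1]` axis, Silverman bandwidth per cluster, each curve
  integrating to 1 within $10^{-2}$.

## The synthetic benchmark generator

`generate_planted()` emulates the features downstream stages consume:
planted blocks (each ordered dyad's weight drawn with mean `mu_in`
within blocks, `mu_out` between; Poisson by default, or truncated-zeta
"power-law" weights with exponent `alpha` and cap 50 via presence
thinning, mirroring the very uneven dyad weights of real connectomes),
bilateral pairs planted inside one block with `L`/`R` names, a
guaranteed reciprocal edge, and partner profile correlation
(`mirror` = 0.5 by default); 1-D positions beta-concentrated around
block centers $c/(k+1)$ (concentration 30), position-decile ganglion
labels G1–G10, and cluster-biased neuronal types.

What it does **not** emulate: the real connectome's degree sequence,
its specific reciprocity and motif statistics, or any spatial wiring
cost. Passing the planted-recovery tests therefore demonstrates that
the optimizer finds strong block structure under the stated
conditions — not that any particular biological claim holds on real
data; the real-data reproduction path (loader, converter, pairing
inference, full pipeline) is exercised separately and expects the
public wiring export as input.

Benchmark conditions used by the tests and the acceptance script (all
chosen once, before any tuning against outcomes): two-block sizes
(30, 20) and five-block sizes (60, 40, 30, 20, 15), `mu_in` 2.0 vs
`mu_out` 0.2 (rate ratio 10, the detectability regime the recovery
property assumes), `pair_fraction` 0.3, 20 seeds per configuration;
exhaustive-oracle checks on 200 random directed networks with 4–8
nodes, where every set partition can be enumerated.

## Numerical choices and degenerate inputs

* $Q$ and all $\Delta Q$ in double precision; the per-stage trace is
  re-evaluated from scratch so incremental drift cannot accumulate
  (at $n \le$ a few hundred no compensated summation is needed).
* Modularity is undefined at $w = 0$ and errors; empty partitions
  canonicalize to themselves; `iqv()` requires a domain of at least 2.
* Tie-breaking among equal-$Q$ proposals is left to the metropolis
  rule (a zero-gain move is always accepted), with all randomness from
  the run's own generator.
* Isolated nodes are retained, flagged, and get $P = 0$, $Z = 0$.
* Cluster labels are canonical 1..k by order of first appearance;
  every function relabels defensively.

## Limitations

* Modularity's resolution limit is inherited: no resolution parameter
  is offered because the reference analysis used plain modularity.
* The annealer is a heuristic; the exhaustive-oracle guarantee is
  empirical and established only at benchmark scale.
* The functional-grouping generator produces refinements of the
  planted truth plus uniform noise — real functional annotations are
  not refinements of any partition.
* HITS on a k×k cluster graph with small k is sensitive to
  near-degenerate spectra; the power iteration caps at 10,000 steps.

## Problem sizes

The shipped tests and `scripts/acceptance.R` run, end to end, in
roughly half a minute on one core: 200 oracle networks of 4–8 nodes,
50 constrained runs of 20 nodes, 40 planted-recovery runs of 50–165
nodes, and a 5-draw null distribution. These sizes were chosen so the
whole verification story is cheap to re-run; the same code paths scale
to the 279-neuron connectome in seconds per restart.
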