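---
title: "Methods: structural controllability of phosphorylation-based interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural controllability of phosphorylation-based interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppicontrol)
```

## The problem

Experimentally determined protein-protein interactions are undirected, yet
signalling through the phosphoproteome is inherently directional: kinases
and phosphatases act *on* substrates, and knockout experiments reveal which
gene perturbations propagate to which targets. `ppicontrol` implements the
analysis chain that turns heterogeneous interaction evidence into a
directed network and asks which proteins matter most for *controlling* it:

1. assemble a **mixed graph** (directed plus undirected edges) from
   interaction records, with explicit de-duplication and conflict rules;
2. **orient** the undirected portion against source-target path
   constraints;
3. classify every node by its role in **structural controllability**
   (critical / redundant / ordinary);
4. probe the stability of that classification (**edge-inversion
   robustness**) and the network's communication structure under **hub
   knockdowns**;
5. test node and edge annotations (PTM sites, intrinsic disorder,
   miRNA-target and phospho-binding-domain flags, DDI/DLI interface types,
   complex memberships) for **class-conditional enrichment**.

Because the compiled human network behind this kind of analysis depends on
versioned proprietary database snapshots, every stage here is exercised on
seeded synthetic networks generated in-package; the synthetic generator is
first-class, tested code.

## Network assembly

`assemble()` applies order-independent rules to the multiset of interaction
records: self loops are dropped (the node is kept); kinase/phosphatase-
substrate (KPI) and knockout (ko) records are *born directed*, whatever
their directedness field says; a directed edge beats an undirected edge on
the same node pair; and a pair directed in both opposite directions
collapses to a single undirected edge. Knockout pairs are filtered at
`p < 0.001` (strictly; a pair at exactly 0.001 is discarded) by
`filter_ko_pairs()` before assembly. Node identifiers are opaque,
case-sensitive strings: cross-database identifier unification is a
curation step that belongs upstream of this package.

## Orientation of undirected edges

Each knockout pair doubles as a source-target **path constraint**: a good
orientation lets the knockout source reach its target by a directed path
whose length equals the shortest-path length between the two in the
original graph with directions ignored. Since every directed path is also
a path in the undirected support, the directed distance can never be
shorter; a constraint is therefore satisfied exactly when the target is
reachable from the source within that many steps. A `reachability_only`
flag relaxes the criterion to plain reachability, since the algorithm
family this objective comes from includes both variants; the stronger
length-preserving rule is the default.

`orient_exact()` exhausts all `2^U` orientations of the `U` undirected
edges (ties broken by the lexicographically smallest orientation vector,
bit 0 orienting an edge from its lexicographically smaller endpoint). The
contract is the optimum, so enumeration is restricted to small instances
(`max_undirected`, default 20). `orient_greedy()` scales beyond that:
constraints are processed in order of increasing undirected shortest-path
length (short constraints are cheapest to satisfy and conflict least);
each still-unsatisfied constraint fixes the free edges along one shortest
admissible path; leftover edges point from their lower- to their
higher-degree endpoint. The greedy result never exceeds the exact optimum,
which the test suite verifies against an independent enumeration oracle on
instances with up to 12 undirected edges.

## Controllability classification

For a directed network with `N` nodes, the minimum number of driver nodes
(nodes that must receive independent external signals so the state can be
steered anywhere) is

```
N_D = max(N - |M*|, 1)
```

where `M*` is a maximum matching of the bipartite lift: an out-copy and an
in-copy of every node, one left-to-right edge per network edge. A matching
in this directed sense is a set of edges sharing no common head and no
common tail. The floor of 1 encodes that even a perfectly matched network
(e.g. a cycle) needs one input. Driver nodes are the nodes unmatched as
edge heads; in the perfect-matching case one node is designated
arbitrarily (the first in sorted order).

`classify_nodes()` deletes each node in turn (with its incident edges,
standard vertex deletion; the remainder may be disconnected) and recomputes
`N'_D` on the `N - 1` remaining nodes with the same convention:

* `N'_D > N_D` — **critical** (e.g. the middle of a directed path),
* `N'_D < N_D` — **redundant** (e.g. a leaf of a directed star),
* `N'_D = N_D` — **ordinary** (e.g. the hub of a directed star).

```{r worked-examples}
classify_nodes(make_path_net(3))$labels
classify_nodes(make_star_net(3))$labels
```

Reclassification recomputes the matching per node rather than updating it
incrementally; at the problem sizes used throughout (hundreds to a few
thousand nodes) the full recomputation is a few milliseconds per node and
an incremental fast path is not worth its complexity.

The matching route is cross-validated numerically through the **Kalman
rank condition**: with random nonzero edge weights (independent
uniform(0.2, 1), fixed seed) and one dedicated input per driver node, the
controllability matrix `[B, AB, ..., A^(N-1)B]` generically has full rank
`N`, while any smaller dedicated input set is structurally uncontrollable.
Structural controllability holds generically, not for measure-zero weight
choices, which is why random weights are the right probe. One subtlety:
when the matching is perfect on part of the graph, matched cycles that no
driver can reach need an extra *connection* from an existing input (not an
extra signal); `control_system()` wires such cycles to the first input
automatically. Rank is decided from singular values with tolerance
`max(dim) * eps * largest singular value`.

**Robustness.** `invert_random_edges()` reverses a seeded random fraction
of edges (capped at 20% by default, the conventional stress range for this
analysis); a reversal that would duplicate an existing edge is merged away
to keep the graph simple, with the count recorded. `robustness_curve()`
reports, per inversion fraction, the percentage difference
`100 |A xor B| / |A union B|` between the perturbed and baseline critical
sets (0 when both are empty).

## Distances and knockdown simulation

Two notions of "diameter" coexist in this literature: the simulation
results use the **characteristic path length** (the average of finite
shortest-path lengths over node pairs), while the discussion uses the
classical diameter (maximum node eccentricity). Both are implemented
(`mean_geodesic()`, `standard_diameter()`); the knockdown metric defaults
to the characteristic path length, which is what the knockdown curves are
based on. Unreachable ordered pairs are excluded from both numerator and
denominator — a directed interaction network always has unreachable pairs,
and counting them as infinite would make the average useless; the
`as_undirected` distance mode reproduces the alternative reading.

`progressive_knockdown()` removes, at each fraction `f` from 0 to 1 in
steps of `step` (default 1%), a fresh uniform random subset of size
`floor(f * pool)` from the target's removal pool, recomputes the
characteristic path length, and averages over `reps` replicates (default
3). Both readings of "knocking down a protein" are supported: removing its
incident edges (`mode = "edges"`, the default — a knockdown destroys the
protein's interactions while its partners remain) or removing its first
neighbours (`mode = "neighbor_nodes"`). Sampling is independent per
fraction, matching a random partial knockdown re-run at each level; a
`nested = TRUE` flag gives one monotone removal order per replicate
instead. The endpoints anchor the curve exactly: `f = 0` equals the
unperturbed value, `f = 1` equals one-shot deletion of the whole pool.

## Enrichment statistics

Distribution comparisons across classes use rank-based tests (Wilcoxon
rank-sum for two groups, Kruskal-Wallis for three); binary attributes use
Fisher's exact test, reported with the sample odds ratio `ad/bc`
(infinite on a zero denominator). PTM "regulation" is binarised per node
as carrying at least one annotated site of the modification; site counts
are retained for sensitivity re-analyses. Degree in class comparisons is
the total `k = k_in + k_out`. `class_summary()` reports raw p-values plus
Benjamini-Hochberg adjusted ones within each attribute family
(distributions / PTMs / regulation flags); `adjust = FALSE` reproduces a
raw-p-only report. Interface rates divide the class-incident DDI or DLI
edge count by the total interaction count and then by the total protein
count; the whole-network denominator is the default, with `per_class`
as the alternative reading. Hubs are the nodes whose total degree reaches
the `ceiling(0.1 N)`-th largest degree, ties included.

Degree-distribution fitting is a discrete maximum-likelihood power-law
fit. With a fixed `xmin` the likelihood is normalised by the Hurwitz zeta
function (evaluated by Euler-Maclaurin summation) and maximised
numerically; with `xmin = "auto"` the cutoff minimising the
Kolmogorov-Smirnov distance is chosen via igraph's plfit implementation.
At least 50 tail observations are required; an all-equal tail is an error.

## The synthetic generator

`scale_free_directed()` draws total degrees from a zeta distribution
`P(k) ~ k^-gamma` (default `gamma = 3`, the exponent such networks are
described by) truncated at the structural cutoff `sqrt(n)`, splits each
node's degree binomially into in- and out-stubs, rebalances so the stub
totals match, and pairs out-stubs to in-stubs uniformly. Self loops and
duplicate pairs are repaired by re-pairing the offending stubs (up to 200
passes; survivors are dropped with the count recorded — zero in practice
at these settings). The estimator-recovery tests confirm the exponent is
reproduced within ±0.15 at `n = 10^4`.

`plant_attributes()` draws annotations *conditional on an existing
classification* (classify first, then annotate — the observational
direction such enrichment studies actually have, without any causal
claim). For each binary attribute with planted odds ratio `OR` and base
rate `p`, critical nodes get rate `q` with `odds(q) = OR * odds(p)` and
everyone else `p`. The planted defaults mirror the reported biology:
phosphorylation, acetylation and ubiquitination about twice as present in
critical as in redundant nodes, sumoylation the strongest excess
(planted `OR = 6` on a 5% base rate — note that an odds ratio of 6 at that
base rate corresponds to a frequency ratio of about 4.8), a miRNA-target
and phospho-binding-domain excess, complex-membership enrichment, a DLI
bias on critical-incident edges, and seven shared-family hubs standing in
for a 14-3-3-like paralog family. Disorder fractions (Beta(1.8, 4.2),
mean ~0.3, the typical disordered fraction of a eukaryotic proteome) and
degradation rates are drawn class-independently, consistent with reports
that neither intrinsic disorder nor turnover differs between classes. Base rates other than the
sumoylation-anchored defaults are generator conventions, not reported
quantities, and are configurable.

What the generator does *not* emulate: degree-degree correlations,
module/community structure, the correlation between disorder and degree,
or biologically structured (non-random) edge directions. Passing tests
therefore demonstrate that the machinery recovers planted truths under the
stated sampling model, not that any specific biological claim holds on
real data.

## Numerical and design choices

* **Perfect-matching floor.** `N_D = max(N - |M*|, 1)`: a cycle needs one
  driver; the state equations always admit at least one input.
* **Exact orientation tie-break.** Lexicographically smallest orientation
  vector, making exact mode fully deterministic.
* **Edge-inversion collisions** merge (with a logged count) rather than
  abort; the alternative would bias inversion away from dense regions.
* **Seeds.** Every stochastic operation takes an explicit seed;
  `run_pipeline()` derives per-stage seeds from one global seed with a
  fixed linear-congruential split (all below 2^31), so stages can be
  rerun in isolation.
* **Problem sizes.** The test suite runs the estimator-recovery checks at
  `n = 10^4` degrees, end-to-end classification instances at 600-2000
  nodes, 200 null simulations for type-I calibration, and 50 seeded
  end-to-end runs for false-positive control — sizes at which every
  statistical band asserted in the tests has comfortable power.
* **Coverage guard.** `class_summary()` refuses annotation tables covering
  less than `min_coverage` of classified nodes and lists the missing
  nodes, instead of silently testing a biased subset.

## Known limitations

* Exact orientation is exponential in the number of undirected edges by
  design; real-scale networks must use the greedy mode, which carries no
  optimality guarantee beyond never beating the optimum.
* The classification treats the network as unweighted and the edge
  directions as certain; orientation errors propagate into the classes
  (the robustness module quantifies exactly this sensitivity).
* The characteristic path length is computed over reachable pairs only,
  so deletions can *remove* hard-to-reach pairs and occasionally lower
  the average even though no surviving geodesic shortens.
* Identifier unification, disorder prediction, direction machine-learning
  and database retrieval are out of scope; the package consumes their
  outputs as annotations.
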