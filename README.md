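# ppicontrol

Structural-controllability analysis of phosphorylation-based
protein–protein interaction (PPI) networks, in R.

Signalling through the phosphoproteome is directional — kinases and
phosphatases act *on* substrates, knockouts propagate *from* genes *to*
targets — but measured PPIs are undirected. `ppicontrol` is for network
biologists who want to go from raw interaction evidence to a directed
network and ask which proteins are load-bearing for its control:

* **Assembly** — build a mixed (partially directed) graph from
  tab-separated interaction records with explicit rules: self loops
  dropped, kinase/phosphatase–substrate (KPI) and knockout (ko) evidence
  born directed, ko pairs filtered at *p* < 0.001, directed edges beating
  undirected ones on the same pair, antiparallel directed pairs merged to
  one undirected edge.
* **Orientation** — direct the undirected edges so as to maximise the
  number of source–target pairs connected by a directed path of the same
  length as their undirected shortest path (`orient_exact()` by
  enumeration on small instances, `orient_greedy()` at scale).
* **Controllability** — the minimum driver-node count of a digraph with
  *N* nodes is `N_D = max(N − |M*|, 1)`, with `M*` a maximum matching of
  the bipartite lift (out-copy → in-copy per edge). Deleting node *v* and
  recomputing `N'_D` classifies it: **critical** (`N'_D > N_D`),
  **redundant** (`N'_D < N_D`) or **ordinary** (equal). The matching
  result is cross-validated by the Kalman rank condition
  `rank [B, AB, …, A^{N−1}B] = N` with random edge weights.
* **Perturbation** — robustness of the critical set to random edge
  inversion, and progressive hub-knockdown curves of the characteristic
  path length (the mean of finite shortest-path lengths).
* **Enrichment** — Fisher / Wilcoxon / Kruskal–Wallis comparisons of node
  annotations (PTM sites, disorder, miRNA targeting, phospho-binding
  domains, complex membership) and edge interface types (DDI vs DLI)
  across controllability classes, with BH adjustment per attribute
  family.
* **Synthetic data** — a seeded directed scale-free generator
  (`P(k) ∝ k^−γ`, default γ = 3) plus planted class-conditional effects,
  so the whole pipeline runs and is tested without any database access.

## Worked example

```r
library(ppicontrol)

g <- scale_free_directed(n = 500, gamma = 3, seed = 42)
g
#> directed_network: 500 nodes, 322 edges

fit_power_law_net(node_degrees(g)$k, xmin = 1)
#> power_law_fit: gamma = 3.043 (xmin = 1, n_tail = 500)

cls <- classify_nodes(g)
cls
#> control_classification: N = 500, N_D = 253 | critical 40 (8%),
#>   redundant 98 (20%), ordinary 362 (72%)
```

The fitted exponent 3.043 recovers the generating γ = 3; 253 driver nodes
are needed because a sparse scale-free digraph leaves many nodes
unmatched. Planting annotations on the classification and summarising:

```r
planted <- plant_attributes(cls, synthetic_spec(seed = 42), network = g, seed = 42)
summ <- class_summary(cls, planted$nodes)
summ[summ$attribute %in% c("k", "ptm_sumo"), ]
#>   attribute critical redundant odds_ratio  p_value adjusted_p
#> 1         k    3.000    1.0000         NA 1.78e-50   5.35e-50
#> 7  ptm_sumo    0.325    0.0714       6.26 3.19e-04   1.28e-03
```

Critical nodes have higher degree than redundant ones (median 3 vs 1;
that association emerges from the matching structure, it is not planted),
and the sumoylation excess planted at odds ratio 6 is recovered as 6.26
with a BH-adjusted p of 0.0013. A progressive knockdown of the
highest-degree hub:

```r
deg <- node_degrees(g)
hub <- deg$node[which.max(deg$k)]           # "P235", k = 10
progressive_knockdown(g, hub, mode = "edges", step = 0.25, reps = 3, seed = 7)
#>   fraction  rep1  rep2  rep3 mean_diameter
#> 1     0.00 1.597 1.597 1.597         1.597
#> 2     0.25 1.585 1.548 1.549         1.561
#> 3     0.50 1.572 1.543 1.543         1.553
#> 4     0.75 1.543 1.540 1.562         1.548
#> 5     1.00 1.543 1.543 1.543         1.543
```

Row `fraction = 0` is the unperturbed characteristic path length and
`fraction = 1` equals one-shot deletion of all the hub's edges. On this
small sparse graph the average *falls* as edges disappear: pairs that
were reachable only through the hub drop out of the average entirely.
The mean over reachable pairs only rises once enough redundant wiring
remains — on large, well-connected networks hub knockdown lengthens it.

A full YAML-configured run (simulate → orient → classify → knockdown →
enrich, every artifact stamped with version, config hash and seed):

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 11))
```

## Documentation

The methods vignette (`vignettes/controllability-methods.Rmd`) describes
the model, its assumptions, all tunable parameters and the design
decisions; every exported function carries roxygen documentation.
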