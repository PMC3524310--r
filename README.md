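# metabonet

Network-based interpretation of differential metabolite sets on a
genome-scale directed metabolic network.

Untargeted metabonomics yields a list of metabolites that differ between a
case and a control group. A list alone says little about mechanism:
metabolites act inside a metabolic network, and the *position* of the
differential set in that network — whether it sits on hubs, concentrates in
particular functional modules, or lies close to a physiological subsystem —
carries the biological signal. `metabonet` implements that analysis for
anyone with (i) a KEGG-style reaction list and (ii) one or more metabolite
sets, and it ships a synthetic KEGG-like data generator with planted ground
truth so the entire pipeline is testable without licensed database content.

## What it computes

**Background network.** Reactions `RID: PID: lhs => rhs` are expanded into
all substrate-product arcs (reversible reactions contribute both
directions) after removal of currency metabolites (H2O, ATP, NAD, ...);
self-loops are dropped and parallel arcs collapsed, giving a simple digraph
`G = (V, A)`. Its bow-tie structure (giant strongly connected component,
IN, OUT, tendrils, isolated subset) is available via `bow_tie()`.

**Centralities vs random-set nulls.** For a set `S` of differential
metabolites, `metabonet` compares the set means of in-/out-degree,
closeness and betweenness against `R` random equal-size node sets:

    Z = (x_S − mean(x_random)) / sd(x_random),   |Z| > 2.33 → significant.

Because the network is not strongly connected, closeness is
reachability-weighted: with `r_v` nodes reachable from `v` and `S_v` the
sum of those path lengths, `closeness(v) = (r_v/(n−1)) · (r_v/S_v)`.
Betweenness is directed, endpoint-excluded, normalised by `(n−1)(n−2)`.

**Module decomposition.** The isolated subset is removed and Newman
modularity

    Q = Σ_s [ l_s/L − (d_s/2L)² ]

is maximised on the undirected projection by simulated annealing
(single-node moves plus merge/split collective moves, geometric cooling,
several restarts). Unassigned nodes are then absorbed by the
neighbour-majority expansion rule, module pathway-composition vectors are
clustered by Ward linkage on Euclidean distances, and each cluster is
tested for enrichment of the differential set with the hypergeometric
upper tail

    p = Σ_{i≥k} C(K,i) C(N−K, n−i) / C(N,n),   p < 0.05 → enriched.

The same test ranks individual pathways (`pathway_enrichment()`).

**Set proximity.** For two metabolite sets A and B (shared members
removed), `proximity()` reports the number of directly linked cross pairs
(connectivity) and the mean min-direction shortest-path distance over
connected cross pairs, each standardised against random sets of size |A|.
`simplified_subnet()` extracts the linking subnetwork for display.

**Core network.** `build_core()` assembles the union of the enriched
pathways, prunes to a radius around the differential members, and
annotates regulation (up/down) and user-supplied roles (e.g.
neurotransmitter), exporting GraphML/SIF for graph viewers.

## Worked example (synthetic data)

```r
library(metabonet)

sim <- generate_synthetic(synth_config(seed = 1))   # KEGG-like inputs + truth
net <- sim$network
net
#> Metabolic network: 71 compounds, 97 arcs (mean degree 1.37 in each direction)
#>   pathway-annotated compounds in network: 67 / 71
#>   pathways with category labels: 5

part <- sa_partition(remove_isolated(net), seed = 1)
part
#> Partition: 59 nodes in 5 modules, modularity = 0.720102

expanded <- expand_partition(net, part)
comp     <- module_composition(net, expanded)
cut      <- ward_cluster(comp, k = 3)

pe <- pathway_enrichment(net, sim$truth$planted_differential)
head(pe, 3)
#>   label modules  K k        p enriched   p_adj
#> 1 00010    <NA> 12 8 0.004235     TRUE 0.02118
#> 2 00020    <NA> 13 4 0.590176    FALSE 0.98363
#> 3 00040    <NA> 13 4 0.590176    FALSE 0.98363

px <- proximity(net, sim$truth$planted_differential,
                sim$truth$planted_target, R = 1000, seed = 1)
px
#> Set proximity: connectivity 18 (rate 0.0600, Z = 4.40); mean distance 5.401
#> over 49% of pairs (Z = 0.99)
#>   |Z| > 2.33: connectivity
```

The generator planted 8 of the 20 differential metabolites in pathway
`00010`; the enrichment table recovers it at `p = 0.004` while every other
pathway stays flat. The planted-proximal target set shows significantly
elevated connectivity (`Z = 4.4`); the distance Z-score is a weaker
statistic at this network size (see the methods vignette for why, and for
the larger-network setting where it separates more often).

The same analysis is scriptable stage by stage:

```sh
inst/cli/metabonet simulate outdir=run seed=5
inst/cli/metabonet build     outdir=run seed=5
inst/cli/metabonet decompose outdir=run seed=5
inst/cli/metabonet enrich    outdir=run seed=5
```

Each stage writes TSV/JSON/GraphML outputs plus a manifest (input hashes,
parameters, seed); reruns with the same config are byte-identical.

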