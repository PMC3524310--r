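---
title: "Methods: network-based analysis of differential metabolite sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based analysis of differential metabolite sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabonet)
```

This vignette documents the models and procedures `metabonet` implements,
the assumptions behind them, the numerical and design choices that were
genuinely open, and what the synthetic benchmark does and does not show
about real data.

## The background network

The unit of analysis is a compound-compound digraph. Each reaction in a
KEGG-style reaction list contributes the full bipartite arc set
substrates × products (the standard substrate-product construction);
reversible reactions contribute both directions, `<=` lines the reverse
direction only. Currency metabolites — water, ATP, NAD and other
ubiquitous cofactors — are removed *before* arc expansion, because they
would otherwise connect almost every pair of reactions and destroy the
distance structure the analysis relies on. There is no canonical currency
list; `default_currency()` names the tokens of the synthetic dialect, and
real analyses should supply a curated list explicitly.

Assumptions baked into the construction:

* the graph is *simple*: parallel arcs collapse and self-loops are
  dropped, because every downstream centrality presupposes a simple
  digraph;
* compound identifiers are opaque, case-sensitive tokens;
* reaction stoichiometry is ignored — only adjacency matters.

`bow_tie()` partitions the nodes into the largest strongly connected
component (GSC; ties between equal-size components are broken toward the
one containing the lexicographically smallest compound id, for
determinism), the IN and OUT sets, tendrils (weakly attached either way),
and the isolated subset (weak components not containing the GSC). Tendrils
and tubes are deliberately merged into one class: downstream analysis only
ever distinguishes "connected to the core" from "isolated".

## Centralities and their conventions

Degree needs no convention. The other two do:

* **Closeness.** Classic closeness `1/Σ d(v,·)` is undefined on graphs
  that are not strongly connected. We use the reachability-weighted form
  `(r_v/(n−1)) · (r_v/S_v)`, where `r_v` counts nodes reachable from `v`
  (or reaching it, for the "in" direction) and `S_v` sums those distances.
  It degrades gracefully — nodes reaching nothing score 0 — and reduces to
  classic closeness on strongly connected graphs, a property the test
  suite checks. The choice is isolated behind `node_closeness()` so an
  alternative convention is a one-function change.
* **Betweenness.** Directed shortest-path betweenness with endpoints
  excluded, all shortest paths weighted equally, normalised by
  `(n−1)(n−2)` ordered pairs (not halved — the graph is directed). The
  implementation delegates to igraph and is cross-checked in the tests
  against explicit shortest-path enumeration on small graphs.

## Random-set null models and Z-scores

Set-level statistics are standardised against `R` random sets of equal
size drawn uniformly *without degree matching* from all network nodes, the
unconstrained control appropriate when the question is precisely whether
the observed set is unusual in degree or position. The sample standard
deviation (n−1 denominator) is used; at the default `R = 1e5` the
difference from the population form is negligible, and desk-scale analyses
pass `R = 1e3`. The observed set's members are *not* excluded from random
draws. Significance uses the conventional `|Z| > 2.33` (one-sided normal
0.01 quantile). `z_score()` refuses degenerate nulls (`sd = 0`) rather
than returning infinities.

## Module decomposition

Newman modularity is evaluated on the *undirected simple projection* of
the network, consistent with reporting a single scalar Q for a directed
graph. Maximisation is by simulated annealing from a singleton start; at
temperature `T` the chain attempts `f·S²` single-node reassignments and
`f·S` collective proposals (S = current module count), each a merge of two
random modules or a split of one (random bisection refined by three greedy
passes before the Metropolis decision). Acceptance is `min(1, exp(ΔQ/T))`;
`T` cools geometrically (default factor 0.995) until fewer than 0.1% of
proposals are accepted for three consecutive temperatures.

Two schedule choices matter and were set empirically on planted-structure
benchmarks before the test suite was frozen:

* the automatic starting temperature is *hot*: eight times the mean |ΔQ|
  of sampled single-node moves, floored at 0.05. A colder start (e.g.
  aiming at 50% initial acceptance) freezes small sparse graphs into local
  optima below the planted partition's modularity;
* `sa_partition()` runs three restarts by default (sub-seeds derived
  deterministically from `seed`) and keeps the best Q. On all 20 small
  random digraphs in the test fixtures the result equals the exhaustive
  Bell-number optimum.

The incremental ΔQ bookkeeping is verified against from-scratch
recomputation (tolerance 1e−12) when `check = TRUE`; the test suite runs
this on random graphs of up to 30 nodes.

**Expansion.** After annealing the connected core, unassigned nodes with
at least one link (in either direction) to an assigned node are absorbed
wave by wave, each joining the module containing most of its neighbours;
ties go to the lowest module index — determinism over any other
consideration, since the rule's source gives no tie-break. Nodes never
reached (the isolated subset) stay unassigned. Expansion never reassigns
an originally assigned node, and terminates because the assigned set grows
monotonically.

**Composition and clustering.** A node annotated to `p` pathways
contributes `1/p` to each pathway's category; unannotated nodes count
toward `"other"`. Module composition vectors (rows on the simplex) are
clustered by Ward linkage (`ward.D2`) on Euclidean distances and the tree
is cut at a user-chosen `k` — the cut level is a visual/judgement call in
the source analysis, so it is an explicit required parameter here.

**Modularity null.** The "random decompositions" null permutes the module
labels over the same nodes (preserving the module-size multiset), the
least-assumption reading of an otherwise unspecified procedure; the
observed Q is standardised against `R = 50` such permutations by default.

## Hypergeometric enrichment

`hyper_tail(N, K, n, k)` is the upper tail `P(X ≥ k)` of the
hypergeometric law, evaluated in log space via the stable CDF and verified
in the tests against direct summation. The tail *includes* `k` ("at least
k members co-occur"). Raw `p < 0.05` flags enrichment — no multiple-testing
correction, matching the source convention; a Benjamini–Hochberg column is
emitted for reference but never gates the flag. For cluster enrichment the
population is the nodes assigned to modules; for pathway enrichment the
default population is the annotated network compounds (`population =
"network"` and `"custom"` are available because the appropriate population
is genuinely ambiguous and materially changes p-values).

## Set proximity

Connectivity counts unordered cross pairs joined by an arc in either
direction; distance is the mean over connected cross pairs of
`min(d(a→b), d(b→a))`, with the connected fraction reported as coverage.
Shared members are removed from both sets first, so the measures describe
between-set structure rather than overlap. Both are standardised against
random sets of size |A| with B held fixed.

A caveat the test suite quantifies rather than hides: the distance
statistic is intrinsically noisy at desk scale. Its null standard
deviation across random sets (driven by which nodes happen to reach B,
and at what lengths) is of the same order as the largest shift any
planted-proximal set can produce, and proximal sets simultaneously raise
coverage — newly finite, medium-length pairs that partially offset the
short planted pairs. In the acceptance suite the connectivity Z exceeds
2.33 for essentially every seed, while the distance Z clears −2.33 in
roughly two thirds of seeds only; at genome scale (thousands of nodes,
target sets of ~10% of the network) the averaging is over far more pairs
and the statistic is better behaved. Conclusions about proximity on small
networks should therefore lean on connectivity, using distance as
supporting evidence.

## Core subnetwork

`build_core()` takes the union of the enriched pathways' induced
subgraphs, keeps nodes within undirected distance `radius` (default 2) of
a differential member — distances measured inside the pathway union, so
`radius = 0` yields exactly the differential members and `radius = Inf`
whole pathways — then drops non-differential nodes left without arcs.
Regulation (+1/−1 → up/down, otherwise unmeasured) and user-supplied role
lists (multiple tags retained) are attached as node attributes and
exported to GraphML/SIF. The display layout, hormone-axis boxes and any
biological curation are out of scope: this module reproduces the
algorithmic skeleton only.

## The synthetic generator

`generate_synthetic()` emulates the features of a currency-filtered
genome-scale compound network that the pipeline's statistics actually
depend on:

* **pathway-aligned modules** — each pathway is internally dense and
  sparsely cross-linked; the first cross reactions follow a random
  spanning tree over pathways so the background forms one weak component;
* **heavy-tailed degrees** — compound participation within a pathway is
  Zipf-weighted (exponent 0.8), creating hub metabolites as in real
  networks; without them, hub-biased sets cannot be distinguished from
  random ones at realistic effect sizes;
* **currency metabolites** woven through reactions of every pathway, so
  the currency-removal path is exercised;
* **reversibility** (default 25–30% of reactions bidirectional) producing
  a strongly connected core, plus planted isolated components;
* **planted truth**: module membership (= pathway), an enriched pathway
  holding 8 of the 20 differential members (12 more drawn from the
  background, regulation ±1 uniform, optional hub bias with sampling
  weight `1 + hub_bias·degree`), and a proximal target set drawn from the
  differential set's distance-2 ball by cycling over its members so the
  proximity is spread across the whole set.

Defaults (5 pathways × 20 compounds, 9 intra-pathway and 8 cross-pathway
reactions, 4 currency compounds, 2 isolated pairs) were calibrated once so
the filtered network's mean in/out degree sits near 1.5 — the density
regime of the genome-scale network this emulates — and then frozen.
Everything is deterministic given the seed, and generation goes through
the same text dialect the parser consumes, so the generator also tests the
I/O path.

What the generator does *not* emulate: mass spectra, feature selection and
metabolite identification upstream of the set; stoichiometry; annotation
errors; and the sheer scale of real networks. Passing benchmarks here
demonstrates the statistical machinery recovers planted structure under
realistic topology — not that any particular biological conclusion is
correct.

**Problem sizes.** The test and acceptance suites run the default 5×20
configuration for parsing/enrichment benchmarks, a 40 pathways × 25
compounds configuration (~650-node networks) with 49-member sets for the
null-calibration, hub-sensitivity and proximity benchmarks — matching the
relative set-to-network occupancy of a genome-scale analysis — and
10-seed recovery runs at 25 intra- vs 5 cross-pathway reactions for the
planted-module benchmark. These sizes keep the full suite in the
low minutes on one CPU while leaving every statistic enough room to
separate signal from null.

## Known limitations

* The closeness convention, while principled, is one of several
  reasonable choices; absolute closeness values are not comparable across
  conventions (Z-scores largely are).
* Modularity maximisation is stochastic; different seeds can return
  different near-optimal partitions, and the module *indices* carry no
  meaning. Judgements should rest on Q, the cluster structure and
  enrichment — not on individual module identities.
* The enrichment population choice (annotated vs all network nodes vs an
  externally defined universe) shifts p-values; report it alongside
  results.
* The distance-proximity Z is underpowered on small networks, as
  discussed above.
* Degree-preserving (rewiring) nulls are deliberately not implemented;
  the random-set null answers the question posed here, but it does not
  control for degree.
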