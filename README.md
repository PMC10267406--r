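# boolpath

Boolean modeling and perturbation analysis of molecular pathway maps.

Curated disease and signaling maps (drawn in process-description notation,
with explicit reactions, complexes and modifiers) are a rich source of
mechanistic knowledge, but they are not directly executable. `boolpath`
turns such maps into executable logical models and runs the full dynamic
analysis a systems biologist needs to screen them for intervention points:

* **Model exchange** — plain-text Boolean rules, the two-level subset of
  SBML-qual, and SIF edge lists, with lossless round trips.
* **Translation** — reduction of process-description reaction graphs to
  activity-flow Boolean networks (receptor/complex/inactive-form/transport
  rewriting rules) and inference of each species' Boolean function.
* **Topology** — in/out degrees, feedback loops, and directed unnormalized
  betweenness and stress centralities.
* **Dynamics** — synchronous and asynchronous updates, state-transition
  graphs, and a Gillespie-style continuous-time stochastic simulator.
* **Attractors** — five search strategies: exhaustive enumeration with
  basins, SAT-based fixed points and fixed-length cycles (compiled DPLL
  with watched literals), SCC-decomposition composition with verification
  flags, heuristic restarts, and certified asynchronous random walks.
* **Perturbation screening** — knockouts and overexpressions scored with
  similarity- and identity-based attractor distances, combined with
  centrality into a target priority ranking.

## The model

A Boolean network assigns each biomolecule *i* a binary activity
σ<sub>i</sub> ∈ {0, 1} and an update function *B<sub>i</sub>* over its
regulators. Synchronous dynamics update all nodes at once,
σ<sub>i</sub>(t+1) = *B<sub>i</sub>*(σ(t)); asynchronous dynamics update
one node per step. Attractors — fixed points, synchronous cycles, or
terminal strongly connected components of the asynchronous state graph —
are the model's stable phenotypic programs, and their basins of attraction
measure how much of state space commits to each program.

Fixed points are found by encoding σ<sub>i</sub> ↔ *B<sub>i</sub>*(σ) as
CNF (Tseitin translation) and enumerating all models. The stochastic
engine treats the network as a continuous-time Markov chain: every node
whose function disagrees with its value flips with rate `rate_up` or
`rate_down` (default 1), and Monte-Carlo trajectories estimate each node's
ON-probability over time.

Structural importance uses betweenness centrality
C<sub>B</sub>(v) = Σ<sub>s,t</sub> σ(s,t|v)/σ(s,t) and stress centrality
C<sub>S</sub>(v) = Σ<sub>s,t</sub> g<sub>st</sub>(v), both on the directed
interaction graph, unnormalized, endpoints excluded. Perturbation impact
compares the unperturbed attractor-state set *A* with the perturbed set
*B* (perturbed node projected out) using the similarity
s = |A∩B|/|A∪B| (a Jaccard index; also reported as the dissimilarity
1 − s) and the identity-based distance d = 1 − |A∩B|/|A|. Targets are
ranked by the mean of min–max-normalized betweenness and identity
distance.

## Worked example

The tau phosphorylation switch — a kinase complex activates, a prolyl
isomerase inhibits (shipped as `inst/extdata/maptp.rules`):

```r
library(boolpath)
bn <- read_rules(system.file("extdata", "maptp.rules", package = "boolpath"))
bn
#> Boolean network  with 3 nodes ( 2 free inputs )
#>   CDK5_p25 = CDK5_p25
#>   PIN1 = PIN1
#>   MAPTP = CDK5_p25 & !PIN1

sif_edges(bn)
#>     source  relation target
#> 1 CDK5_p25 activates  MAPTP
#> 2     PIN1  inhibits  MAPTP

attractor_table(exhaustive_sync(bn))
#>     kind     method length states basin_size verified certified
#> 1 steady exhaustive      1    000          2       NA        NA
#> 2 steady exhaustive      1    010          2       NA        NA
#> 3 steady exhaustive      1    110          2       NA        NA
#> 4 steady exhaustive      1    101          2       NA        NA
```

Four steady states, one per input combination (bit order
`CDK5_p25 PIN1 MAPTP`): tau is phosphorylated (`101`) exactly when the
kinase is present and the isomerase absent. Knocking out either input
loses half of the projected attractor patterns, while clamping the output
itself changes nothing upstream:

```r
rep <- sensitivity_report(bn,
  search = attractor_search_config(methods = "exhaustive"))
rep[rep$mode == "knockout", c("node", "d_sim", "d_id")]
#>       node     d_sim      d_id
#> 1 CDK5_p25 0.6666667 0.3333333
#> 3     PIN1 0.6666667 0.3333333
#> 5    MAPTP 1.0000000 0.0000000
```

The same model can be produced from its process-description form
(`inst/extdata/maptp_pd.txt`) with `translate_pd(read_pd_graph(...))`, and
pathway-scale synthetic models (65–391 nodes, layered inputs → signaling
cascade → phenotype sinks such as `autophagy` and `neuron_death`) come
from `pathway_like()`. `run_pipeline()` chains topology, attractor search,
perturbation scan and stochastic simulation into a reproducible report
bundle with a hashed manifest (`verify_run()` re-checks it).

## Rule dialect

One line per node: `target, expression`, with `&`, `|`, `!`, parentheses,
constants `0`/`1`, `#` comments. A node whose expression is its own name is
a free input. Identifiers containing spaces or colons (common in curated
map exports) are normalized to underscores on read; original names are
kept as labels. The SIF export uses the relation vocabulary
`activates` / `inhibits` / `interacts` (the latter for regulators that
appear in both polarities).

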