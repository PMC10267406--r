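---
title: "Boolean modeling of pathway maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean modeling of pathway maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolpath)
```

This vignette documents the modeling assumptions, algorithmic choices and
numerical conventions behind `boolpath`, in the spirit of a methods
section: what the package computes, why each default is what it is, and
where the approximations live.

## From reaction diagrams to logic

Curated pathway maps describe mechanism in process-description style:
reactions with reactants, products, and positive or negative modifiers,
plus bookkeeping species (inactive forms, receptor–ligand complexes,
transported copies of one biomolecule). An executable logical model wants
one node per biomolecule *activity*. `apply_reduction_rules()` bridges the
two representations with four rewriting rules, applied in order 1→4 and
iterated to a fixpoint:

1. in a receptor–ligand association the receptor reactant is removed;
2. in a protein–protein association all reactants are removed and the
   reaction's modifiers remain attached to the complex product;
3. an inactive species participating in exactly one reaction is removed;
4. a transport reaction between two copies of the same biomolecule is
   collapsed onto the product, re-linking the reactant's other reactions.

Each application is logged in a `TranslationTrace`; `replay_trace()`
re-derives the reduced graph from the original, so every deletion is
auditable. Termination is guaranteed because each rule strictly shrinks
the graph; a cap of `10 * n_reactions` iterations guards against
implementation regressions.

`infer_logic()` then assigns each produced species the function

> (OR over producing reactions of (AND of reactants and positive
> modifiers)) AND NOT (OR of negative modifiers)

This *dominant-inhibitor* combination — any inhibitor vetoes all
production routes — is the single most consequential modeling choice in
the translation, and the example fragments that motivate it (a kinase
driving a phosphorylation against an isomerase) do not pin down the
general case. It is therefore switchable: `inhibitor_mode = "or"` scopes
each reaction's inhibitors to its own disjunct. Whether the reactants of
non-association reactions should always be AND-ed is equally
under-determined by the source material conventions; we keep the AND as
the mechanistically conservative reading and document it here rather than
guessing further. Species that are never produced become free inputs
(self-identity functions), which keeps the input/state distinction visible
in every downstream report.

## Update schemes and their semantics

* **Synchronous** (`sync_step`): all nodes recomputed simultaneously; the
  dynamics are a deterministic map on $\{0,1\}^n$, so every trajectory
  ends in a fixed point or a cycle.
* **Asynchronous** (`async_step`, `build_stg`): one node recomputed per
  transition; no-change self-loops are omitted from the state-transition
  graph so steady states are exactly its sinks, and complex attractors
  are its terminal strongly connected components.
* **Continuous-time stochastic** (`simulate_ctmc`): a Markov jump process
  in which every node whose function disagrees with its current value is
  an eligible flip with propensity `rate_up` (toward ON) or `rate_down`
  (toward OFF). Jump times are exponential in the summed propensity and
  the flipped node is chosen proportionally (a Gillespie scheme). Rates
  default to 1 in both directions — absent kinetic information the chain
  is then exactly the uniform asynchronous random walk in continuous
  time. Graded biological inputs (expression levels, flux magnitudes in
  [0, 1]) are mapped to *initial ON-probabilities*, not to rates: a level
  of 0.8 means the input starts ON in 80% of trajectories. Unspecified
  nodes start at Bernoulli(0.5).

The simulator reports per-node ON-probabilities on a regular time grid
with binomial Monte-Carlo standard errors, plus the occupancy of each
distinct final-time pattern. Every stochastic result records its seed.

## Attractor search strategies

Five strategies cover the speed/completeness spectrum:

* `exhaustive_sync()` enumerates all $2^n$ states (cap: 24 nodes,
  vectorized successor map, pointer-doubling cycle detection) and returns
  exact basins of attraction.
* `sat_steady_states()` encodes $x_i \leftrightarrow B_i(x)$ via Tseitin
  translation and enumerates all models of the CNF with blocking clauses.
  The solver (`src/dpll.cpp`) is a DPLL with two-watched-literal unit
  propagation; branching on the lowest-numbered unassigned variable makes
  the $n$ state variables decision variables and all Tseitin gates
  propagated. `write_dimacs()` exports the same CNF for any external
  solver. Note a model with $m$ unconstrained inputs has at least $2^m$
  fixed points; `limit` caps the enumeration.
* `sat_cycles(L)` unrolls the update over $L$ steps with wrap-around and
  pairwise state-distinctness, blocking each found cycle together with
  all its rotations. Cycles are canonicalized to their lexicographically
  smallest rotation, so deduplication is deterministic.
* `decomposition_search()` condenses the interaction graph into strongly
  connected blocks, solves each block exhaustively under its upstream
  context (frozen to the candidate's first phase), and composes block
  attractors with least-common-multiple phase alignment. The composition
  is deliberately surfaced as an *approximation*: freezing upstream
  phases discards inter-block synchrony, which both misses some product
  cycles and fabricates candidates. Every candidate therefore carries a
  `verified` flag from a direct synchronous check on the full network,
  and the tests pin down that verified candidates are exactly the true
  attractors.
* `heuristic_search()` iterates the synchronous map from random starts
  with Brent's cycle detection; `async_random_walk()` performs random
  asynchronous walks. A walk that exhausts its step budget triggers a
  bounded forward-closure exploration from its final state; because the
  closure is complete, its terminal SCCs are *certified* attractors of
  the full system (closed under every asynchronous transition). If the
  closure would exceed `state_cap` (default 4096 states) the tail is
  reported uncertified rather than silently trusted. When the state space
  is no larger than the number of walks, initial states are sampled
  without replacement, making attractor recovery a guarantee instead of a
  coupon-collector gamble. Both samplers' outputs are lower bounds on the
  true attractor set by construction.

## Topology conventions

Centralities are computed on the directed interaction graph (one edge per
regulator → target pair, as emitted by `write_sif()`), unnormalized, with
path endpoints excluded — raw-count magnitudes are what make the scores
comparable across models of different sizes in reports. Betweenness uses
Brandes's dependency accumulation; stress shares the same BFS shortest-path
DAG and accumulates $\sigma_{sv} \cdot P(v)$ where $P(v)$ counts DAG path
continuations. The two satisfy $C_B(v) \le C_S(v)$ everywhere, which the
tests exploit as an invariant. `top_quantile()` reads "top quantile" as
the top quartile of the *nonzero* betweenness distribution by default
(`q = 0.25`, ties included), and an `undirected` switch exposes the
alternative convention since source material for such analyses often
leaves the direction convention unstated.

## Perturbation semantics

A perturbation clamps one node's function to a constant (`knockout` = 0,
`overexpression` = 1). Sensitivity compares the *union of all attractor
states* before and after clamping, with the clamped node's coordinate
projected out — the union because multi-attractor landscapes must be
compared as wholes, the projection because the clamped coordinate would
otherwise register as a guaranteed, uninformative difference. On those
projected sets:

* similarity $s = |A \cap B| / |A \cup B|$ (Jaccard; 1 − s is also
  reported as `dissimilarity`), and
* identity distance $d = 1 - |A \cap B| / |A_{\text{unpert}}|$,
  asymmetric by design: it measures how much of the unperturbed landscape
  is lost.

The headline scalar is the identity distance, because a single "knockout
sensitivity" number should be anchored on the unperturbed reference. Both
distances are always reported side by side. `prioritize_targets()`
min–max-normalizes betweenness and identity distance and ranks by their
mean, additionally reporting the intersection of the top-`q` sets under
each criterion separately — high-centrality/low-sensitivity inversions,
which are common, are then visible rather than averaged away.

## Synthetic models and what the tests show

`random_network()` draws classic N-K-p random Boolean networks: `k`
distinct regulators per non-input node, truth tables with ON-bias `p`
(default 0.5, the standard unbiased ensemble), constant tables redrawn so
the realized in-degree equals `k`. `pathway_like()` builds layered
input → signaling → phenotype networks with dominant-inhibitor functions
and a controlled number of genuine feedback cycles, sized to the scales
of curated pathway models (about 65/86, 167/196 and 391/436
nodes/edges), with phenotype sinks (`autophagy`, `neuron_death`)
reachable from inputs. `motif()` provides fixed fixtures with known
attractor structure.

These generators emulate the *sizes and shapes* of curated pathway
models — cascade depth, dedicated inputs, phenotype sinks, sparse
feedback — not their biology: no annotation, no compartment semantics, no
empirically fitted degree distribution, and functions drawn from a
uniform grammar rather than curated mechanisms. Green tests on this
ensemble therefore certify the *algorithms* (set equalities against
brute-force oracles, closed-form laws, matrix-exponential references),
not the biological fidelity of any particular map translation.

Validation problem sizes were chosen so each oracle stays exact: ensembles
of 100 networks with up to 12 nodes for SAT-vs-exhaustive equality and
format round trips, all-states ground truth up to 8 nodes for
asynchronous walks, 6-node chains against `Matrix::expm`, 50 digraphs
against a full shortest-path enumeration, and $10^4$ trajectories for
stochastic comparisons at 3–4 standard errors.

## Numerical conventions and degenerate inputs

* States are encoded as integer codes (node $i$ = bit $2^{i-1}$) wherever
  the state space is exhaustively enumerable; codes are exact up to 48
  nodes. Beyond that every set-valued computation (SAT enumeration,
  walks, sensitivity) switches to bit-string keys, which are exact at any
  size — pathway-scale models run through the same public API.
* `exhaustive_sync` caps at 24 nodes; full STGs at 20; decomposition
  blocks at 16; closure exploration at 4096 states. Caps fail loudly.
* Empty attractor-state sets: two empty sets have similarity 1; the
  identity distance requires a nonempty reference and errors otherwise.
* Expression parsing accepts only `&`, `|`, `!`, parentheses, identifiers
  and 0/1; anything else is a hard error with a line number — malformed
  model files never degrade silently. The same strictness applies to the
  SBML-qual subset (two-level species only, one transition per target,
  `and`/`or`/`not`/`eq` MathML).
* All RNG flows through R's generator via explicit seeds; the pipeline
  fans a single global seed out to per-stage seeds (`seed + 1000 ×
  stage position`), so stage-level reruns match full runs, and the run
  manifest records content hashes for every output file.

## Known limitations

* The dominant-inhibitor logic inference is a convention, not a derived
  fact; models whose curation intends OR-of-inhibited-routes semantics
  must set `inhibitor_mode = "or"`.
* Decomposition search is approximate by construction (see above); its
  unverified candidates are reported, not suppressed, because the
  mismatch pattern itself is diagnostic of inter-block coupling.
* SAT fixed-point enumeration is exponential in the number of free
  inputs; use `limit`, or clamp inputs to scenario values first.
* The stochastic engine implements binary activities only; multi-level
  logic and ODE hybrid semantics are out of scope.
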