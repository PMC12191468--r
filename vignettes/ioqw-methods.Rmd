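---
title: "Methods: a quantum-walk-inspired influence score and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a quantum-walk-inspired influence score and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioqw)
```

## The walk and what it assumes

The package scores the nodes of a simple undirected graph by spreading
influence using machinery borrowed from one-dimensional coined quantum
walks. On a line, a coined walker has two directions per site, so its state
space has dimension twice the number of sites, and the evolution is the
repeated product of a shift operator with a coin. The influence score keeps
this 2-per-node structure on an arbitrary graph by a modelling device:
every node gets a conceptual self-loop (the *stay* direction, `f`) and its
entire neighbourhood is treated as one integrated unit (the *move*
direction, `b`). The state vector therefore has length `2N` in coin-major
order, and no operator ever exceeds `2N x 2N`.

The three operators, and the reasoning behind their shapes:

* **Coin** `C[j,k] = -A[j,k] + 2/(Pa(j,k) + 2)` — a Grover-diffusion-like
  matrix. The path term decays with the shortest-path distance `Pa`, so the
  coin injects global topology; the `-A` term gives each edge entry the
  constant value `-1/3`, and the diagonal (`Pa = 0`) is 1, so amplitude
  prefers to stay put, damping the oscillatory "traceback" that makes long
  coined walks unstable to measure.
* **Shift** `S = I ⊕ Â`, with `Â` the row-normalised adjacency. The stay
  sector is untouched; the move sector follows the classical random-walk
  transition. `S` is intentionally *not* unitary — `Â` is stochastic, not
  orthogonal — so total "probability" is not conserved. The test suite
  asserts this non-conservation explicitly; only relative score magnitudes
  carry meaning. The genuinely unitary regime (permutation shift, unitary
  2x2 coin) is retained in the `line_*` functions as a validation reference,
  where probability *is* conserved to 1e-10 over hundreds of steps.
* **Measurement** `P(j) = (⟨ĵ| U(t) |ψ(0)⟩)²` with `⟨ĵ|` weighting each
  neighbour `k` of `j` by `|N(k)|/M` in both sectors. Reading influence
  through the degrees of the neighbourhood makes the score sensitive to
  nodes that sit next to hubs even when their own degree is modest.

Because `U(t) = (S · (C ⊕ C))^t = blockdiag(C^t, (ÂC)^t)`, the ranking
pipeline needs only matrix–vector products; the `2N x 2N` operator is
materialised only in the structural test that verifies this identity.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `t` (walk steps) | 2 | hops of structure folded into the evolution; 2 captures the 2-hop neighbourhood that local-information studies find sufficient, while suppressing traceback oscillation |
| `variant` (coin) | `"additive"` | algebraic reading of the coin entry; see below |
| `max_distance` | `Inf` | distances beyond this are treated as infinite in the coin, capping the all-pairs cost for very large graphs |
| `damping` (PageRank) | 0.85 | pinned: reproduces the canonical karate-club PageRank order |
| `gamma` (SIR recovery) | 1 | infected nodes recover after exactly one step — the standard convention in influence benchmarking; exposed for sensitivity work |
| `p` (SIR infection) | `1.5 x` threshold, capped at 1 | the outbreak condition only bounds `p` from below by `<k>/(<k²>-<k>)`; a fixed multiplier makes runs comparable and reproducible |
| `runs` (SIR) | 1000 | repetitions per seed node; the scale at which mean final sizes stabilise to a few percent on small networks |

## The coin-variant decision

The coin entry can be read two ways: *additive*,
`-A[j,k] + 2/(Pa+2)`, or *ratio*, `(2-A[j,k])/(Pa+2)`. Both are
implemented; the additive form is the shipped default, for two reasons.
First, it mirrors the Grover diffusion structure (a constant negative
contribution on links, a dominant diagonal) that motivates the design.
Second, on the Zachary karate-club benchmark the additive form recovers
the canonical influential set — leaders 1 and 34 first, then the community
hubs 3, 33, 2 and the bridge 14, with the structurally subtle nodes 8 and
9 inside the top-10 — whereas the ratio form drops node 8 (whose influence
comes entirely from sitting next to four hubs) in favour of the peripheral
node 31. Node 8 is exactly the kind of node a degree-blind score misses,
so the variant that finds it is the better default. Within the top-10 the
scores of the mid-ranked nodes (4, 8, 9, 32) are close in magnitude, and
their exact order is sensitive to implementation details of this
resolution; the package's deterministic tie-break (descending score, then
ascending label) fixes one canonical order.

A related choice: the diagonal uses `Pa(j,j) = 0`, giving `C[j,j] = 1`.
Treating the conceptual self-loop as a unit distance (diagonal `2/3`)
demotes the leaders' separation on the same benchmark and was rejected.

## Initial-state normalisation

The uniform initial state is stored with entries `1/sqrt(2N)` (unit
Euclidean norm). A uniform state normalised per sector instead would scale
every amplitude by a constant; the measured scores scale by the constant
squared and the ranking is provably unchanged (this invariance is tested).
Unit norm keeps the quantum-walk reading honest without affecting results.

## The SIR ground truth

Influence ground truth is the mean final outbreak size from a discrete-time
SIR process seeded at each node: susceptible neighbours of an infected node
are infected independently with probability `p`; infection is resolved
before recovery within a step (synchronous updates); a run ends when no
infected nodes remain, and its outcome is the count of ever-infected nodes.
Each (seed node, repetition) pair draws from its own RNG substream derived
from the master seed, so results are bit-for-bit reproducible and
independent of evaluation order. On the karate club at `runs = 1000` the
walk's scores reach Kendall τ ≈ 0.89 against this ground truth, versus
≈ 0.66 for degree (both recomputed by `scripts/acceptance.R`).

## Kendall τ convention

`kendall_tau()` implements τ-a: strictly concordant minus strictly
discordant pairs over all `n(n-1)/2` pairs, ties counting in neither. This
matches the pair-counting definition used in influence benchmarking, but
differs from the tie-corrected τ-b of `stats::cor.test`; heavily tied
score vectors (degree sequences, for instance) cannot reach `|τ| = 1`
even against themselves. `average_tau()` rounds half-up, the convention of
printed tables (R's `round` is half-even on binary doubles and would turn
a mean of 0.4715 into 0.471).

## Synthetic graphs: what they do and do not cover

`generate_random()` provides Erdős–Rényi graphs (homogeneous degrees,
vanishing clustering) and Barabási–Albert graphs (heavy-tailed degrees,
connected by construction). They exercise the pipeline across densities
and degree heterogeneity, which is what the invariance tests (permutation
equivariance, handshake counts, distance oracles) need. They do not emulate
the community structure, high clustering, or degree assortativity of real
social and biological networks, so green tests on them demonstrate
correctness of the computation, not ranking quality on real data; the
karate-club fixture and the SIR correlation carry that burden at small
scale.

## Numerical choices and degenerate inputs

* Disconnected node pairs take the `Pa -> Inf` limit of the path term,
  `2/(Pa+2) -> 0`; no large-finite-distance surrogate is ever used.
  Ranking a disconnected graph warns but proceeds.
* Isolated nodes get a zero row in `Â`, a zero measurement vector and
  score 0, ranked last among ties.
* Ranking ties are broken by ascending node label (numeric when all labels
  are numeric, lexicographic otherwise), making every ranking
  deterministic.
* All arithmetic is double precision and dense; the all-pairs BFS distance
  matrix is the dominant cost (`O(N·M)` time, `O(N²)` memory). A
  2000-node, 8000-edge scale-free graph ranks in a few seconds. The
  `max_distance` truncation exists for users who want near-linear cost on
  bigger graphs at the price of coarsening long-range coin entries.
* PageRank is computed by explicit power iteration with an L1 stopping
  rule (`tol = 1e-10`), dangling mass redistributed uniformly; the test
  suite cross-checks it against an independent solver.

## Problem sizes in the test suite

The suite validates distances against a Floyd–Warshall oracle (graphs up
to 30 nodes), betweenness against exhaustive shortest-path enumeration (up
to 12 nodes), τ-a against a quadratic pair count (200 random vectors up to
length 50), equivariance on 20 random graphs, unitary-walk conservation
over 100 steps, and SIR behaviour at 1000 runs per seed on the karate
club. These sizes keep the full suite to a couple of minutes while leaving
every property at a scale where the brute-force oracle is exact.

## Known limitations

* Directed, weighted, temporal and multilayer networks are out of scope.
* The full coin uses all-pairs shortest paths, so the end-to-end cost is
  `O(N·M)` rather than the `O(N<k>)` of the neighbour-local parts; on
  graphs where that matters, `max_distance` trades fidelity for cost.
* SIR is synchronous discrete-time; continuous-time (Gillespie) dynamics
  are not implemented.
* Scores are not a probability distribution (non-unitary evolution); do
  not compare raw magnitudes across graphs.
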