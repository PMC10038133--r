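---
title: "Streaming contact-network generation: models, algorithms and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming contact-network generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamnet)
```

# The streaming contract

streamnet generates undirected contact networks for epidemic-simulation
pipelines. The central design decision is that a network is never a
materialized object: it is an `edge_stream`, a declared node count `n` plus
a closure that yields successive chunks of edges (two-column matrices) and
`NULL` on exhaustion. Writers pull chunks and flush them, so peak memory is
the chunk buffer — independent of both `n` and `|E|` — with two documented
exceptions:

* `gen_ba()` keeps the repeated-endpoints array required by preferential
  attachment, `2m(n−m)` numbers, reserved up-front because the final edge
  count is known exactly;
* `gen_nws()` keeps its `S` shortcut edges (`S ~ Binomial(nk/2, p)`), but
  never the `nk/2` lattice edges, which are streamed arithmetically.

`degree_histogram()`, `is_connected()`, `stream_edges()` and the two file
readers are explicitly test-scale utilities: they need O(n) or O(|E|)
memory and are exempt from the contract.

Streams are single-use. Reproducibility is by reconstruction: a generator
rebuilt with the same parameters and seed is edge-for-edge identical, which
is also what makes seeded CLI runs byte-identical.

Nodes are consecutive 0-based integers `0 … n−1`, stored as doubles so that
labels beyond the 32-bit integer range work; all label and index arithmetic
is exact up to 2^53, and generators reject larger `n` rather than risk
silent rounding. The 8-byte on-disk width therefore supports the full
double-exact range, not the full 64-bit range.

# Randomness

All stochastic generators draw from an explicit `random_source`, which owns
a private copy of R's Mersenne-Twister state. Draws are made by swapping
that state in, drawing, and swapping it out, so streams never perturb the
global RNG or each other, and a seed plus a call sequence determines every
draw. Binomial counts use `stats::rbinom` (exact for any `size`, including
sizes beyond 2^31 — verified at construction time in tests); a normal
approximation is never used, because test assertions at small `nk/2` depend
on exact binomial tails. Uniform integers on huge ranges are
`floor(runif() * N)` clamped to `N−1`, whose bias at `N ≤ 2^53` is
below observable levels for any feasible draw count.

# Deterministic models

Emission order is part of the package contract, chosen for streaming
simplicity and testability:

* **complete** — all pairs `(u, v)`, `u < v`, lexicographically;
* **path** — `(i, i+1)` for `i = 0 … n−2`;
* **cycle** (`n ≥ 3`) — the path, then the closing edge `(n−1, 0)`.
  Smaller `n` is rejected: a 1- or 2-cycle needs self-loops or duplicate
  edges, both excluded from every model here;
* **barbell** — bell A (complete on `0 … n1−1`), bell B (complete on
  `n1 … 2n1−1`), then the connecting path on `2n1 … 2n1+n2−1`, attached to
  node `n1−1` of A and node `n1` of B (a single direct bridge when
  `n2 = 0`). The attachment nodes are this package's choice — the usual
  barbell construction — and keep the graph connected for all `n2 ≥ 0`.
  Total edges `n1(n1−1) + n2 + 1`;
* **ring lattice** — for each node `u` and forward offset `d = 1 … k/2`,
  the edge `(u, (u+d) mod n)`; each undirected edge appears exactly once
  because only forward offsets are emitted. `k` must be even (each node
  takes `k/2` neighbours per side) and `2 ≤ k ≤ n−2`: beyond `n−2` the
  mod-`n` offsets would revisit pairs, so such lattices are rejected rather
  than silently deduplicated. `RingLattice(n, 2)` coincides with
  `Cycle(n)` — edge for edge, in our orders — which the tests assert;
* **empty** — `n` nodes, no edges: the node count travels in the stream
  (and in the FAVITES dialect), since a plain edge list cannot represent
  isolated nodes.

# Erdős–Rényi G(n, p)

Each of the `C(n,2)` pairs is included independently with probability `p`.
The naive sampler walks all pairs and flips per-pair coins in vectorized
blocks — O(1) state but O(n²) time. The fast sampler exploits the fact that
the gap between consecutive included pairs is geometric: with
`r ~ Uniform(0,1)`, advance `1 + floor(log(1−r)/log(1−p))` positions and
emit the pair landed on. Gaps are drawn in batches and cumulated, so the
sampler is vectorized in R yet still O(1) in retained state, with expected
time O(n + |E|). The two samplers are distributionally identical, which the
acceptance suite checks both per-pair (inclusion frequency of a fixed pair
against a 99% binomial CI) and in aggregate (chi-square goodness of fit of
the edge-count distribution against `Binomial(C(n,2), p)` at α = 0.01).

Numerical choices: `p = 0` emits nothing without consuming draws, and
`p = 1` delegates to the complete-graph walk, since `log(1−p)` is undefined
there. The skip length uses floating-point `log1p`, but positions are exact
integer-valued doubles, decoded to pairs by inverting
`f(u) = un − u(u+1)/2` with a square-root estimate corrected by exact
integer comparisons (at most ±1 off, fixed by a two-pass adjustment). This
is why the fast sampler requires `C(n,2) ≤ 2^53`.

# Barabási–Albert

Nodes `0 … m−1` seed the target set; each new node `v = m … n−1` picks `m`
distinct targets by uniform draws from the repeated-endpoints list
(degree-proportional by construction), redrawing on duplicates, then `v`
and its targets join the list. The first new node necessarily takes all of
`0 … m−1` and does so directly, without consuming draws. This yields
exactly `m(n−m)` edges, a simple graph, and connectivity by induction —
the three properties the tests pin down. The redraw-on-duplicate scheme
conditions each step's target set on being distinct, matching the standard
growth construction.

# Newman–Watts–Strogatz

Start from `RingLattice(n, k)`; for each of its `nk/2` edges, add a random
shortcut with probability `p`. No edges are removed, so the cycle inside
the lattice survives and every sample is connected.

The memory-efficient sampler rests on an exact combinatorial bijection.
Each node `u` has `n−k−1` admissible partners (everyone except itself and
its `k` lattice neighbours), giving an `n × (n−k−1)` matrix whose cell
`(r, j)` holds partner `w = (r + k/2 + 1 + j) mod n`. Unordered symmetry
lets the lower-right half be disregarded: rows `0 … k/2` remain full
(length `L = n−k−1`), row `k/2 + i` loses `i` cells, and rows from
`n − k/2 − 1` on are empty, leaving exactly `n(n−k−1)/2` admissible cells —
always equal to `C(n,2) − nk/2`. Numbering those cells row-major gives a
flat index range that can be sampled uniformly:

1. draw `S ~ Binomial(nk/2, p)` — the `nk/2` Bernoulli trials collapse into
   one binomial draw;
2. draw `S` distinct integers uniformly from `0 … n(n−k−1)/2 − 1`
   (`sample_distinct_integers()`: rejection with de-duplication, O(S)
   memory; when `S` exceeds half the range — itself then O(S) — it falls
   back to R's without-replacement sampler);
3. map each index to its cell — full rows by integer division, the
   triangular tail of row lengths `L−1, L−2, … 1` by a square-root estimate
   corrected with exact integer comparisons (±1 post-check, so the
   bijection stays exact at 8-byte widths) — and each cell to its edge.

Because the bijection's range is exactly the non-lattice pairs, shortcuts
can never duplicate lattice edges, and distinct indices can never collide.
The tests verify the bijection against a brute-force circular-distance
enumeration for every valid `(n, k)` with `n ≤ 25`.

One corner the model description leaves open: when `k > (n−1)/2` there are
more lattice edges than admissible cells, so `S` can exceed the range. We
clamp `S` to the admissible count and warn, rather than error — the sample
then simply saturates at the complete graph's missing pairs.

A second open point is the naive reference sampler's shortcut-endpoint
distribution: "add `(u, w)` with probability `p`" does not pin down how `w`
is drawn. `gen_nws_naive()` draws `w` uniformly from the nodes not already
adjacent to `u`; the efficient sampler is cell-uniform over admissible
pairs. On a plain ring these coincide marginally per edge (vertex
transitivity), but their joint distributions need not be identical, so the
equivalence test compares the statistics both readings share: the per-edge
shortcut frequency table (two-sample chi-square, α = 0.01) and the
shortcut-count distribution. The cell-uniform distribution is treated as
normative; the naive sampler is an oracle, capped at test-scale `n`.

# File formats

The plain dialect is one `u<TAB>v` line per edge; the FAVITES dialect
writes `NODE<TAB>label<TAB>.` for every node then
`EDGE<TAB>u<TAB>v<TAB>.<TAB>u` per edge (attributes empty, trailing `u` =
undirected), so it round-trips the node count. The binary format is one
header byte holding the width `b`, then `2b` bytes per edge, endpoints as
`b`-byte little-endian unsigned integers in emission order: exactly
`2b|E| + 1` bytes. Header semantics, endianness and ordering are this
package's own dialect — self-consistent and round-trip-exact, but not
claimed byte-compatible with other tools' binary formats, whose layouts
are unpublished. Labels that do not fit the chosen width abort the write
with the offending edge named. A `.gz` suffix wraps either format in gzip
transparently.

The readers materialize files rather than stream them (the plain dialect
cannot even declare `n` until fully read); they exist for round-tripping
and interoperability, not for the generation path.

# Test scales and what passing shows

Stochastic assertions run at sizes chosen to make the checks sharp yet
quick: G(n,p) equivalence at `n = 30`, `p ∈ {0.05, 0.2}`, 5000 replicates
per sampler; NWS connectivity over 200 random parameter draws with
`n ≤ 60`; the shortcut-count chi-square at `n = 9, k = 2, p = 0.5`, 4000
replicates; uniformity of distinct-integer sampling at 20,000 replicates.
All use fixed seeds, with 99% confidence intervals or α = 0.01 tests, so
a correct implementation fails any given check with probability about
1%. Laziness is asserted behaviourally: bounded prefixes of 10^8-node
streams must arrive in well under a second, across four orders of
magnitude of `n`.

These tests exercise generated graphs only. They show the samplers have
the intended distributions and invariants; they do not show that any model
is a good description of a real contact pattern — model choice against the
transmission mode of a pathogen remains the epidemiologist's call.

# Known limitations

* Node labels and pair indices above 2^53 are rejected, so the practical
  ceiling is below the nominal 8-byte limit.
* `gen_er_fast()` additionally requires `C(n,2) ≤ 2^53`.
* The plain edge-list dialect drops isolated nodes; use the FAVITES
  dialect (or the binary format plus external metadata) when `n` matters
  downstream — in particular for empty and very sparse graphs.
* Writing binary output to standard output uses `/dev/stdout` (POSIX).
* Directed graphs, self-loops, multi-edges and node/edge attributes are
  out of scope, as are rewiring small-world variants and degree-sequence
  models.
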